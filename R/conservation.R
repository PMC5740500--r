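## Cross-species conservation of exon clusters under Dollo parsimony: a
## single gain at the last common ancestor of the species carrying the
## cluster, any number of subsequent losses.

## normalise presence flags to "1"/"0"/"?" named by species
normalise_presence <- function(presence) {
  v <- as.character(unlist(presence))
  v[is.na(v)] <- "?"
  v[v %in% c("TRUE", "present")] <- "1"
  v[v %in% c("FALSE", "absent")] <- "0"
  if (!all(v %in% c("1", "0", "?")))
    stop("presence flags must be 1/0/? (or logical/NA)")
  setNames(v, names(presence))
}

#' Origin of a cluster under Dollo parsimony
#'
#' The gain node is the last common ancestor of all species carrying the
#' cluster; species with unknown state (assembly gaps, unidentifiable
#' orthologs) are ignored for origin placement.
#'
#' @param tree rooted [ape::phylo] tree with unique tip labels.
#' @param presence named vector over tip labels with values 1/0/? (or
#'   logical with NA for unknown).
#' @return node number (a tip number when a single species is present).
#' @export
dollo_origin <- function(tree, presence) {
  p <- normalise_presence(presence)
  miss <- setdiff(names(p), tree$tip.label)
  if (length(miss)) stop("species not in tree: ", paste(miss, collapse = ", "))
  present <- names(p)[p == "1"]
  if (length(present) == 0L) stop("no present species: origin undefined")
  if (length(present) == 1L) return(match(present, tree$tip.label))
  ape::getMRCA(tree, present)
}

#' Loss events of a cluster under Dollo parsimony
#'
#' Given the gain node, losses are the maximal subtrees below the origin
#' whose non-unknown leaves are all absent (at least one such leaf).
#' Unknown leaves never create or split a loss.
#'
#' @param tree rooted [ape::phylo].
#' @param presence named presence vector, see [dollo_origin()].
#' @param origin gain node; computed with [dollo_origin()] when NULL.
#' @return list with `losses` (count), `loss_nodes` (node numbers of the
#'   maximal all-absent subtrees) and `origin`.
#' @export
dollo_losses <- function(tree, presence, origin = NULL) {
  p <- normalise_presence(presence)
  if (is.null(origin)) origin <- dollo_origin(tree, p)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  kids <- vector("list", n_node)
  for (r in seq_len(nrow(tree$edge)))
    kids[[tree$edge[r, 1]]] <- c(kids[[tree$edge[r, 1]]], tree$edge[r, 2])
  state <- setNames(rep("?", n_tip), tree$tip.label)
  state[names(p)] <- p
  has_present <- logical(n_node)
  has_absent <- logical(n_node)
  fill <- function(v) {
    if (v <= n_tip) {
      has_present[v] <<- state[v] == "1"
      has_absent[v] <<- state[v] == "0"
      return(invisible())
    }
    for (k in kids[[v]]) fill(k)
    has_present[v] <<- any(has_present[kids[[v]]])
    has_absent[v] <<- any(has_absent[kids[[v]]])
  }
  root <- n_tip + 1L
  fill(root)
  loss_nodes <- integer(0)
  walk <- function(v) {
    for (k in kids[[v]]) {
      if (!has_present[k] && has_absent[k]) {
        loss_nodes <<- c(loss_nodes, k)   # maximal all-absent subtree
      } else if (k > n_tip) walk(k)
    }
  }
  if (origin > n_tip) walk(origin)
  list(losses = length(loss_nodes), loss_nodes = loss_nodes,
       origin = origin)
}

#' Read a presence/absence matrix
#'
#' TSV: first column cluster ids, remaining columns one per species, values
#' in {1, 0, ?}.
#'
#' @param path file path.
#' @return character matrix, clusters x species.
#' @export
read_presence_matrix <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                  check.names = FALSE, colClasses = "character")
  as.matrix(m)
}

#' Dollo conservation analysis over a cluster set
#'
#' @param tree rooted [ape::phylo] (or path to a Newick file).
#' @param presence matrix clusters x species with values 1/0/? (or path to a
#'   TSV, see [read_presence_matrix()]).
#' @return data.frame: cluster_id, origin node, origin label ("root", tip
#'   label, or internal node number), n_present, losses.
#' @export
dollo_analysis <- function(tree, presence) {
  if (is.character(tree) && !inherits(tree, "phylo"))
    tree <- ape::read.tree(tree)
  if (is.character(presence) && !is.matrix(presence))
    presence <- read_presence_matrix(presence)
  miss <- setdiff(colnames(presence), tree$tip.label)
  if (length(miss)) stop("species not in tree: ", paste(miss, collapse = ", "))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  rows <- lapply(rownames(presence), function(cl) {
    p <- setNames(presence[cl, ], colnames(presence))
    origin <- dollo_origin(tree, p)
    dl <- dollo_losses(tree, p, origin)
    data.frame(cluster_id = cl, origin = origin,
               origin_label = if (origin == root) "root"
                 else if (origin <= n_tip) tree$tip.label[origin]
                 else as.character(origin),
               n_present = sum(normalise_presence(p) == "1"),
               losses = dl$losses, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
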