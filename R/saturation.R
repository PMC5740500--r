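## Read-depth saturation: re-validate clusters on random sample subsets and
## extrapolate the validation count with a power-law fit.

#' Saturation analysis by sample subsampling
#'
#' For each fraction and each of `runs` independent replicates, a random
#' subset of whole samples is drawn, the clusters are re-validated on the
#' pooled reads of that subset, and two counts are recorded: the number of
#' validated clusters, and the number of clusters validated on the subset
#' but rejected on the full data (early validations that more reads
#' overturn). Per-fraction means over the runs are reported alongside the
#' per-run counts.
#'
#' @param sj an [sj_index] holding all samples.
#' @param clusters list of [mxe_cluster].
#' @param fractions proportions of samples to draw, each in (0, 1].
#' @param runs number of independent replicates per fraction (default 30).
#' @param seed optional RNG seed.
#' @inheritParams classify_cluster
#' @return list of class `saturation_curve` with `per_run` (fraction, run,
#'   n_samples, validated, rejected) and `summary` (fraction, mean_validated,
#'   mean_rejected), plus the full-data counts as attributes.
#' @export
saturation_curve <- function(sj, clusters, fractions, runs = 30L,
                             seed = NULL, min_reads = 3L, strict = FALSE,
                             frame_rule = c("per_pair", "pair_sum")) {
  frame_rule <- match.arg(frame_rule)
  stopifnot(all(fractions > 0), all(fractions <= 1))
  samples <- unique(sj$sample_id)
  if (length(samples) < 2L) stop("saturation analysis needs >= 2 samples")
  if (!is.null(seed)) set.seed(seed)
  full <- classify_clusters(clusters, sj, min_reads = min_reads,
                            strict = strict, frame_rule = frame_rule)$table
  status_full <- setNames(full$status, full$cluster_id)
  per_run <- list()
  for (f in fractions) {
    n_sub <- floor(f * length(samples))
    if (n_sub < 1L) {
      warning(sprintf("fraction %.3f yields zero samples; skipped", f))
      next
    }
    for (r in seq_len(runs)) {
      sub <- if (n_sub == length(samples)) samples
             else sample(samples, n_sub)
      tab <- classify_clusters(clusters, sj, min_reads = min_reads,
                               strict = strict, samples = sub,
                               frame_rule = frame_rule)$table
      validated <- sum(tab$status == "validated")
      rejected <- sum(tab$status == "validated" &
                        status_full[tab$cluster_id] == "rejected")
      per_run[[length(per_run) + 1L]] <- data.frame(
        fraction = f, run = r, n_samples = n_sub,
        validated = validated, rejected = rejected)
    }
  }
  per_run <- do.call(rbind, per_run)
  summary <- aggregate(cbind(validated, rejected) ~ fraction, per_run, mean)
  names(summary) <- c("fraction", "mean_validated", "mean_rejected")
  out <- list(per_run = per_run, summary = summary)
  attr(out, "full_validated") <- sum(full$status == "validated")
  attr(out, "full_rejected") <- sum(full$status == "rejected")
  class(out) <- "saturation_curve"
  out
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat("saturation curve (means over runs):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fit a power function to a saturation curve
#'
#' Nonlinear least squares for f(x) = a * x^b + c, with b constrained
#' non-negative to resolve the flat-curve ambiguity. Returns Wald 95%
#' confidence intervals and the extrapolated value at x = 2 (a twofold
#' increase in data) with a delta-method interval.
#'
#' @param x,y curve points; at least four distinct positive x values.
#' @param conf_level confidence level for the intervals.
#' @return list of class `power_fit`: a, b, c, ci (3x2 matrix), f2, f2_ci,
#'   fitted, residuals.
#' @export
fit_power <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 4L) stop("need >= 4 distinct x values")
  if (any(x <= 0)) stop("x must be positive")
  spread <- max(y) - min(y)
  if (spread == 0) {
    ## constant curve: a*x^b + c is only identified up to a + c; report the
    ## degenerate exact fit with b at its lower bound
    est <- c(a = 0, b = 0, c = y[1])
    out <- list(a = 0, b = 0, c = y[1],
                ci = cbind(lower = est, upper = est), f2 = y[1],
                f2_ci = c(lower = y[1], upper = y[1]),
                fitted = rep(y[1], length(x)),
                residuals = rep(0, length(x)))
    class(out) <- "power_fit"
    return(out)
  }
  c0 <- min(y) - max(0.05 * spread, 1e-8)
  lf <- lm(log(y - c0) ~ log(x))
  start <- list(a = unname(exp(coef(lf)[1])),
                b = max(unname(coef(lf)[2]), 0), c = c0)
  fit <- tryCatch(
    nls(y ~ a * x^b + c, data = data.frame(x = x, y = y), start = start,
        algorithm = "port", lower = c(a = -Inf, b = 0, c = -Inf),
        control = nls.control(maxiter = 1000, tol = 1e-12,
                              scaleOffset = 1, warnOnly = FALSE)),
    error = function(e)
      stop(sprintf(paste0("power fit did not converge: %s ",
                          "(start a=%.4g b=%.4g c=%.4g; residual range ",
                          "%.4g..%.4g at start)"),
                   conditionMessage(e), start$a, start$b, start$c,
                   min(y - (start$a * x^start$b + start$c)),
                   max(y - (start$a * x^start$b + start$c))),
           call. = FALSE))
  est <- coef(fit)
  V <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(pmax(diag(V), 0))
  ci <- cbind(lower = est - z * se, upper = est + z * se)
  f2 <- unname(est["a"] * 2^est["b"] + est["c"])
  grad <- c(2^est["b"], est["a"] * 2^est["b"] * log(2), 1)
  f2_se <- sqrt(max(drop(t(grad) %*% V %*% grad), 0))
  out <- list(a = unname(est["a"]), b = unname(est["b"]),
              c = unname(est["c"]), ci = ci, f2 = f2,
              f2_ci = c(lower = f2 - z * f2_se, upper = f2 + z * f2_se),
              fitted = predict(fit), residuals = y - predict(fit))
  class(out) <- "power_fit"
  out
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("f(x) = %.4g * x^%.4g + %.4g; f(2) = %.4g [%.4g, %.4g]\n",
              x$a, x$b, x$c, x$f2, x$f2_ci[1], x$f2_ci[2]))
  invisible(x)
}
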