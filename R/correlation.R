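#' Mid-parent expression matrix
#'
#' For every hybrid, the average `L` of the log2 expression of its two
#' parental lines: `L[g, h] = (x[g, flint parent] + x[g, dent parent]) / 2`.
#'
#' @param line_means matrix of probes by lines (see [line_means()]).
#' @param design factorial design with `hybrid_id, flint_parent, dent_parent`.
#' @return matrix of probes by hybrids, log2 intensity units.
#' @export
compute_midparent <- function(line_means, design) {
  fi <- match(design$flint_parent, colnames(line_means))
  di <- match(design$dent_parent, colnames(line_means))
  if (anyNA(fi) || anyNA(di)) {
    bad <- design$hybrid_id[which(is.na(fi) | is.na(di))[1L]]
    stop("hybrid '", bad, "': parent line missing from the line-mean matrix")
  }
  L <- (line_means[, fi, drop = FALSE] + line_means[, di, drop = FALSE]) / 2
  colnames(L) <- design$hybrid_id
  L
}

#' Mid-parent heterosis
#'
#' Heterosis of each hybrid as the F1 trait value minus the mean per-se value
#' of its two parents, either on the absolute trait scale (Mg/ha or percent;
#' default) or as a percentage of the mid-parent value.
#'
#' @param traits hybrid trait table with `hybrid_id, PY, PD`.
#' @param perse line per-se table with `line_id, PY_perse, PD_perse`.
#' @param design factorial design.
#' @param scale `"absolute"` or `"percent"`.
#' @return `traits` with `HY` and `HD` columns (re)computed.
#' @export
compute_heterosis <- function(traits, perse, design, scale = c("absolute", "percent")) {
  scale <- match.arg(scale)
  fi <- match(design$flint_parent, perse$line_id)
  di <- match(design$dent_parent, perse$line_id)
  if (anyNA(fi) || anyNA(di)) {
    bad <- design$hybrid_id[which(is.na(fi) | is.na(di))[1L]]
    stop("hybrid '", bad, "': per-se trait value missing for a parent")
  }
  ti <- match(design$hybrid_id, traits$hybrid_id)
  if (anyNA(ti)) stop("trait table is missing hybrid '",
                      design$hybrid_id[which(is.na(ti))[1L]], "'")
  het <- function(f1, pvals) {
    mp <- (pvals[fi] + pvals[di]) / 2
    if (scale == "absolute") f1 - mp else 100 * (f1 - mp) / mp
  }
  out <- traits
  out$HY[ti] <- het(traits$PY[ti], perse$PY_perse)
  out$HD[ti] <- het(traits$PD[ti], perse$PD_perse)
  out
}

#' Pearson correlation with t-test
#'
#' Pearson correlation r between two vectors with the exact t-test on
#' n - 2 degrees of freedom: `t = r sqrt(n - 2) / sqrt(1 - r^2)`, two-sided
#' p from the Student t distribution; `r = +/-1` yields p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `t`, `p`, `n`.
#' @export
correlate_trait <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, t = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    return(list(r = sign(r), t = sign(r) * Inf, p = 0, n = n, undefined = FALSE))
  }
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(r = r, t = tt, p = p, n = n, undefined = FALSE)
}

# Row-wise Pearson correlation of a matrix against one vector, with t-test
# p-values; constant rows yield NA and are flagged, never an error.
cor_rows <- function(L, y) {
  n <- length(y)
  Lc <- L - rowMeans(L)
  yc <- y - mean(y)
  denom_y <- sqrt(sum(yc^2))
  denom_L <- sqrt(rowSums(Lc^2))
  r <- as.numeric(Lc %*% yc) / (denom_L * denom_y)
  undefined <- denom_L == 0 | denom_y == 0
  r[undefined] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- as.numeric(ifelse(abs(r) >= 1, 0,
                         2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)))
  data.frame(probe_id = rownames(L) %||% as.character(seq_len(nrow(L))),
             r = as.numeric(r), t = as.numeric(tt), p = p,
             undefined = undefined, stringsAsFactors = FALSE)
}

#' Gene-trait correlation table
#'
#' Correlates every row of the mid-parent matrix with each requested trait,
#' reporting Pearson r, the t statistic on n - 2 df, the raw p and the
#' BH-adjusted q per trait.
#'
#' @param L mid-parent matrix (probes by hybrids).
#' @param traits hybrid trait table; columns named in `which` are used, with
#'   rows matched to `colnames(L)` via `hybrid_id`.
#' @param which trait columns to correlate (default PY, HY, PD, HD).
#' @return long data frame `probe_id, trait, r, t, p, q, undefined` of class
#'   \code{hc_cortab}.
#' @export
correlate_all <- function(L, traits, which = c("PY", "HY", "PD", "HD")) {
  which <- intersect(which, names(traits))
  idx <- match(colnames(L), traits$hybrid_id)
  if (anyNA(idx)) stop("trait table is missing hybrid '",
                       colnames(L)[which(is.na(idx))[1L]], "'")
  out <- lapply(which, function(tr) {
    df <- cor_rows(L, traits[[tr]][idx])
    df$trait <- rep(tr, nrow(df))
    ok <- !df$undefined
    df$q <- rep(NA_real_, nrow(df))
    df$q[ok] <- adjust_fdr(df$p[ok])
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out[, c("probe_id", "trait", "r", "t", "p", "q", "undefined")],
            class = c("hc_cortab", "data.frame"))
}

#' BCa bootstrap confidence interval for a correlation
#'
#' Bias-corrected accelerated bootstrap interval for the Pearson correlation
#' of paired observations: pairs are resampled with replacement `B` times;
#' the bias correction is `z0 = qnorm((#\{r* < r\} + 0.5 #\{r* = r\}) / B)`;
#' the acceleration comes from jackknife skewness
#' `a = sum((rbar - r_i)^3) / (6 [sum((rbar - r_i)^2)]^{3/2})`; the adjusted
#' percentile levels are read off the empirical bootstrap distribution.
#' Deterministic given `seed`.
#'
#' @param x,y paired numeric vectors, length >= 4.
#' @param B number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return numeric vector `c(low, high)`; a degenerate bootstrap (all r*
#'   equal, e.g. exactly collinear data) yields the point interval.
#' @export
bca_ci <- function(x, y, B = 10000L, level = 0.95, seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("vectors must have equal length")
  if (n < 4L) stop("need at least 4 paired observations")
  theta_hat <- cor(x, y)
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  theta_star <- boot_cor(x, y, idx)
  theta_star <- theta_star[is.finite(theta_star)]
  if (!length(theta_star) || max(theta_star) == min(theta_star)) {
    hc_log("BCa: degenerate bootstrap distribution, returning point interval")
    return(c(theta_hat, theta_hat))
  }
  Bn <- length(theta_star)
  prop <- (sum(theta_star < theta_hat) + 0.5 * sum(theta_star == theta_hat)) / Bn
  prop <- min(max(prop, 0.5 / Bn), 1 - 0.5 / Bn)
  z0 <- qnorm(prop)
  # jackknife acceleration
  loo <- loo_cor(x, y)
  dev <- mean(loo) - loo
  denom <- sum(dev^2)^1.5
  a <- if (denom == 0) 0 else sum(dev^3) / (6 * denom)
  zlo <- qnorm((1 - level) / 2)
  zhi <- -zlo
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  alpha <- c(adj(zlo), adj(zhi))
  sorted <- sort(theta_star)
  pick <- pmin(Bn, pmax(1L, ceiling(Bn * alpha)))
  ci <- sorted[pick]
  pmin(1, pmax(-1, ci))
}

# vectorized bootstrap correlations from an index matrix (resamples x n)
boot_cor <- function(x, y, idx) {
  n <- ncol(idx)
  xm <- matrix(x[idx], nrow = nrow(idx))
  ym <- matrix(y[idx], nrow = nrow(idx))
  sx <- rowSums(xm); sy <- rowSums(ym)
  sxx <- rowSums(xm^2); syy <- rowSums(ym^2); sxy <- rowSums(xm * ym)
  num <- sxy - sx * sy / n
  den <- sqrt(pmax(sxx - sx^2 / n, 0) * pmax(syy - sy^2 / n, 0))
  r <- num / den
  r[den == 0] <- NA_real_
  pmin(1, pmax(-1, r))
}

# leave-one-out correlations via downdated sums
loo_cor <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  m <- n - 1
  num <- (sxy - x * y) - (sx - x) * (sy - y) / m
  den <- sqrt(pmax((sxx - x^2) - (sx - x)^2 / m, 0) *
                pmax((syy - y^2) - (sy - y)^2 / m, 0))
  r <- num / den
  r[den == 0] <- 0
  pmin(1, pmax(-1, r))
}

#' Monte Carlo permutation test for a correlation
#'
#' Tests the Pearson correlation of two trait vectors by permuting the second
#' vector `n_perm` times; the two-sided p-value follows the add-one rule
#' `p = (1 + #\{|r*| >= |r|\}) / (n_perm + 1)`, so the smallest attainable p
#' is `1 / (n_perm + 1)`. Deterministic given `seed`.
#'
#' @param y1,y2 numeric vectors of equal length >= 3.
#' @param n_perm number of Monte Carlo permutations (default 9999).
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
trait_permutation_test <- function(y1, y2, n_perm = 9999L, seed = 1L) {
  n <- length(y1)
  if (length(y2) != n) stop("vectors must have equal length")
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(y1) == 0 || sd(y2) == 0) stop("constant vector: correlation undefined")
  r_obs <- cor(y1, y2)
  set.seed(as.integer(seed))
  # under permutation only the cross-product term varies
  y1c <- (y1 - mean(y1)) / (sd(y1) * sqrt(n - 1))
  y2c <- (y2 - mean(y2)) / (sd(y2) * sqrt(n - 1))
  r_perm <- vapply(seq_len(n_perm),
                   function(b) sum(y1c * y2c[sample.int(n)]), numeric(1))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  list(r = r_obs, p = p, n_perm = n_perm)
}
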