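#' Per-line mean expression
#'
#' Averages replicate samples within each parental line.
#'
#' @param expr an \code{hc_expr}.
#' @return matrix of probes by lines (log2 scale).
#' @export
line_means <- function(expr) {
  lines <- unique(expr$samples$line_id)
  out <- vapply(lines, function(l) {
    cols <- expr$samples$sample_id[expr$samples$line_id == l]
    rowMeans(expr$x[, cols, drop = FALSE])
  }, numeric(nrow(expr$x)))
  colnames(out) <- lines
  out
}

#' Spike-in reliability threshold
#'
#' A probe is considered reliably expressed when its intensity exceeds the
#' average of all spike-in control probes plus three times their standard
#' deviation (sample sd, divisor n - 1).
#'
#' @param spikein_values log2 intensities of spike-in probes.
#' @return the threshold, mean + 3 sd, in log2 intensity units.
#' @export
#' @examples
#' reliability_threshold(c(6, 7, 8))  # 7 + 3 * 1 = 10
reliability_threshold <- function(spikein_values) {
  v <- as.numeric(spikein_values)
  if (length(v) < 2L) stop("need at least 2 spike-in values (sd undefined)")
  if (anyNA(v)) stop("spike-in values must not contain NA")
  mean(v) + 3 * sd(v)
}

# Newton inversion of the trigamma function, used for moment-matching the
# variance prior: solves trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

# Moment-matching estimate of the scaled inverse-chi-square prior of gene
# residual variances from log sample variances: E[log s^2] and Var[log s^2]
# identify (d0, s0sq) through digamma/trigamma relations. Falls back to a
# point prior (d0 = Inf, s0sq = geometric-mean variance) when the observed
# spread of log s^2 does not exceed its sampling component.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("variance prior: all residual variances are zero")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  excess <- var(e) - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 0) {
    return(list(d0 = Inf, s0sq = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

#' Empirical-Bayes moderated F-test across parental lines
#'
#' Fits the one-way line-means model per probe, estimates a scaled
#' inverse-chi-square prior (d0, s0sq) for the residual variances by
#' moment-matching of log s^2 (digamma/trigamma inversion), shrinks each
#' residual variance to the posterior value
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}, and refers the
#' moderated statistic F = (between-line mean square) / \eqn{\tilde{s}^2}
#' to F(k - 1, d0 + d). Probes with zero between-line mean square get F = 0.
#'
#' @param x matrix of log2 intensities, probes by samples.
#' @param lines factor or character vector assigning each column to a line;
#'   at least two lines, each with at least two replicates.
#' @param d0_override optional fixed prior df: 0 recovers the ordinary
#'   per-probe F-test, Inf the pooled-common-variance test.
#' @return an object of class \code{hc_modfit}: list with `prior`
#'   (d0, s0sq), `table` (data frame: probe_id, F, p, s2, stilde2), the line
#'   means, per-line replicate counts, residual df `d` and denominator df
#'   `df_total = d0 + d`.
#' @export
moderated_f_test <- function(x, lines, d0_override = NULL) {
  lines <- as.character(lines)
  if (ncol(x) != length(lines)) stop("'lines' must label every column of x")
  tab <- table(lines)
  if (length(tab) < 2L) stop("need at least 2 lines")
  if (any(tab < 2L)) {
    stop("every line needs at least 2 replicates (zero residual df for line '",
         names(tab)[tab < 2][1L], "')")
  }
  k <- length(tab)
  n <- ncol(x)
  d <- n - k

  uline <- names(tab)
  means <- vapply(uline, function(l) rowMeans(x[, lines == l, drop = FALSE]),
                  numeric(nrow(x)))
  reps <- as.numeric(tab[uline])
  grand <- as.numeric(means %*% reps) / n
  msb <- (sweep(means, 1L, grand)^2 %*% reps) / (k - 1)
  msb <- as.numeric(msb)
  # residual SS = total SS - between SS
  ssw <- rowSums(x^2) - as.numeric((means^2) %*% reps)
  s2 <- pmax(ssw, 0) / d

  prior <- if (is.null(d0_override)) {
    fit_variance_prior(s2, d)
  } else {
    if (!is.numeric(d0_override) || d0_override < 0) {
      stop("d0_override must be a non-negative prior df (possibly Inf)")
    }
    s0 <- if (is.finite(d0_override) && d0_override > 0) {
      fit_variance_prior(s2, d)$s0sq
    } else if (!is.finite(d0_override)) {
      mean(s2)   # pooled common variance in the d0 -> Inf limit
    } else {
      0          # d0 = 0: no shrinkage, posterior variance equals s2
    }
    list(d0 = d0_override, s0sq = s0)
  }

  stilde2 <- if (is.finite(prior$d0)) {
    (prior$d0 * prior$s0sq + d * s2) / (prior$d0 + d)
  } else {
    rep(prior$s0sq, length(s2))
  }
  df_total <- prior$d0 + d
  Fstat <- ifelse(msb <= 0, 0, msb / stilde2)
  Fstat[msb > 0 & stilde2 <= 0] <- Inf
  p <- f_pvalue(Fstat, k - 1, df_total)

  structure(list(
    prior = prior,
    table = data.frame(probe_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                       F = Fstat, p = p, s2 = s2, stilde2 = stilde2,
                       stringsAsFactors = FALSE),
    means = means, reps = setNames(reps, uline),
    k = k, d = d, df_total = df_total
  ), class = "hc_modfit")
}

f_pvalue <- function(Fstat, df1, df2) {
  if (is.finite(df2)) {
    pf(Fstat, df1, df2, lower.tail = FALSE)
  } else {
    pchisq(Fstat * df1, df1, lower.tail = FALSE)
  }
}

#' Nested pairwise moderated tests
#'
#' Moderated t-contrast for each requested pair of parental lines, using the
#' same shrunken variance as the overall moderated F-test; the statistic is
#' squared and referred to F(1, d0 + d).
#'
#' @param fit an \code{hc_modfit}.
#' @param pairs two-column matrix or data frame of line ids.
#' @return list with matrices `p` (probes x pairs) and `abs_log2fc`.
#' @export
nested_pairwise_tests <- function(fit, pairs) {
  pairs <- as.matrix(pairs)
  miss <- setdiff(unique(as.vector(pairs)), colnames(fit$means))
  if (length(miss)) stop("line '", miss[1L], "' absent from the fitted matrix")
  nprobe <- nrow(fit$means)
  pm <- matrix(NA_real_, nprobe, nrow(pairs))
  fc <- matrix(NA_real_, nprobe, nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    a <- pairs[j, 1L]; b <- pairs[j, 2L]
    diff <- fit$means[, a] - fit$means[, b]
    se2 <- fit$table$stilde2 * (1 / fit$reps[[a]] + 1 / fit$reps[[b]])
    F1 <- ifelse(diff == 0, 0, diff^2 / se2)
    pm[, j] <- f_pvalue(F1, 1, fit$df_total)
    fc[, j] <- abs(diff)
  }
  rownames(pm) <- rownames(fc) <- fit$table$probe_id
  colnames(pm) <- colnames(fc) <- paste(pairs[, 1L], pairs[, 2L], sep = ":")
  list(p = pm, abs_log2fc = fc)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment; order-preserving and never below
#' the raw p-value.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted q-values of the same length.
#' @export
adjust_fdr <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("p-values must be numeric")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Differential-expression screen
#'
#' Reproduces the full screen on parental-line expression: (1) reliability --
#' a probe's line-mean intensity must exceed the spike-in threshold
#' ([reliability_threshold()]) in at least `min_lines` lines; (2) fold-change
#' prefilter -- the largest difference between line means must exceed
#' `log2(fc_min)`; (3) moderated F-test with BH-adjusted q <= `fdr_de`
#' (spike-in probes are tested alongside gene probes, and the smallest
#' spike-in q is reported as a calibration diagnostic, but spike-ins never
#' enter the DE set); (4) final filter -- fold-change condition and summary
#' log2 intensity above `intensity_min`.
#'
#' @param expr an \code{hc_expr}.
#' @param config an [hc_config()].
#' @return object of class \code{hc_de}: list with `table` (per-probe F, p,
#'   q, max |log2 fc|, mean intensity and pass flags), `threshold`,
#'   `spikein_min_q`, the moderated `fit` restricted to tested probes, and
#'   the config used.
#' @export
select_differential <- function(expr, config = hc_config()) {
  spike <- expr$probes$probe_id[expr$probes$is_spikein == 1]
  genes <- expr$probes$probe_id[expr$probes$is_spikein == 0]
  spike <- intersect(spike, rownames(expr$x))
  genes <- intersect(genes, rownames(expr$x))

  thr <- reliability_threshold(expr$x[spike, , drop = FALSE])
  lm_mat <- line_means(expr)

  maxfc_all <- apply(lm_mat, 1L, function(v) diff(range(v)))
  intensity <- switch(config$intensity_summary,
                      mean = rowMeans(lm_mat),
                      max = apply(lm_mat, 1L, max))
  reliable <- rowSums(lm_mat > thr) >= config$min_lines
  fc_pass <- maxfc_all > log2(config$fc_min)

  test_genes <- if (config$fc_prefilter) {
    genes[reliable[genes] & fc_pass[genes]]
  } else {
    genes[reliable[genes]]
  }
  tested <- c(test_genes, spike)
  if (!length(test_genes)) {
    hc_log("differential screen: no gene probe passed the prefilter")
  }
  fit <- moderated_f_test(expr$x[tested, , drop = FALSE],
                          expr$samples$line_id[match(colnames(expr$x),
                                                     expr$samples$sample_id)])
  q_tested <- adjust_fdr(fit$table$p)
  names(q_tested) <- fit$table$probe_id
  spike_q <- q_tested[spike]
  spikein_min_q <- if (length(spike_q)) min(spike_q) else NA_real_

  tab <- data.frame(
    probe_id = genes,
    F = fit$table$F[match(genes, fit$table$probe_id)],
    p = fit$table$p[match(genes, fit$table$probe_id)],
    q = q_tested[match(genes, names(q_tested))],
    max_abs_log2fc = maxfc_all[genes],
    mean_intensity = intensity[genes],
    reliable = unname(reliable[genes]),
    fc_pass = unname(fc_pass[genes]),
    stringsAsFactors = FALSE
  )
  tab$q_pass <- !is.na(tab$q) & tab$q <= config$fdr_de
  tab$intensity_pass <- tab$mean_intensity > config$intensity_min
  tab$de_pass <- tab$reliable & tab$fc_pass & tab$q_pass & tab$intensity_pass
  rownames(tab) <- NULL

  hc_log("differential screen: threshold %.3f; %d reliable, %d fc-pass, %d DE of %d gene probes",
         thr, sum(tab$reliable), sum(tab$fc_pass), sum(tab$de_pass), nrow(tab))
  structure(list(table = tab, threshold = thr, spikein_min_q = spikein_min_q,
                 fit = fit, config = config), class = "hc_de")
}

#' @export
print.hc_de <- function(x, ...) {
  cat("Differential-expression screen (hc_de)\n")
  cat(sprintf("  reliability threshold: %.3f log2 units\n", x$threshold))
  cat(sprintf("  prior: d0 = %s, s0sq = %.4g\n",
              format(x$fit$prior$d0, digits = 4), x$fit$prior$s0sq))
  cat(sprintf("  gene probes: %d tested, %d DE (q <= %g, fc > %g, intensity > %g)\n",
              sum(!is.na(x$table$q)), sum(x$table$de_pass),
              x$config$fdr_de, x$config$fc_min, x$config$intensity_min))
  if (is.finite(x$spikein_min_q)) {
    cat(sprintf("  most significant spike-in adjusted p: %.3f\n", x$spikein_min_q))
  }
  invisible(x)
}

#' DE probe ids
#' @param de an \code{hc_de}.
#' @return character vector of probes passing all filters.
#' @export
de_probes <- function(de) de$table$probe_id[de$table$de_pass]

#' Per-hybrid differential-expression counts
#'
#' For every hybrid, counts the DE probes whose parental-pair nested
#' moderated test has BH-adjusted q at or below `fdr_de` and whose pairwise
#' fold change exceeds `fc_min`; nested p-values are adjusted across probes
#' within each parental pair.
#'
#' @param de an \code{hc_de}.
#' @param design factorial design data frame.
#' @param config an [hc_config()].
#' @return data frame `hybrid_id, n_de`, with attributes `mean_count` and
#'   `pct_of_probes` (mean count as a percentage of all gene probes).
#' @export
per_hybrid_de_counts <- function(de, design, config = de$config) {
  pairs <- cbind(design$flint_parent, design$dent_parent)
  nest <- nested_pairwise_tests(de$fit, pairs)
  de_set <- de_probes(de)
  idx <- match(de_set, rownames(nest$p))
  counts <- vapply(seq_len(nrow(design)), function(j) {
    qj <- adjust_fdr(nest$p[, j])
    sum(qj[idx] <= config$fdr_de & nest$abs_log2fc[idx, j] > log2(config$fc_min))
  }, numeric(1))
  out <- data.frame(hybrid_id = design$hybrid_id, n_de = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "mean_count") <- mean(counts)
  attr(out, "pct_of_probes") <- 100 * mean(counts) / nrow(de$table)
  hc_log("per-hybrid DE counts: mean %.1f (%.1f%% of %d gene probes)",
         mean(counts), attr(out, "pct_of_probes"), nrow(de$table))
  out
}

#' Percentage helper for count accounting
#'
#' Expresses a subset count as a percentage of a total, rounded to the given
#' number of digits; used for composition summaries such as the share of
#' positively correlated genes in a selection or the mean per-hybrid DE count
#' relative to the array size.
#'
#' @param k subset count.
#' @param n total count.
#' @param digits rounding digits (default 1).
#' @return percentage value.
#' @export
#' @examples
#' proportion_percent(468, 745)  # 62.8
proportion_percent <- function(k, n, digits = 1) {
  if (n <= 0) stop("total must be positive")
  round(100 * k / n, digits)
}
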