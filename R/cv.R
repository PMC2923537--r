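#' Line-resampling cross-validation of gene rankings
#'
#' In each round, 3 of the flint and 5 of the dent parental lines are sampled
#' uniformly without replacement; the estimation set is the hybrids whose two
#' parents were both sampled (15 hybrids under the default 3 x 5 draw), or
#' the complementary hybrids when `config$cv_complement` is TRUE. Trait
#' correlations are recomputed on the estimation set, genes are ranked by
#' smallest p (ties broken by |r| descending, then probe id), and the top-k
#' list is compared with the full-data top-k. Deterministic given `seed`.
#'
#' @param L mid-parent matrix (probes by hybrids); rows are the candidate
#'   genes to rank.
#' @param trait_values numeric trait vector aligned with `colnames(L)`.
#' @param design factorial design (provides each hybrid's parents and the
#'   flint/dent line pools).
#' @param config an [hc_config()]; uses `cv_rounds`, `cv_top`,
#'   `cv_complement`.
#' @param seed integer seed.
#' @param n_flint_sample,n_dent_sample lines sampled per group (defaults 3
#'   and 5).
#' @return object of class \code{hc_cv}: list with `rounds` (per-round
#'   sampled lines, estimation-set size and top-k overlap with the full
#'   data), `frequency` (per-gene selection counts over rounds),
#'   `full_top` (full-data top-k), `mean_overlap`,
#'   `frequency_rank_overlap`, and `k`.
#' @export
run_crossvalidation <- function(L, trait_values, design, config = hc_config(),
                                seed = 1L, n_flint_sample = 3L, n_dent_sample = 5L) {
  k <- config$cv_top
  if (k > nrow(L)) {
    stop("cv_top (", k, ") exceeds the number of candidate genes (", nrow(L), ")")
  }
  flint <- unique(design$flint_parent)
  dent <- unique(design$dent_parent)
  if (n_flint_sample > length(flint) || n_dent_sample > length(dent)) {
    stop("cannot sample more lines than the design provides")
  }
  hyb_idx <- match(design$hybrid_id, colnames(L))
  if (anyNA(hyb_idx)) stop("mid-parent matrix is missing hybrid '",
                           design$hybrid_id[which(is.na(hyb_idx))[1L]], "'")

  rank_top <- function(cols) {
    ct <- cor_rows(L[, cols, drop = FALSE], trait_values[cols])
    ct$p[ct$undefined] <- Inf
    ord <- order(ct$p, -abs(ct$r), ct$probe_id)
    ct$probe_id[ord][seq_len(k)]
  }
  full_top <- rank_top(seq_len(ncol(L)))

  set.seed(as.integer(seed))
  freq <- setNames(integer(nrow(L)), rownames(L))
  rounds <- vector("list", config$cv_rounds)
  top_lists <- vector("list", config$cv_rounds)
  for (b in seq_len(config$cv_rounds)) {
    sf <- sample(flint, n_flint_sample)
    sd_ <- sample(dent, n_dent_sample)
    in_est <- design$flint_parent %in% sf & design$dent_parent %in% sd_
    if (config$cv_complement) in_est <- !in_est
    cols <- hyb_idx[in_est]
    top_b <- rank_top(cols)
    top_lists[[b]] <- top_b
    freq[top_b] <- freq[top_b] + 1L
    rounds[[b]] <- data.frame(
      round = b,
      flint_lines = paste(sort(sf), collapse = ","),
      dent_lines = paste(sort(sd_), collapse = ","),
      n_hybrids = length(cols),
      overlap = length(intersect(top_b, full_top)),
      stringsAsFactors = FALSE
    )
  }
  rounds <- do.call(rbind, rounds)
  freq_rank <- names(freq)[order(-freq, names(freq))]  # ties broken by probe id
  freq_top <- freq_rank[seq_len(k)]

  out <- list(rounds = rounds,
              top_lists = top_lists,
              frequency = data.frame(probe_id = names(freq),
                                     n_selected = as.integer(freq),
                                     stringsAsFactors = FALSE),
              full_top = full_top,
              mean_overlap = mean(rounds$overlap),
              frequency_rank_overlap = length(intersect(freq_top, full_top)),
              k = k, n_rounds = config$cv_rounds)
  hc_log("cross-validation: mean top-%d overlap %.1f over %d rounds; frequency-rank overlap %d",
         k, out$mean_overlap, config$cv_rounds, out$frequency_rank_overlap)
  structure(out, class = "hc_cv")
}

#' @export
print.hc_cv <- function(x, ...) {
  cat("Line-resampling cross-validation (hc_cv)\n")
  cat(sprintf("  %d rounds, top-%d ranking\n", x$n_rounds, x$k))
  cat(sprintf("  mean overlap with full-data top-%d: %.1f\n", x$k, x$mean_overlap))
  cat(sprintf("  frequency-ranked top-%d overlap:    %d\n", x$k,
              x$frequency_rank_overlap))
  invisible(x)
}

#' Overlap metrics of a cross-validation run
#'
#' Both stability summaries: the mean over rounds of the overlap between the
#' round's top-k list and the full-data top-k, and the overlap between the
#' selection-frequency-ranked top-k and the full-data top-k.
#'
#' @param cv an \code{hc_cv}.
#' @return list `mean_overlap`, `frequency_rank_overlap`, `k`.
#' @export
overlap_metrics <- function(cv) {
  list(mean_overlap = cv$mean_overlap,
       frequency_rank_overlap = cv$frequency_rank_overlap,
       k = cv$k)
}
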