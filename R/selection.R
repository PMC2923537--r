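#' Two-step correlation selection of trait-associated genes
#'
#' Step 1 assigns to the set every gene whose mid-parent expression is highly
#' significantly correlated with the trait (for grain yield: hybrid
#' performance PY or mid-parent heterosis HY at `alpha_step1`; for grain dry
#' matter content: PD only). Step 2 then iterates over the candidate pool of
#' genes significant at the looser `alpha_step2`, adding any candidate whose
#' mid-parent profile is co-expressed (signed Pearson r above `r_coexpr`)
#' with a gene already in the set; the update is synchronous -- a candidate
#' is certified only against the set as of the end of the previous iteration
#' -- and repeats until a fixpoint, so the result does not depend on
#' candidate order.
#'
#' @param correlations an \code{hc_cortab} from [correlate_all()] covering
#'   all candidate probes.
#' @param L mid-parent matrix (or line-mean matrix when
#'   `config$coexpr_profile == "line"`) with rows covering the candidates.
#' @param trait `"yield"` (gates on PY and HY) or `"gdmc"` (gates on PD).
#' @param config an [hc_config()]; uses `alpha_step1`, `alpha_step2`,
#'   `r_coexpr`, `threshold_on`, `coexpr_signed`.
#' @return object of class \code{hc_selection}: list with `trait`, `members`
#'   (probe_id, step, iteration, r, p, sign, certifier, r_to_certifier),
#'   `n_iterations`, `thresholds`.
#' @export
select_trait_genes <- function(correlations, L, trait = c("yield", "gdmc"),
                               config = hc_config()) {
  trait <- match.arg(trait)
  trait_cols <- if (trait == "yield") c("PY", "HY") else "PD"
  trait_cols <- intersect(trait_cols, unique(correlations$trait))
  if (!length(trait_cols) && nrow(correlations)) {
    stop("no correlation records for trait '", trait, "'")
  }
  cors <- correlations[correlations$trait %in% trait_cols &
                         !correlations$undefined, , drop = FALSE]
  pcol <- if (config$threshold_on == "fdr") "q" else "p"

  # per probe: smallest gate p across the relevant traits, and the
  # correlation with largest |r| (which fixes the reported sign)
  sp <- split(seq_len(nrow(cors)), cors$probe_id)
  probe_ids <- names(sp)
  best_p <- vapply(sp, function(i) min(cors[[pcol]][i]), numeric(1))
  best_r <- vapply(sp, function(i) {
    r <- cors$r[i]; r[which.max(abs(r))]
  }, numeric(1))
  raw_p_of_best <- vapply(sp, function(i) {
    r <- cors$r[i]; cors$p[i][which.max(abs(r))]
  }, numeric(1))

  step1 <- probe_ids[best_p < config$alpha_step1]
  pool <- setdiff(probe_ids[best_p < config$alpha_step2], step1)
  pool <- intersect(pool, rownames(L))
  step1 <- intersect(step1, rownames(L))

  members <- data.frame(
    probe_id = step1,
    step = rep(1L, length(step1)),
    iteration = rep(0L, length(step1)),
    r = unname(best_r[step1]), p = unname(best_p[step1]),
    sign = as.character(ifelse(best_r[step1] > 0, "P", "N")),
    certifier = rep(NA_character_, length(step1)),
    r_to_certifier = rep(NA_real_, length(step1)),
    stringsAsFactors = FALSE
  )

  coexpr <- function(cand, memb) {
    # candidates x members correlation of expression profiles
    cc <- suppressWarnings(cor(t(L[cand, , drop = FALSE]),
                               t(L[memb, , drop = FALSE])))
    cc[!is.finite(cc)] <- -Inf
    if (!config$coexpr_signed) cc <- abs(cc)
    cc
  }

  iter <- 0L
  best_link_r <- rep(-Inf, length(pool))
  best_link_id <- rep(NA_character_, length(pool))
  names(best_link_r) <- names(best_link_id) <- pool
  new_members <- step1
  current <- step1
  while (length(new_members) && length(pool)) {
    cc <- coexpr(pool, new_members)
    jmax <- max.col(cc, ties.method = "first")
    rmax <- cc[cbind(seq_along(pool), jmax)]
    upd <- rmax > best_link_r[pool]
    best_link_r[pool][upd] <- rmax[upd]
    best_link_id[pool][upd] <- new_members[jmax[upd]]
    iter <- iter + 1L
    added <- pool[best_link_r[pool] > config$r_coexpr]
    if (length(added)) {
      members <- rbind(members, data.frame(
        probe_id = added, step = 2L, iteration = iter,
        r = best_r[added], p = best_p[added],
        sign = ifelse(best_r[added] > 0, "P", "N"),
        certifier = unname(best_link_id[added]),
        r_to_certifier = unname(best_link_r[added]),
        stringsAsFactors = FALSE
      ))
      current <- c(current, added)
      pool <- setdiff(pool, added)
    }
    new_members <- added
  }

  rownames(members) <- NULL
  hc_log("two-step selection (%s): %d step-1 + %d step-2 members in %d iteration(s)",
         trait, sum(members$step == 1L), sum(members$step == 2L), iter)
  structure(list(trait = trait, members = members, n_iterations = iter,
                 thresholds = list(alpha_step1 = config$alpha_step1,
                                   alpha_step2 = config$alpha_step2,
                                   r_coexpr = config$r_coexpr,
                                   threshold_on = config$threshold_on)),
            class = "hc_selection")
}

#' @export
print.hc_selection <- function(x, ...) {
  cat(sprintf("Two-step selection for %s (hc_selection)\n", x$trait))
  cat(sprintf("  step 1 (p < %g): %d genes\n", x$thresholds$alpha_step1,
              sum(x$members$step == 1L)))
  cat(sprintf("  step 2 (p < %g, co-expression r > %g): %d genes in %d iteration(s)\n",
              x$thresholds$alpha_step2, x$thresholds$r_coexpr,
              sum(x$members$step == 2L), x$n_iterations))
  cat(sprintf("  total: %d genes (%d positive, %d negative)\n",
              nrow(x$members), sum(x$members$sign == "P"),
              sum(x$members$sign == "N")))
  invisible(x)
}

#' @export
summary.hc_selection <- function(object, ...) {
  m <- object$members
  out <- list(trait = object$trait,
              n_total = nrow(m),
              n_step1 = sum(m$step == 1L),
              n_step2 = sum(m$step == 2L),
              n_positive = sum(m$sign == "P"),
              n_negative = sum(m$sign == "N"),
              pct_positive = if (nrow(m)) proportion_percent(sum(m$sign == "P"), nrow(m)) else NA_real_,
              n_iterations = object$n_iterations)
  class(out) <- "summary.hc_selection"
  out
}

#' @export
print.summary.hc_selection <- function(x, ...) {
  cat(sprintf("%s: %d genes = %d (step 1) + %d (step 2); %d positive (%.1f%%), %d negative\n",
              x$trait, x$n_total, x$n_step1, x$n_step2, x$n_positive,
              x$pct_positive, x$n_negative))
  invisible(x)
}

#' Verify the two-step fixpoint
#'
#' Exhaustively checks that no probe outside the selected set satisfies both
#' gates (trait significance at `alpha_step2` and co-expression above
#' `r_coexpr` with any member).
#'
#' @inheritParams select_trait_genes
#' @param selection an \code{hc_selection}.
#' @return TRUE if the set is a fixpoint, otherwise FALSE.
#' @export
verify_fixpoint <- function(selection, correlations, L, config = hc_config()) {
  trait_cols <- if (selection$trait == "yield") c("PY", "HY") else "PD"
  cors <- correlations[correlations$trait %in% trait_cols &
                         !correlations$undefined, , drop = FALSE]
  pcol <- if (config$threshold_on == "fdr") "q" else "p"
  sp <- split(cors[[pcol]], cors$probe_id)
  best_p <- vapply(sp, min, numeric(1))
  outside <- setdiff(names(best_p)[best_p < config$alpha_step2],
                     selection$members$probe_id)
  outside <- intersect(outside, rownames(L))
  if (!length(outside) || !nrow(selection$members)) return(TRUE)
  cc <- suppressWarnings(cor(t(L[outside, , drop = FALSE]),
                             t(L[selection$members$probe_id, , drop = FALSE])))
  cc[!is.finite(cc)] <- -Inf
  if (!config$coexpr_signed) cc <- abs(cc)
  !any(cc > config$r_coexpr)
}

#' Trait-interaction gene set
#'
#' Intersects the yield and grain dry matter content selections, flags genes
#' whose correlation signs differ between the traits (the interaction
#' criterion), and tallies the step provenance of the overlap.
#'
#' @param sel_yield,sel_gdmc \code{hc_selection} objects for the two traits.
#' @return object of class \code{hc_interaction}: data frame
#'   `probe_id, sign_yield, sign_gdmc, opposite_sign, step_yield, step_gdmc`
#'   with attribute `summary` (n_overlap, n_opposite, n_step1_both,
#'   n_step2_any).
#' @export
interaction_genes <- function(sel_yield, sel_gdmc) {
  y <- sel_yield$members; d <- sel_gdmc$members
  common <- intersect(y$probe_id, d$probe_id)
  yi <- match(common, y$probe_id); di <- match(common, d$probe_id)
  out <- data.frame(
    probe_id = common,
    sign_yield = y$sign[yi],
    sign_gdmc = d$sign[di],
    opposite_sign = y$sign[yi] != d$sign[di],
    step_yield = y$step[yi],
    step_gdmc = d$step[di],
    stringsAsFactors = FALSE
  )
  summ <- list(
    n_overlap = nrow(out),
    n_opposite = sum(out$opposite_sign),
    n_step1_both = sum(out$step_yield == 1L & out$step_gdmc == 1L),
    n_step2_any = sum(out$step_yield == 2L | out$step_gdmc == 2L)
  )
  attr(out, "summary") <- summ
  class(out) <- c("hc_interaction", "data.frame")
  out
}

#' @export
print.hc_interaction <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Trait-interaction genes (hc_interaction)\n")
  cat(sprintf("  overlap: %d genes; opposite sign: %d\n", s$n_overlap, s$n_opposite))
  cat(sprintf("  step 1 in both selections: %d; entering via step 2: %d\n",
              s$n_step1_both, s$n_step2_any))
  invisible(x)
}
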