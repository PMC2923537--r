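#' Run the full analysis pipeline
#'
#' Orchestrates one reproducible end-to-end run: synthetic-data generation
#' (or user-supplied inputs), the differential-expression screen, mid-parent
#' and heterosis computation, gene-trait correlation (with BCa confidence
#' intervals for the configured probe set), the trait-trait permutation test,
#' two-step selection for both traits, the interaction set, cross-validation
#' of the yield ranking, and category enrichment. Every stage writes a
#' tab-separated output under `outdir` and is seeded from a documented
#' per-stage substream (`seed * 1000 + stage`), so a rerun with the same
#' configuration and seed reproduces all outputs bit-identically.
#'
#' @param config an [hc_config()].
#' @param gen_config a [generator_config()], used when `inputs` is NULL.
#' @param outdir output directory (created if missing).
#' @param seed integer run seed.
#' @param inputs optional named list of file paths
#'   (`matrix, samples, probes, design, traits, perse, gmt`) to analyse
#'   user-supplied data instead of a synthetic study.
#' @param run_cv run the cross-validation stage (skipped when the candidate
#'   pool is smaller than `config$cv_top`).
#' @return object of class \code{hc_run}: the manifest, plus the in-memory
#'   stage results (`de`, `correlations`, `sel_yield`, `sel_gdmc`,
#'   `interaction`, `cv`, `enrichment`).
#' @export
run_all <- function(config = hc_config(), gen_config = generator_config(),
                    outdir, seed = 1L, inputs = NULL, run_cv = TRUE) {
  if (missing(outdir)) stop("outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  outputs <- character(0)
  tick <- function(name, files) {
    stages[[name]] <<- list(elapsed = round(proc.time()[["elapsed"]] - t0, 2))
    outputs <<- c(outputs, files)
  }
  pth <- function(...) file.path(outdir, ...)

  # stage 1: inputs -------------------------------------------------------
  if (is.null(inputs)) {
    sim <- generate_dataset(gen_config, seed = stage_seed(seed, 1L))
    expr <- sim$expr; design <- sim$design; traits <- sim$traits
    perse <- sim$perse
    categories <- synthetic_categories(sim, seed = stage_seed(seed, 11L))
    write_expression(expr, pth("expression.tsv"), pth("samples.tsv"), pth("probes.tsv"))
    write_design(design, pth("design.tsv"))
    write_traits(traits, pth("traits.tsv"))
    write_perse(perse, pth("line_perse.tsv"))
    write_truth(sim$truth, pth("truth.tsv"))
    write_gmt(categories, pth("categories.gmt"))
    tick("simulate", c("expression.tsv", "samples.tsv", "probes.tsv",
                       "design.tsv", "traits.tsv", "line_perse.tsv",
                       "truth.tsv", "categories.gmt"))
  } else {
    expr <- read_expression(inputs$matrix, inputs$samples, inputs$probes)
    design <- read_design(inputs$design)
    traits <- read_traits(inputs$traits)
    perse <- if (!is.null(inputs$perse)) read_perse(inputs$perse) else NULL
    categories <- if (!is.null(inputs$gmt)) read_gmt(inputs$gmt) else NULL
    sim <- NULL
    tick("load", character(0))
  }

  # stage 2: differential expression --------------------------------------
  de <- select_differential(expr, config)
  write_tsv(de$table, pth("de_results.tsv"))
  de_counts <- per_hybrid_de_counts(de, design, config)
  write_tsv(de_counts, pth("de_per_hybrid.tsv"))
  tick("de_filter", c("de_results.tsv", "de_per_hybrid.tsv"))

  # stage 3: mid-parent expression and trait correlations ------------------
  lm_mat <- line_means(expr)
  L <- compute_midparent(lm_mat, design)
  if (!is.null(perse) && (!all(c("HY", "HD") %in% names(traits)) ||
                          anyNA(traits$HY))) {
    traits <- compute_heterosis(traits, perse, design,
                                scale = config$heterosis_scale)
  }
  cand <- if (config$correlate_probes == "de") de_probes(de) else {
    de$table$probe_id[de$table$reliable]
  }
  if (!length(cand)) {
    hc_log("pipeline: empty candidate set; downstream selections will be empty")
  }
  Lc <- L[cand, , drop = FALSE]
  cors <- correlate_all(Lc, traits)
  write_tsv(cors, pth("correlations.tsv"))
  perm <- trait_permutation_test(traits$PY, traits$PD, n_perm = config$n_perm,
                                 seed = stage_seed(seed, 3L))
  tick("correlate", "correlations.tsv")

  # stage 4: two-step selection and interaction ---------------------------
  coexpr_mat <- if (config$coexpr_profile == "line") {
    lm_mat[cand, , drop = FALSE]
  } else {
    Lc
  }
  sel_yield <- select_trait_genes(cors, coexpr_mat, "yield", config)
  sel_gdmc <- select_trait_genes(cors, coexpr_mat, "gdmc", config)
  inter <- interaction_genes(sel_yield, sel_gdmc)
  if (config$ci_for != "none") {
    ci_ids <- if (config$ci_for == "all") cand else {
      union(sel_yield$members$probe_id, sel_gdmc$members$probe_id)
    }
    idx <- match(colnames(L), traits$hybrid_id)
    add_ci <- function(sel, trait_col) {
      m <- sel$members
      if (!nrow(m)) { m$ci_low <- numeric(0); m$ci_high <- numeric(0); sel$members <- m; return(sel) }
      keep <- m$probe_id %in% ci_ids
      ci <- t(vapply(seq_len(nrow(m)), function(i) {
        if (!keep[i]) return(c(NA_real_, NA_real_))
        bca_ci(Lc[m$probe_id[i], ], traits[[trait_col]][idx],
               B = config$n_boot, seed = stage_seed(seed, 4L))
      }, numeric(2)))
      m$ci_low <- ci[, 1L]; m$ci_high <- ci[, 2L]
      sel$members <- m
      sel
    }
    sel_yield <- add_ci(sel_yield, "PY")
    sel_gdmc <- add_ci(sel_gdmc, "PD")
  }
  write_tsv(sel_yield$members, pth("selection_yield.tsv"))
  write_tsv(sel_gdmc$members, pth("selection_gdmc.tsv"))
  write_tsv(as.data.frame(inter), pth("interaction.tsv"))
  tick("select", c("selection_yield.tsv", "selection_gdmc.tsv", "interaction.tsv"))

  # stage 5: cross-validation ---------------------------------------------
  cv <- NULL
  if (run_cv && length(cand) >= config$cv_top) {
    idx <- match(colnames(L), traits$hybrid_id)
    py <- setNames(traits$PY[idx], colnames(L))
    cv <- run_crossvalidation(Lc, py, design, config,
                              seed = stage_seed(seed, 5L))
    write_tsv(cv$rounds, pth("cv_rounds.tsv"))
    write_tsv(cv$frequency, pth("cv_frequency.tsv"))
    tick("crossval", c("cv_rounds.tsv", "cv_frequency.tsv"))
  } else if (run_cv) {
    hc_log("pipeline: cross-validation skipped (fewer than cv_top candidates)")
  }

  # stage 6: enrichment ----------------------------------------------------
  enr <- NULL
  if (!is.null(categories) && nrow(sel_yield$members)) {
    enr <- enrich_categories(categories, background = cand,
                             query = sel_yield$members$probe_id)
    write_tsv(as.data.frame(enr), pth("enrichment_yield.tsv"))
    tick("enrich", "enrichment_yield.tsv")
  }

  manifest <- list(
    seed = as.integer(seed),
    config = unclass(config),
    generator = if (is.null(inputs)) unclass(gen_config) else NULL,
    stages = stages,
    counts = list(
      n_probes = nrow(expr$x), n_samples = ncol(expr$x),
      n_hybrids = nrow(design),
      n_de = sum(de$table$de_pass),
      mean_de_per_hybrid = attr(de_counts, "mean_count"),
      n_yield = nrow(sel_yield$members),
      n_gdmc = nrow(sel_gdmc$members),
      n_interaction = attr(inter, "summary")$n_overlap,
      r_py_pd = unname(perm$r),
      p_py_pd = unname(perm$p)
    ),
    outputs = as.list(setNames(unname(tools::md5sum(file.path(outdir, outputs))),
                               outputs))
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  res <- list(manifest = manifest, outdir = outdir, sim = sim, de = de,
              correlations = cors, sel_yield = sel_yield, sel_gdmc = sel_gdmc,
              interaction = inter, cv = cv, enrichment = enr,
              permutation = perm)
  structure(res, class = "hc_run")
}

#' @export
print.hc_run <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline run (hc_run)\n")
  cat(sprintf("  seed %d; %d stage(s); outputs in %s\n", m$seed,
              length(m$stages), x$outdir))
  cat(sprintf("  DE probes: %d; yield set: %d; GDMC set: %d; interaction: %d\n",
              m$counts$n_de, m$counts$n_yield, m$counts$n_gdmc,
              m$counts$n_interaction))
  cat(sprintf("  r(PY, PD) = %.3f (permutation p = %.4g)\n",
              m$counts$r_py_pd, m$counts$p_py_pd))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV mean top-%d overlap: %.1f\n", x$cv$k, x$cv$mean_overlap))
  }
  invisible(x)
}
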