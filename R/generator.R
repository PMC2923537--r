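#' Synthetic-study generator configuration
#'
#' Parameters of the seeded generator that emulates a factorial maize
#' transcriptome-phenotype study: two heterotic groups (7 flint and 14 dent
#' inbred lines, hence 98 hybrids), probe-level log2 intensities with
#' spike-in control probes, gene-wise residual variances drawn from a scaled
#' inverse-chi-square prior, co-expression modules driven by latent per-line
#' factors, and hybrid traits (grain yield PY in Mg/ha, grain dry matter
#' content PD in percent) constructed from the mid-parent expression of
#' designated causal genes.
#'
#' @param n_flint,n_dent number of inbred lines per heterotic group.
#' @param n_probes number of gene-oriented probes.
#' @param n_spikein number of spike-in control probes (no line effects).
#' @param n_replicates biological replicates per line.
#' @param frac_variable fraction of gene probes with nonzero line effects,
#'   in `[0, 1)`; 0 disables all line effects (and hence modules and causal
#'   genes).
#' @param n_modules,module_size co-expression module layout; module members
#'   share a latent per-line factor strong enough that their mid-parent
#'   profiles correlate above 0.9 in expectation.
#' @param n_causal_yield,n_causal_gdmc,n_causal_shared causal gene counts;
#'   shared genes influence both traits with opposite signs and must not
#'   exceed either trait total.
#' @param causal_corr_target target population correlation (rho) between a
#'   causal gene's mid-parent expression and its trait, in (0, 1).
#' @param trait_coupling coupling coefficient kappa: PD loads with
#'   `-trait_coupling` on the shared latent trait component, producing a
#'   negative r(PY, PD). Set it with [calibrate_trait_coupling()].
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution of
#'   ordinary gene probes.
#' @param module_mean,module_sd baseline intensity distribution of module
#'   (and hence causal) genes; drawn from the clearly expressed regime so the
#'   trait signal is not censored by the reliability and intensity filters.
#' @param spikein_mean,spikein_sd intensity distribution of spike-in probes.
#' @param effect_sd standard deviation of line effects for variable genes
#'   outside modules.
#' @param causal_share,comember_share fraction of a module gene's latent
#'   variance carried by the trait driver, for causal members and ordinary
#'   co-members respectively (co-members sit deliberately nearer the step-1
#'   significance boundary).
#' @param module_noise_sd per-gene, per-line noise added to module loadings.
#' @param d0_true,s0sq_true parameters of the scaled inverse-chi-square prior
#'   of gene residual variances: sigma_g^2 = d0 * s0sq / chi2(d0).
#' @param py_mean,py_sd,pd_mean,pd_sd trait location/scale (Mg/ha; percent).
#' @param perse_py_mean,perse_py_sd,perse_pd_mean,perse_pd_sd distribution of
#'   parental per-se trait values used to derive mid-parent heterosis.
#' @param seed default integer seed of [generate_dataset()].
#'
#' @return a validated list of class \code{hc_gencfg}.
#' @export
generator_config <- function(n_flint = 7L, n_dent = 14L,
                             n_probes = 5000L, n_spikein = 100L,
                             n_replicates = 3L,
                             frac_variable = 0.3,
                             n_modules = 10L, module_size = 15L,
                             n_causal_yield = 40L, n_causal_gdmc = 30L,
                             n_causal_shared = 10L,
                             causal_corr_target = 0.6,
                             trait_coupling = 0.6,
                             baseline_mean = 9.0, baseline_sd = 1.5,
                             module_mean = 10.5, module_sd = 0.75,
                             spikein_mean = 5.0, spikein_sd = 0.5,
                             effect_sd = 0.5,
                             causal_share = 0.8, comember_share = 0.45,
                             module_noise_sd = 0.1,
                             d0_true = 4.0, s0sq_true = 0.05,
                             py_mean = 10.0, py_sd = 1.0,
                             pd_mean = 80.0, pd_sd = 2.0,
                             perse_py_mean = 5.0, perse_py_sd = 0.5,
                             perse_pd_mean = 79.0, perse_pd_sd = 1.0,
                             seed = 1L) {
  cfg <- as.list(environment())
  validate_generator_config(cfg)
  structure(cfg, class = "hc_gencfg")
}

validate_generator_config <- function(cfg) {
  pos_count <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 || v != round(v)) {
      stop(sprintf("generator field '%s' must be a positive integer", key))
    }
  }
  nonneg_count <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
      stop(sprintf("generator field '%s' must be a non-negative integer", key))
    }
  }
  for (k in c("n_flint", "n_dent", "n_probes", "n_spikein", "n_replicates",
              "n_modules", "module_size")) pos_count(k)
  for (k in c("n_causal_yield", "n_causal_gdmc", "n_causal_shared")) nonneg_count(k)
  if (cfg$n_replicates < 2) {
    stop("generator field 'n_replicates' must be >= 2 (residual df needed)")
  }
  if (cfg$n_causal_shared > min(cfg$n_causal_yield, cfg$n_causal_gdmc)) {
    stop("generator field 'n_causal_shared' exceeds min(n_causal_yield, n_causal_gdmc)")
  }
  if (!is.numeric(cfg$frac_variable) || cfg$frac_variable < 0 || cfg$frac_variable >= 1) {
    stop("generator field 'frac_variable' must lie in [0, 1)")
  }
  rho <- cfg$causal_corr_target
  if (!is.numeric(rho) || rho <= 0 || rho >= 1) {
    stop("generator field 'causal_corr_target' must lie in (0, 1)")
  }
  for (k in c("baseline_sd", "module_sd", "spikein_sd", "effect_sd",
              "py_sd", "pd_sd", "perse_py_sd", "perse_pd_sd",
              "d0_true", "s0sq_true")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop(sprintf("generator field '%s' must be positive", k))
    }
  }
  for (k in c("causal_share", "comember_share")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] > 1) {
      stop(sprintf("generator field '%s' must lie in (0, 1]", k))
    }
  }
  if (!is.numeric(cfg$module_noise_sd) || cfg$module_noise_sd < 0) {
    stop("generator field 'module_noise_sd' must be non-negative")
  }
  if (!is.numeric(cfg$trait_coupling) || !is.finite(cfg$trait_coupling)) {
    stop("generator field 'trait_coupling' must be finite")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed)) {
    stop("generator field 'seed' must be a finite number")
  }
  invisible(cfg)
}

# Module layout: causal genes occupy up to ceiling(2/3 * module_size) slots of
# a module so that every causal module retains ordinary co-members.
plan_modules <- function(cfg) {
  cpm <- ceiling(2 * cfg$module_size / 3)
  y_only <- cfg$n_causal_yield - cfg$n_causal_shared
  d_only <- cfg$n_causal_gdmc - cfg$n_causal_shared
  shared <- cfg$n_causal_shared
  need <- function(n) if (n > 0) ceiling(n / cpm) else 0L
  m_y <- need(y_only); m_d <- need(d_only); m_s <- need(shared)
  if (m_y + m_d + m_s > cfg$n_modules) {
    stop("generator field 'n_modules' too small for the requested causal gene counts")
  }
  roles <- c(rep("yield", m_y), rep("gdmc", m_d), rep("shared", m_s),
             rep("null", cfg$n_modules - m_y - m_d - m_s))
  counts <- integer(cfg$n_modules)
  alloc <- function(counts, total, role) {
    idx <- which(roles == role)
    for (m in idx) {
      take <- min(cpm, total)
      counts[m] <- take
      total <- total - take
    }
    counts
  }
  counts <- alloc(counts, y_only, "yield")
  counts <- alloc(counts, d_only, "gdmc")
  counts <- alloc(counts, shared, "shared")
  list(roles = roles, n_causal = counts, cpm = cpm)
}

#' Generate a complete synthetic study
#'
#' Draws one seeded realization of the factorial study: a probe-by-sample
#' log2 expression matrix with sample and probe annotation, the full
#' flint-by-dent crossing design, a hybrid trait table (PY, PD, and
#' mid-parent heterosis HY, HD derived from emitted per-se line values), and
#' a ground-truth record of causal genes, module membership, true residual
#' variances and the realized r(PY, PD).
#'
#' Traits are linear combinations of the standardized mid-parent expression
#' of the causal genes plus Gaussian noise scaled so that each causal gene's
#' population correlation with its trait matches `causal_corr_target`; PD
#' additionally loads with `-trait_coupling` on the shared latent component,
#' which induces the negative PY-PD coupling.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; defaults to `config$seed`. Identical
#'   config + seed give bit-identical output.
#' @return an object of class \code{hc_sim}: a list with elements
#'   \code{expr} (class \code{hc_expr}), \code{design}, \code{traits},
#'   \code{perse}, \code{truth}, \code{config} and \code{seed}.
#' @export
#' @examples
#' sim <- generate_dataset(generator_config(n_probes = 200, n_spikein = 10,
#'                                          n_modules = 6, module_size = 8,
#'                                          n_causal_yield = 8, n_causal_gdmc = 6,
#'                                          n_causal_shared = 3), seed = 1)
#' dim(sim$expr$x)
#' nrow(sim$design)
generate_dataset <- function(config = generator_config(), seed = config$seed) {
  validate_generator_config(config)
  cfg <- config
  set.seed(as.integer(seed))

  flint <- sprintf("F%02d", seq_len(cfg$n_flint))
  dent <- sprintf("D%02d", seq_len(cfg$n_dent))
  lines <- c(flint, dent)
  n_lines <- length(lines)
  groups <- c(rep("flint", cfg$n_flint), rep("dent", cfg$n_dent))

  samples <- data.frame(
    sample_id = paste0(rep(lines, each = cfg$n_replicates), "_r",
                       rep(seq_len(cfg$n_replicates), times = n_lines)),
    line_id = rep(lines, each = cfg$n_replicates),
    group = rep(groups, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = n_lines),
    stringsAsFactors = FALSE
  )

  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_probes))
  spike_ids <- sprintf("spike%03d", seq_len(cfg$n_spikein))
  probe_ids <- c(gene_ids, spike_ids)
  probes <- data.frame(
    probe_id = probe_ids,
    is_spikein = c(rep(0L, cfg$n_probes), rep(1L, cfg$n_spikein)),
    stringsAsFactors = FALSE
  )

  # --- line effects -------------------------------------------------------
  n_var <- round(cfg$frac_variable * cfg$n_probes)
  plan <- plan_modules(cfg)
  need_mod <- cfg$n_modules * cfg$module_size
  has_modules <- n_var > 0
  if (has_modules && n_var < need_mod) {
    stop("generator field 'frac_variable' too small to host ",
         need_mod, " module genes among ", n_var, " variable probes")
  }

  beta <- matrix(0, nrow = cfg$n_probes, ncol = n_lines)
  module_df <- data.frame(probe_id = character(), module_id = integer(),
                          role = character(), module_sign = integer(),
                          stringsAsFactors = FALSE)
  module_roles <- plan$roles

  if (n_var > 0) {
    var_idx <- sample.int(cfg$n_probes, n_var)
    mod_idx <- if (has_modules) var_idx[seq_len(need_mod)] else integer(0)
    free_idx <- setdiff(var_idx, mod_idx)

    if (has_modules) {
      w <- list(yield = rnorm(n_lines), gdmc = rnorm(n_lines),
                shared = rnorm(n_lines))
      rows <- vector("list", cfg$n_modules)
      for (m in seq_len(cfg$n_modules)) {
        members <- mod_idx[((m - 1) * cfg$module_size + 1):(m * cfg$module_size)]
        role <- module_roles[m]
        sgn <- sample(c(-1L, 1L), 1L)
        xi <- rnorm(n_lines)
        n_causal <- plan$n_causal[m]
        is_causal <- c(rep(TRUE, n_causal),
                       rep(FALSE, cfg$module_size - n_causal))
        for (j in seq_along(members)) {
          g <- members[j]
          b <- if (role == "null") 0 else if (is_causal[j]) cfg$causal_share else cfg$comember_share
          u <- if (role == "null") xi else sqrt(b) * w[[role]] + sqrt(1 - b) * xi
          sc <- runif(1, 0.8, 1.2)
          beta[g, ] <- sgn * sc * (u + rnorm(n_lines, 0, cfg$module_noise_sd))
        }
        rows[[m]] <- data.frame(
          probe_id = gene_ids[members],
          module_id = m,
          role = ifelse(is_causal & role != "null", "causal", "comember"),
          module_sign = sgn,
          stringsAsFactors = FALSE
        )
      }
      module_df <- do.call(rbind, rows)
    }
    if (length(free_idx)) {
      beta[free_idx, ] <- matrix(rnorm(length(free_idx) * n_lines, 0, cfg$effect_sd),
                                 nrow = length(free_idx))
    }
  }

  # --- intensities --------------------------------------------------------
  mu <- rnorm(cfg$n_probes, cfg$baseline_mean, cfg$baseline_sd)
  if (nrow(module_df)) {
    mod_rows <- match(module_df$probe_id, gene_ids)
    mu[mod_rows] <- rnorm(length(mod_rows), cfg$module_mean, cfg$module_sd)
  }
  mu_all <- c(mu, rnorm(cfg$n_spikein, cfg$spikein_mean, cfg$spikein_sd))
  sigma2 <- cfg$d0_true * cfg$s0sq_true / rchisq(length(probe_ids), df = cfg$d0_true)

  beta_all <- rbind(beta, matrix(0, nrow = cfg$n_spikein, ncol = n_lines))
  line_of_sample <- match(samples$line_id, lines)
  n_samp <- nrow(samples)
  x <- mu_all + beta_all[, line_of_sample] +
    matrix(rnorm(length(probe_ids) * n_samp, 0, sqrt(sigma2)), ncol = n_samp)
  dimnames(x) <- list(probe_ids, samples$sample_id)

  expr <- new_expression(x, samples, probes)

  # --- design and traits --------------------------------------------------
  design <- data.frame(
    hybrid_id = paste0(rep(flint, each = cfg$n_dent), "x", rep(dent, times = cfg$n_flint)),
    flint_parent = rep(flint, each = cfg$n_dent),
    dent_parent = rep(dent, times = cfg$n_flint),
    stringsAsFactors = FALSE
  )
  n_hyb <- nrow(design)

  lm_mat <- line_means(expr)
  L <- compute_midparent(lm_mat, design)

  causal_tab <- module_df[module_df$role == "causal", , drop = FALSE]
  role_of_module <- function(m) module_roles[m]
  composite <- function(ids) {
    if (!length(ids)) return(NULL)
    sgns <- module_df$module_sign[match(ids, module_df$probe_id)]
    z <- t(scale(t(L[ids, , drop = FALSE]))) * sgns
    m <- colMeans(z)
    as.numeric(scale(m))
  }
  causal_ids_by_role <- split(causal_tab$probe_id,
                              role_of_module(causal_tab$module_id))
  m_Y <- composite(causal_ids_by_role[["yield"]])
  m_D <- composite(causal_ids_by_role[["gdmc"]])
  m_S <- composite(causal_ids_by_role[["shared"]])
  # orthogonalize the trait-specific composites against the shared one so the
  # unit trait-variance budget is exact for every realization
  orth_std <- function(v, u) {
    if (is.null(v) || is.null(u)) return(v)
    r <- v - cov(v, u) / var(u) * u
    if (sd(r) == 0) stop("degenerate causal composites: traits unidentifiable")
    as.numeric(scale(r))
  }
  m_Y <- orth_std(m_Y, m_S)
  m_D <- orth_std(m_D, m_S)

  rho <- cfg$causal_corr_target
  kappa <- cfg$trait_coupling
  mean_abs_cor <- function(ids, comp) {
    sgns <- module_df$module_sign[match(ids, module_df$probe_id)]
    mean(vapply(seq_along(ids),
                function(i) cor(L[ids[i], ], comp) * sgns[i], numeric(1)))
  }
  a_Y <- if (!is.null(m_Y)) rho / mean_abs_cor(causal_ids_by_role[["yield"]], m_Y) else 0
  a_D <- if (!is.null(m_D)) rho / mean_abs_cor(causal_ids_by_role[["gdmc"]], m_D) else 0
  a_S <- if (!is.null(m_S)) rho / mean_abs_cor(causal_ids_by_role[["shared"]], m_S) else 0

  # Feasibility: the causal signal plus coupling must fit inside the unit
  # trait variance. The realized composite-gene correlations q vary with the
  # 21-line latent draw, so a = rho / q can occasionally overshoot; such
  # realizations are capped at a 0.98 signal-variance budget (logged), while
  # a config whose coupling alone exceeds the budget is rejected outright.
  budget <- 0.98
  if (!is.null(m_S) && kappa^2 >= budget) {
    stop(sprintf(paste0("generator field 'trait_coupling' (%.3f) unattainable: ",
                        "|trait_coupling| must be below %.3f"),
                 kappa, sqrt(budget)))
  }
  v_py <- a_Y^2 * (!is.null(m_Y)) + a_S^2 * (!is.null(m_S))
  if (v_py > budget) {
    sc <- sqrt(budget / v_py)
    hc_log("trait budget: yield coefficients scaled by %.3f for this realization", sc)
    a_Y <- a_Y * sc; a_S <- a_S * sc
    v_py <- budget
  }
  a_D_cap <- sqrt(max(budget - kappa^2 * (!is.null(m_S)), 0))
  if (!is.null(m_D) && a_D > a_D_cap) {
    hc_log("trait budget: GDMC coefficient capped at %.3f for this realization", a_D_cap)
    a_D <- a_D_cap
  }
  kappa_max <- if (!is.null(m_S)) sqrt(max(0, budget - a_D^2 * (!is.null(m_D)))) else 0
  zero <- rep(0, n_hyb)
  py_core <- a_Y * (m_Y %||% zero) + a_S * (m_S %||% zero)
  pd_core <- a_D * (m_D %||% zero) - kappa * (m_S %||% zero)
  v_pd <- a_D^2 * (!is.null(m_D)) + kappa^2 * (!is.null(m_S))
  py_std <- py_core + rnorm(n_hyb, 0, sqrt(1 - v_py))
  pd_std <- pd_core + rnorm(n_hyb, 0, sqrt(1 - v_pd))
  PY <- cfg$py_mean + cfg$py_sd * py_std
  PD <- cfg$pd_mean + cfg$pd_sd * pd_std

  perse <- data.frame(
    line_id = lines,
    PY_perse = rnorm(n_lines, cfg$perse_py_mean, cfg$perse_py_sd),
    PD_perse = rnorm(n_lines, cfg$perse_pd_mean, cfg$perse_pd_sd),
    stringsAsFactors = FALSE
  )
  mid <- function(vals) {
    (vals[match(design$flint_parent, perse$line_id)] +
       vals[match(design$dent_parent, perse$line_id)]) / 2
  }
  traits <- data.frame(
    hybrid_id = design$hybrid_id,
    PY = PY, PD = PD,
    HY = PY - mid(perse$PY_perse),
    HD = PD - mid(perse$PD_perse),
    stringsAsFactors = FALSE
  )

  causal_rows <- list()
  sgn_chr <- function(s) ifelse(s > 0, "P", "N")
  if (nrow(causal_tab)) {
    role <- role_of_module(causal_tab$module_id)
    s <- causal_tab$module_sign
    add <- function(ids, trait, sign) {
      data.frame(probe_id = ids, trait = trait, sign = sgn_chr(sign),
                 stringsAsFactors = FALSE)
    }
    yield_ids <- causal_tab$probe_id[role %in% c("yield", "shared")]
    yield_sgn <- s[role %in% c("yield", "shared")]
    gdmc_ids <- c(causal_tab$probe_id[role == "gdmc"],
                  causal_tab$probe_id[role == "shared"])
    gdmc_sgn <- c(s[role == "gdmc"], -s[role == "shared"] * sign(kappa + (kappa == 0)))
    causal_rows <- rbind(add(yield_ids, "yield", yield_sgn),
                         add(gdmc_ids, "gdmc", gdmc_sgn))
  } else {
    causal_rows <- data.frame(probe_id = character(), trait = character(),
                              sign = character(), stringsAsFactors = FALSE)
  }

  truth <- list(
    causal = causal_rows,
    modules = module_df,
    sigma2 = setNames(sigma2, probe_ids),
    d0_true = cfg$d0_true,
    s0sq_true = cfg$s0sq_true,
    realized_r_py_pd = cor(traits$PY, traits$PD),
    coef = list(a_Y = a_Y, a_D = a_D, a_S = a_S, kappa = kappa,
                kappa_max = kappa_max)
  )

  hc_log("generated %d probes x %d samples, %d hybrids (seed %s)",
         nrow(x), ncol(x), n_hyb, format(seed))
  structure(list(expr = expr, design = design, traits = traits, perse = perse,
                 truth = truth, config = cfg, seed = as.integer(seed)),
            class = "hc_sim")
}

#' @export
print.hc_sim <- function(x, ...) {
  cat("Synthetic factorial study (hc_sim)\n")
  cat(sprintf("  probes : %d (+%d spike-in)\n",
              sum(x$expr$probes$is_spikein == 0), sum(x$expr$probes$is_spikein == 1)))
  cat(sprintf("  samples: %d (%d lines x %d replicates)\n", ncol(x$expr$x),
              length(unique(x$expr$samples$line_id)), x$config$n_replicates))
  cat(sprintf("  hybrids: %d; causal genes: %d; realized r(PY,PD) = %.3f\n",
              nrow(x$design), length(unique(x$truth$causal$probe_id)),
              x$truth$realized_r_py_pd))
  invisible(x)
}

#' Calibrate the PY-PD coupling coefficient
#'
#' Finds the `trait_coupling` value (kappa) for which the mean realized
#' Pearson correlation between the two hybrid traits across seeded generator
#' replicates matches a target. The realized correlation is linear in kappa
#' (it arises solely from the shared latent component), so the coefficient is
#' estimated by weighted least squares through the origin from probe
#' simulations at two kappa values. Deterministic given `seed`.
#'
#' @param config a [generator_config()]; its `trait_coupling` entry is
#'   ignored during calibration.
#' @param target_r target correlation in (-1, 1). A target of exactly 0
#'   returns kappa = 0 without simulation.
#' @param n_reps generator replicates per probe value.
#' @param seed integer seed controlling the calibration replicates.
#' @return the calibrated kappa, with attributes `slope` (d r / d kappa) and
#'   `achievable` (the attainable |r| bound).
#' @export
calibrate_trait_coupling <- function(config = generator_config(), target_r,
                                     n_reps = 20L, seed = 1L) {
  if (!is.numeric(target_r) || length(target_r) != 1L ||
      target_r <= -1 || target_r >= 1) {
    stop("target_r must lie in (-1, 1)")
  }
  if (target_r == 0) return(structure(0, slope = NA_real_, achievable = NA_real_))
  # The realized correlation decomposes as r(PY, PD) = -a_S * kappa plus
  # zero-mean terms (cross-correlations of the orthogonalized composites and
  # of the trait noise), so the slope in kappa is -E[a_S]. The generator
  # records a_S and the feasibility bound kappa_max per realization; both are
  # averaged over seeded probe replicates.
  probe_kappa <- 0.5
  cfg <- config
  cfg$trait_coupling <- probe_kappa
  coefs <- vapply(seq_len(n_reps), function(i) {
    sim <- generate_dataset(cfg, seed = stage_seed(seed, i))
    c(sim$truth$coef$a_S, sim$truth$coef$kappa_max)
  }, numeric(2))
  slope <- -mean(coefs[1L, ])
  kmax <- mean(coefs[2L, ])
  if (abs(slope) < 1e-8) {
    stop("target_r unattainable: the generator configuration has no shared ",
         "causal genes, so only r(PY, PD) = 0 is achievable")
  }
  achievable <- abs(slope) * kmax
  if (abs(target_r) >= achievable) {
    stop(sprintf(paste0("target_r = %.3f unattainable under these noise ",
                        "settings: achievable |r(PY, PD)| is below %.3f"),
                 target_r, achievable))
  }
  kappa <- target_r / slope
  if (abs(kappa) >= kmax) kappa <- sign(kappa) * 0.999 * kmax
  hc_log("calibrated trait_coupling = %.4f for target r = %.3f", kappa, target_r)
  structure(kappa, slope = slope, achievable = achievable)
}

#' Build a synthetic category map from a simulated study
#'
#' Emits one category per co-expression module plus random gene groupings,
#' as a stand-in functional catalogue for exercising the enrichment stage on
#' synthetic data.
#'
#' @param sim an \code{hc_sim}.
#' @param n_random number of random categories.
#' @param size_range size range of the random categories.
#' @param seed integer seed.
#' @return named list mapping category name to a character vector of probe
#'   ids (a CategoryMap).
#' @export
synthetic_categories <- function(sim, n_random = 15L, size_range = c(30L, 120L),
                                 seed = 1L) {
  set.seed(as.integer(seed))
  cats <- list()
  if (nrow(sim$truth$modules)) {
    by_mod <- split(sim$truth$modules$probe_id, sim$truth$modules$module_id)
    names(by_mod) <- sprintf("module_%02d", as.integer(names(by_mod)))
    cats <- by_mod
  }
  gene_ids <- sim$expr$probes$probe_id[sim$expr$probes$is_spikein == 0]
  for (i in seq_len(n_random)) {
    sz <- sample(size_range[1]:size_range[2], 1L)
    cats[[sprintf("random_%02d", i)]] <- sample(gene_ids, sz)
  }
  cats
}
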