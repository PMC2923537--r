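#' Analysis configuration
#'
#' Assembles and validates the threshold set used throughout the pipeline.
#' Defaults follow the study design the package emulates: differential
#' expression is controlled at FDR 0.01 with a 1.3 fold-change and a mean
#' log2 intensity of 8.0; the two-step selection uses p < 1e-4 (step 1),
#' p < 0.01 (step 2 candidate pool) and a co-expression gate of r > 0.9;
#' bootstrap confidence intervals use 10,000 resamples; the trait-trait
#' permutation test uses 9,999 Monte Carlo samples; cross-validation runs
#' 100 rounds comparing top-200 rankings.
#'
#' @param ... named settings overriding the defaults below.
#'
#' @details Settings and defaults:
#' \describe{
#'   \item{fdr_de (0.01)}{BH-adjusted significance cutoff of the moderated
#'     F-test.}
#'   \item{fc_min (1.3)}{minimum fold change between at least one pair of
#'     parental lines, compared as \code{log2(fc_min)} on the log2 scale.}
#'   \item{intensity_min (8.0)}{minimum summary log2 intensity of a probe.}
#'   \item{alpha_step1 (1e-4), alpha_step2 (0.01)}{significance gates of the
#'     two selection steps; step 1 must not be looser than step 2.}
#'   \item{r_coexpr (0.9)}{signed Pearson co-expression gate of step 2.}
#'   \item{n_boot (10000)}{BCa bootstrap resamples.}
#'   \item{n_perm (9999)}{Monte Carlo samples of the permutation test.}
#'   \item{cv_rounds (100), cv_top (200)}{cross-validation rounds and the
#'     ranking depth k of the overlap metric.}
#'   \item{min_lines (1)}{number of line means that must exceed the spike-in
#'     reliability threshold.}
#'   \item{intensity_summary ("mean")}{"mean" or "max" of line means used for
#'     the intensity filter.}
#'   \item{fc_prefilter (TRUE)}{apply the fold-change screen before the
#'     moderated F-test (the test then runs on the prefiltered set).}
#'   \item{threshold_on ("raw")}{apply selection gates to raw p ("raw") or
#'     BH-adjusted q ("fdr").}
#'   \item{coexpr_profile ("midparent")}{co-expression computed between
#'     mid-parent profiles across hybrids, or "line" for line-level profiles.}
#'   \item{coexpr_signed (TRUE)}{gate on signed r (TRUE) or |r| (FALSE).}
#'   \item{heterosis_scale ("absolute")}{mid-parent heterosis as an absolute
#'     difference or as "percent" of the mid-parent value.}
#'   \item{correlate_probes ("de")}{correlate DE-passing probes only, or
#'     "all" reliable probes.}
#'   \item{cv_complement (FALSE)}{use the complement of the sampled lines as
#'     the estimation set.}
#'   \item{ci_for ("selected")}{compute BCa intervals for "selected" genes,
#'     "all" correlated probes, or "none".}
#' }
#'
#' @return a validated named list of class \code{hc_config}.
#' @export
#' @examples
#' cfg <- hc_config(fc_min = 1.5)
#' cfg$fc_min
hc_config <- function(...) {
  defaults <- list(
    fdr_de = 0.01,
    fc_min = 1.3,
    intensity_min = 8.0,
    alpha_step1 = 1e-4,
    alpha_step2 = 0.01,
    r_coexpr = 0.9,
    n_boot = 10000L,
    n_perm = 9999L,
    cv_rounds = 100L,
    cv_top = 200L,
    min_lines = 1L,
    intensity_summary = "mean",
    fc_prefilter = TRUE,
    threshold_on = "raw",
    coexpr_profile = "midparent",
    coexpr_signed = TRUE,
    heterosis_scale = "absolute",
    correlate_probes = "de",
    cv_complement = FALSE,
    ci_for = "selected"
  )
  override <- list(...)
  if (length(override) == 1L && is.list(override[[1L]]) && is.null(names(override))) {
    override <- override[[1L]]
  }
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, override)
  validate_config(cfg)
  structure(cfg, class = "hc_config")
}

validate_config <- function(cfg) {
  chk_prob <- function(key, lo = 0, hi = 1, lo_open = TRUE, hi_open = FALSE) {
    v <- cfg[[key]]
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v) &&
      (if (lo_open) v > lo else v >= lo) &&
      (if (hi_open) v < hi else v <= hi)
    if (!ok) stop(sprintf("configuration key '%s' out of range: %s", key, format(v)))
  }
  chk_count <- function(key, min = 1) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < min || v != round(v)) {
      stop(sprintf("configuration key '%s' must be an integer >= %d", key, min))
    }
  }
  chk_choice <- function(key, choices) {
    v <- cfg[[key]]
    if (!is.character(v) || length(v) != 1L || !(v %in% choices)) {
      stop(sprintf("configuration key '%s' must be one of: %s", key,
                   paste(choices, collapse = ", ")))
    }
  }
  chk_flag <- function(key) {
    v <- cfg[[key]]
    if (!is.logical(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("configuration key '%s' must be TRUE or FALSE", key))
    }
  }
  chk_prob("fdr_de"); chk_prob("alpha_step1"); chk_prob("alpha_step2")
  chk_prob("r_coexpr")
  if (!is.numeric(cfg$fc_min) || cfg$fc_min < 1) {
    stop("configuration key 'fc_min' must be a ratio >= 1")
  }
  if (!is.numeric(cfg$intensity_min) || !is.finite(cfg$intensity_min)) {
    stop("configuration key 'intensity_min' must be finite")
  }
  if (cfg$alpha_step1 > cfg$alpha_step2) {
    stop("configuration key 'alpha_step1' must not exceed 'alpha_step2' ",
         "(step 1 is the stringent gate)")
  }
  chk_count("n_boot", 100); chk_count("n_perm", 1)
  chk_count("cv_rounds"); chk_count("cv_top"); chk_count("min_lines")
  chk_choice("intensity_summary", c("mean", "max"))
  chk_choice("threshold_on", c("raw", "fdr"))
  chk_choice("coexpr_profile", c("midparent", "line"))
  chk_choice("heterosis_scale", c("absolute", "percent"))
  chk_choice("correlate_probes", c("de", "all"))
  chk_choice("ci_for", c("selected", "all", "none"))
  chk_flag("fc_prefilter"); chk_flag("coexpr_signed"); chk_flag("cv_complement")
  invisible(cfg)
}

#' Load a flat key:value configuration file
#'
#' Reads a plain-text configuration in `key: value` form (one setting per
#' line; blank lines and lines starting with `#` are ignored), coerces each
#' value to the type of the corresponding default, and validates the result
#' with [hc_config()]. An empty file yields the full default set; unknown
#' keys are rejected.
#'
#' @param path path to the configuration file.
#' @return a validated \code{hc_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  override <- list()
  defaults <- hc_config()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    sep <- regexpr("[:=]", ln)
    if (sep < 0) stop(sprintf("%s: line %d is not 'key: value'", path, i))
    key <- trimws(substr(ln, 1L, sep - 1L))
    val <- trimws(substr(ln, sep + 1L, nchar(ln)))
    if (!key %in% names(defaults)) {
      stop(sprintf("%s: unknown configuration key '%s' (line %d)", path, key, i))
    }
    proto <- defaults[[key]]
    parsed <- if (is.logical(proto)) {
      if (!toupper(val) %in% c("TRUE", "FALSE", "T", "F")) {
        stop(sprintf("%s: key '%s' expects TRUE/FALSE, got '%s'", path, key, val))
      }
      toupper(val) %in% c("TRUE", "T")
    } else if (is.numeric(proto)) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop(sprintf("%s: key '%s' expects a number, got '%s'", path, key, val))
      if (is.integer(proto)) as.integer(num) else num
    } else {
      val
    }
    override[[key]] <- parsed
  }
  do.call(hc_config, override)
}
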