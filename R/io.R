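# All pipeline files are tab-separated text with header rows. Identifiers are
# opaque strings; missing values are not permitted in the expression matrix.

new_expression <- function(x, samples, probes) {
  stopifnot(is.matrix(x))
  obj <- list(x = x, samples = samples, probes = probes)
  validate_expression(obj)
  structure(obj, class = "hc_expr")
}

validate_expression <- function(obj, context = "expression data") {
  x <- obj$x; samples <- obj$samples; probes <- obj$probes
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1L]
    stop(sprintf("%s: duplicated probe id '%s'", context, dup))
  }
  if (anyDuplicated(colnames(x))) {
    dup <- colnames(x)[duplicated(colnames(x))][1L]
    stop(sprintf("%s: duplicated sample id '%s'", context, dup))
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-finite intensity at probe '%s', sample '%s'",
                 context, rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  missing_samp <- setdiff(colnames(x), samples$sample_id)
  if (length(missing_samp)) {
    stop(sprintf("%s: sample '%s' absent from the sample sheet",
                 context, missing_samp[1L]))
  }
  bad_group <- setdiff(unique(samples$group), c("flint", "dent"))
  if (length(bad_group)) {
    stop(sprintf("%s: unknown heterotic group label '%s' in sample sheet",
                 context, bad_group[1L]))
  }
  missing_probe <- setdiff(rownames(x), probes$probe_id)
  if (length(missing_probe)) {
    stop(sprintf("%s: probe '%s' absent from the probe sheet",
                 context, missing_probe[1L]))
  }
  if (!all(probes$is_spikein %in% c(0L, 1L))) {
    stop(sprintf("%s: probe sheet column 'is_spikein' must be 0/1", context))
  }
  invisible(obj)
}

read_tsv <- function(path, required, what = path) {
  if (!file.exists(path)) stop(what, ": file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  df
}

write_tsv <- function(df, path) {
  # full-precision numeric formatting so paired readers round-trip exactly
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with its sample and probe sheets
#'
#' The matrix file is tab-separated with a header row of sample ids and a
#' first column of probe ids; the sample sheet carries
#' `sample_id, line_id, group, replicate` (groups restricted to flint/dent)
#' and the probe sheet `probe_id, is_spikein`. Malformed input is rejected
#' with an error naming the offending file, row or column; nothing is
#' silently coerced.
#'
#' @param matrix_path,sample_sheet_path,probe_sheet_path file paths.
#' @return an object of class \code{hc_expr}.
#' @export
read_expression <- function(matrix_path, sample_sheet_path, probe_sheet_path) {
  raw <- read.delim(matrix_path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop(matrix_path, ": expected probe id column plus samples")
  ids <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1L]
      stop(sprintf("%s: non-numeric intensity at row %d (probe '%s'), column '%s'",
                   matrix_path, row, ids[row], names(vals)[j]))
    }
    vals[[j]] <- v
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  samples <- read_tsv(sample_sheet_path,
                      c("sample_id", "line_id", "group", "replicate"))
  probes <- read_tsv(probe_sheet_path, c("probe_id", "is_spikein"))
  new_expression(x, samples, probes)
}

#' Write an expression matrix and its annotation sheets
#'
#' @param expr an \code{hc_expr}.
#' @param matrix_path,sample_sheet_path,probe_sheet_path output paths.
#' @return the matrix path, invisibly.
#' @export
write_expression <- function(expr, matrix_path, sample_sheet_path, probe_sheet_path) {
  df <- data.frame(probe_id = rownames(expr$x), expr$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  write_tsv(expr$samples, sample_sheet_path)
  write_tsv(expr$probes, probe_sheet_path)
  invisible(matrix_path)
}

#' Read / write the factorial crossing design
#'
#' Columns `hybrid_id, flint_parent, dent_parent`; hybrid ids must be unique.
#' @param path file path.
#' @return data frame with one row per hybrid.
#' @export
read_design <- function(path) {
  df <- read_tsv(path, c("hybrid_id", "flint_parent", "dent_parent"))
  if (anyDuplicated(df$hybrid_id)) {
    stop(path, ": duplicated hybrid id '",
         df$hybrid_id[duplicated(df$hybrid_id)][1L], "'")
  }
  df
}

#' @rdname read_design
#' @param design design data frame.
#' @export
write_design <- function(design, path) write_tsv(design, path)

#' Read / write the hybrid trait table
#'
#' Requires `hybrid_id, PY, PD` (grain yield in Mg/ha, grain dry matter
#' content in percent); optional `HY, HD` heterosis columns. PD must lie in
#' (0, 100) and PY must be positive.
#' @param path file path.
#' @return data frame with one row per hybrid.
#' @export
read_traits <- function(path) {
  df <- read_tsv(path, c("hybrid_id", "PY", "PD"))
  if (anyDuplicated(df$hybrid_id)) {
    stop(path, ": duplicated hybrid id '",
         df$hybrid_id[duplicated(df$hybrid_id)][1L], "'")
  }
  if (any(df$PY <= 0)) stop(path, ": PY must be positive (Mg/ha)")
  if (any(df$PD <= 0 | df$PD >= 100)) stop(path, ": PD must lie in (0, 100) percent")
  df
}

#' @rdname read_traits
#' @param traits trait data frame.
#' @export
write_traits <- function(traits, path) write_tsv(traits, path)

#' Read / write per-se line trait values
#'
#' Columns `line_id, PY_perse, PD_perse` used to derive mid-parent heterosis.
#' @param path file path.
#' @return data frame with one row per line.
#' @export
read_perse <- function(path) read_tsv(path, c("line_id", "PY_perse", "PD_perse"))

#' @rdname read_perse
#' @param perse per-se data frame.
#' @export
write_perse <- function(perse, path) write_tsv(perse, path)

#' Read a GMT category map
#'
#' Standard GMT dialect: per line, category name, description, then member
#' ids, tab-separated. Duplicate members within a category are collapsed.
#'
#' @param path GMT file path.
#' @return named list mapping category name to a character vector of ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cats <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("%s: line %d has %d field(s); GMT needs category, description and at least one member",
                   path, i, length(f)))
    }
    cats[[f[1L]]] <- unique(f[-(1:2)])
  }
  cats
}

#' @rdname read_gmt
#' @param categories named list of member id vectors.
#' @param descriptions optional character vector of category descriptions.
#' @export
write_gmt <- function(categories, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(categories))
  lines <- vapply(seq_along(categories), function(i) {
    paste(c(names(categories)[i], descriptions[i], categories[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the generator ground-truth table
#'
#' Tab-separated columns `probe_id, role, trait, sign, module_id`; one row
#' per module gene and trait assignment.
#' @param truth the `truth` element of an \code{hc_sim}.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  mod <- truth$modules
  if (!nrow(mod)) {
    df <- data.frame(probe_id = character(), role = character(),
                     trait = character(), sign = character(),
                     module_id = integer())
    return(write_tsv(df, path))
  }
  key <- paste(truth$causal$probe_id, truth$causal$trait)
  rows <- merge(mod[, c("probe_id", "role", "module_id")],
                truth$causal, by = "probe_id", all.x = TRUE)
  rows$trait[is.na(rows$trait)] <- "none"
  rows$sign[is.na(rows$sign)] <- "."
  write_tsv(rows[order(rows$module_id, rows$probe_id, rows$trait),
                 c("probe_id", "role", "trait", "sign", "module_id")], path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read_tsv(path, c("probe_id", "role", "trait", "sign", "module_id"))
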