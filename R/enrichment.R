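#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' background of `N` of which `K` belong to the category. Used as the
#' one-sided overrepresentation p-value.
#'
#' @param N background size.
#' @param K category members in the background.
#' @param n query-set size.
#' @param k category members in the query set.
#' @return upper-tail probability; `k = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 3)  # 55/210
hypergeom_upper_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      stop("counts must be single non-negative integers")
    }
  }
  if (K > N || n > N) stop("inconsistent counts: K and n must not exceed N")
  if (k > min(K, n)) stop("inconsistent counts: k exceeds min(K, n)")
  if (k == 0) return(1)
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Category overrepresentation test
#'
#' Tests each category for overrepresentation in a query gene set against a
#' background (by default the differentially expressed set), using the
#' hypergeometric upper tail. Both sets are restricted to genes annotated to
#' at least one category; query genes outside the background are dropped
#' (logged). Multi-category genes count in every category they belong to.
#'
#' @param categories named list mapping category to member ids (see
#'   [read_gmt()]).
#' @param background character vector of background probe ids.
#' @param query character vector of query probe ids.
#' @param include_zero also report categories with no query member (their
#'   p is 1).
#' @return data frame of class \code{hc_enrichment}:
#'   `category, N, K, n, k, p, q` with BH-adjusted q across the reported
#'   categories.
#' @export
enrich_categories <- function(categories, background, query,
                              include_zero = FALSE) {
  if (!length(categories)) stop("empty category map")
  stray <- setdiff(query, background)
  if (length(stray)) {
    hc_log("enrichment: %d query gene(s) outside the background were dropped",
           length(stray))
    query <- intersect(query, background)
  }
  annotated <- unique(unlist(categories, use.names = FALSE))
  bg <- intersect(background, annotated)
  if (!length(bg)) stop("no background gene is annotated to any category")
  qs <- intersect(query, annotated)
  N <- length(bg); n <- length(qs)
  rows <- lapply(names(categories), function(cat) {
    members <- categories[[cat]]
    K <- length(intersect(bg, members))
    k <- length(intersect(qs, members))
    if (K == 0L) return(NULL)
    if (k == 0L && !include_zero) return(NULL)
    data.frame(category = cat, N = N, K = K, n = n, k = k,
               p = hypergeom_upper_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(category = character(), N = integer(), K = integer(),
                       n = integer(), k = integer(), p = numeric(),
                       q = numeric(), stringsAsFactors = FALSE)
    return(structure(rows, class = c("hc_enrichment", "data.frame")))
  }
  rows$q <- adjust_fdr(rows$p)
  rows <- rows[order(rows$p, rows$category), ]
  rownames(rows) <- NULL
  structure(rows, class = c("hc_enrichment", "data.frame"))
}

#' Category distribution table
#'
#' For each category and each labeled gene set, the number of member genes
#' and their percentage of the set's annotated genes. Categories may overlap,
#' so percentages need not sum to 100.
#'
#' @param categories named list mapping category to member ids.
#' @param background character vector of background probe ids (reported as
#'   its own column).
#' @param query_sets named list of character vectors.
#' @return data frame with `category` and, per set (background first), count
#'   and percentage columns.
#' @export
category_table <- function(categories, background, query_sets) {
  sets <- c(list(background = background), query_sets)
  annotated <- unique(unlist(categories, use.names = FALSE))
  out <- data.frame(category = names(categories), stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    s <- intersect(sets[[nm]], annotated)
    cnt <- vapply(categories, function(m) length(intersect(m, s)), numeric(1))
    out[[paste0(nm, "_n")]] <- as.integer(cnt)
    out[[paste0(nm, "_pct")]] <- if (length(s)) {
      round(100 * cnt / length(s), 1)
    } else {
      rep(NA_real_, length(cnt))
    }
  }
  out
}
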