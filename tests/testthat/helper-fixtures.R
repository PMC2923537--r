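# Shared fixtures built in code at test time.

# A reduced factorial study that keeps every structural feature of the
# default design (two heterotic groups, spike-ins, modules, causal genes)
# at a fraction of the size.
small_gencfg <- function(...) {
  args <- utils::modifyList(
    list(n_probes = 400L, n_spikein = 20L, n_modules = 4L, module_size = 8L,
         n_causal_yield = 10L, n_causal_gdmc = 8L, n_causal_shared = 4L,
         trait_coupling = 0.6),
    list(...))
  do.call(generator_config, args)
}

# Hand-built expression object: x is a probes x samples matrix, `lines`
# labels each column, `groups` each line.
toy_expression <- function(x, lines, groups = NULL, spike = character(0)) {
  if (is.null(colnames(x))) colnames(x) <- paste0(lines, "_r", ave(seq_along(lines), lines, FUN = seq_along))
  if (is.null(rownames(x))) rownames(x) <- paste0("p", seq_len(nrow(x)))
  uline <- unique(lines)
  if (is.null(groups)) {
    groups <- setNames(rep(c("flint", "dent"), length.out = length(uline)), uline)
  }
  samples <- data.frame(
    sample_id = colnames(x),
    line_id = lines,
    group = unname(groups[lines]),
    replicate = as.integer(ave(seq_along(lines), lines, FUN = seq_along)),
    stringsAsFactors = FALSE
  )
  probes <- data.frame(probe_id = rownames(x),
                       is_spikein = as.integer(rownames(x) %in% spike),
                       stringsAsFactors = FALSE)
  hybridcor:::new_expression(x, samples, probes)
}

# Brute-force Benjamini-Hochberg step-up, written independently of the
# implementation: q_i = min over j with p_j >= p_i of min(1, m p_j / rank_j).
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- match(seq_len(m), ord)  # rank of each p in ascending order
  sapply(seq_len(m), function(i) {
    cand <- sapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) min(1, m * p[j] / which(ord == j)) else Inf
    })
    min(cand)
  })
}

# All permutations of 1:n as a list of index vectors.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (s in sub) {
    for (pos in 0:(n - 1)) {
      i <- i + 1L
      out[[i]] <- append(s, n, after = pos)
    }
  }
  out
}

# Exact hypergeometric upper tail by combinatorial enumeration.
hyper_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Construct row vectors with exact pairwise sample correlations: rows of
# `coefs` (unit norm) give the target Gram matrix; the basis columns are
# orthonormal and centered, so sample correlations equal coefs %*% t(coefs).
exact_cor_rows <- function(coefs, n = 24, seed = 99) {
  set.seed(seed)
  m <- scale(matrix(rnorm(n * ncol(coefs)), n), scale = FALSE)
  q <- qr.Q(qr(m))
  out <- coefs %*% t(q)
  rownames(out) <- rownames(coefs)
  out
}
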