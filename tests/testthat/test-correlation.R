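test_that("mid-parent expression is the parental average", {
  lm_mat <- matrix(c(8, 10), 1, 2, dimnames = list("g1", c("F01", "D01")))
  design <- data.frame(hybrid_id = "h1", flint_parent = "F01", dent_parent = "D01")
  expect_equal(compute_midparent(lm_mat, design)["g1", "h1"], 9)

  # identical parents reproduce the parental value
  lm2 <- matrix(c(7.3, 7.3), 1, 2, dimnames = list("g1", c("F01", "D01")))
  expect_equal(compute_midparent(lm2, design)["g1", "h1"], 7.3)

  # brute-force enumeration on a random 10 x (3 x 3) factorial
  set.seed(5)
  lm3 <- matrix(rnorm(10 * 6, 9, 1), 10, 6,
                dimnames = list(paste0("g", 1:10),
                                c(paste0("F0", 1:3), paste0("D0", 1:3))))
  des3 <- expand.grid(flint_parent = paste0("F0", 1:3),
                      dent_parent = paste0("D0", 1:3),
                      stringsAsFactors = FALSE)
  des3$hybrid_id <- paste0(des3$flint_parent, "x", des3$dent_parent)
  L <- compute_midparent(lm3, des3)
  for (h in seq_len(nrow(des3))) {
    expect_identical(L[, des3$hybrid_id[h]],
                     (lm3[, des3$flint_parent[h]] + lm3[, des3$dent_parent[h]]) / 2)
  }
  # bounds: min(parents) <= L <= max(parents)
  expect_true(all(L >= pmin(lm3[, des3$flint_parent], lm3[, des3$dent_parent])))
  expect_true(all(L <= pmax(lm3[, des3$flint_parent], lm3[, des3$dent_parent])))

  bad <- data.frame(hybrid_id = "hx", flint_parent = "F09", dent_parent = "D01")
  expect_error(compute_midparent(lm3, bad), "hx")
})

test_that("heterosis is the F1 deviation from the mid-parent value", {
  design <- data.frame(hybrid_id = "h1", flint_parent = "F01", dent_parent = "D01")
  perse <- data.frame(line_id = c("F01", "D01"), PY_perse = c(8, 8),
                      PD_perse = c(80, 84))
  traits <- data.frame(hybrid_id = "h1", PY = 10, PD = 82)
  out <- compute_heterosis(traits, perse, design)
  expect_equal(out$HY, 2)
  expect_equal(out$HD, 0)   # F1 equals mid-parent
  pct <- compute_heterosis(traits, perse, design, scale = "percent")
  expect_equal(pct$HY, 100 * 2 / 8)

  expect_error(compute_heterosis(traits, perse[1, ], design), "h1")

  # generator round trip: recomputed heterosis equals the emitted values
  sim <- generate_dataset(small_gencfg(), seed = 4)
  redo <- compute_heterosis(sim$traits, sim$perse, sim$design)
  expect_equal(redo$HY, sim$traits$HY)
  expect_equal(redo$HD, sim$traits$HD)
})

test_that("correlation t-test matches its closed-form distribution", {
  expect_equal(correlate_trait(1:10, 2 * (1:10) + 1)[c("r", "p")],
               list(r = 1, p = 0))
  res <- correlate_trait(c(1, 2, 3, 4), c(1, 2, 2, 1))
  expect_equal(res$r, 0)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # affine invariance; negative scaling flips the sign of r
  set.seed(77)
  x <- rnorm(30); y <- rnorm(30)
  r0 <- correlate_trait(x, y)
  r1 <- correlate_trait(2 * x + 5, y)
  r2 <- correlate_trait(-3 * x + 1, y)
  expect_equal(r1$r, r0$r); expect_equal(r1$p, r0$p)
  expect_equal(r2$r, -r0$r); expect_equal(r2$p, r0$p)

  # independent high-precision oracle: the two-sided t-test p equals the
  # regularized incomplete beta I_{df/(df+t^2)}(df/2, 1/2)
  set.seed(98)
  n <- 98
  for (i in 1:20) {
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    res <- correlate_trait(x, y)
    oracle <- pbeta((n - 2) / ((n - 2) + res$t^2), (n - 2) / 2, 0.5)
    expect_equal(res$p, oracle, tolerance = 1e-10)
  }

  const <- correlate_trait(rep(1, 10), rnorm(10))
  expect_true(const$undefined)
  expect_error(correlate_trait(1:3, 1:4), "equal length")
  expect_error(correlate_trait(1:2, 2:1), "at least 3")
})

test_that("correlation tables carry monotone FDR per trait", {
  sim <- generate_dataset(small_gencfg(), seed = 10)
  L <- compute_midparent(line_means(sim$expr), sim$design)
  ct <- correlate_all(L[1:150, ], sim$traits)
  expect_setequal(unique(ct$trait), c("PY", "HY", "PD", "HD"))
  ok <- !ct$undefined
  expect_true(all(ct$q[ok] >= ct$p[ok]))
  expect_true(all(abs(ct$r[ok]) <= 1))
  for (tr in unique(ct$trait)) {
    sub <- ct[ct$trait == tr & !ct$undefined, ]
    expect_true(all(diff(sub$q[order(sub$p)]) >= -1e-15))
  }
})

test_that("BCa intervals behave at the degenerate and symmetric limits", {
  # exactly collinear pairs give the point interval (1, 1)
  expect_equal(bca_ci(1:20, 2 * (1:20) + 3, B = 500, seed = 1), c(1, 1))

  # deterministic given seed
  set.seed(3); x <- rnorm(40); y <- rnorm(40)
  expect_identical(bca_ci(x, y, B = 2000, seed = 9),
                   bca_ci(x, y, B = 2000, seed = 9))

  # endpoints stay inside [-1, 1] and bracket r when the bootstrap succeeds
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    ci <- bca_ci(x, y, B = 2000, seed = i)
    expect_gte(ci[1], -1); expect_lte(ci[2], 1)
    expect_lte(ci[1], cor(x, y)); expect_gte(ci[2], cor(x, y))
  }

  # symmetric null data: BCa reduces to the percentile interval
  set.seed(6); x <- rnorm(98); y <- rnorm(98)
  ci <- bca_ci(x, y, B = 10000, seed = 2)
  set.seed(2)
  idx <- matrix(sample.int(98, 98 * 10000, replace = TRUE), nrow = 10000)
  theta <- hybridcor:::boot_cor(x, y, idx)
  perc <- sort(theta)[pmax(1, ceiling(10000 * c(0.025, 0.975)))]
  expect_lt(max(abs(ci - perc)), 0.01)

  expect_error(bca_ci(1:3, 3:1), "at least 4")
})

test_that("BCa intervals agree with the established bootstrap implementation", {
  skip_if_not_installed("boot")
  set.seed(7)
  n <- 98; x <- rnorm(n); y <- 0.4 * x + rnorm(n, 0, sqrt(1 - 0.16))
  ci <- bca_ci(x, y, B = 10000, seed = 3)
  b <- boot::boot(data.frame(x, y),
                  function(d, i) cor(d$x[i], d$y[i]), R = 10000)
  bc <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_lt(max(abs(ci - bc)), 0.02)
})

test_that("the permutation test follows the add-one rule", {
  set.seed(15)
  y <- rnorm(30)
  res <- trait_permutation_test(y, y, n_perm = 9999, seed = 1)
  expect_equal(res$p, 1e-4)      # maximal statistic: minimum attainable p
  expect_equal(res$r, 1)

  # determinism and the add-one lower bound
  x2 <- rnorm(30); y2 <- x2 + rnorm(30, 0, 0.1)
  a <- trait_permutation_test(x2, y2, n_perm = 999, seed = 5)
  b <- trait_permutation_test(x2, y2, n_perm = 999, seed = 5)
  expect_identical(a, b)
  expect_gte(a$p, 1 / 1000)

  expect_error(trait_permutation_test(rep(1, 10), rnorm(10)), "constant")

  # asymptotic agreement with the parametric t-test for independent Gaussians
  set.seed(30)
  diffs <- replicate(30, {
    x <- rnorm(98); y <- rnorm(98)
    pp <- trait_permutation_test(x, y, n_perm = 1999, seed = 11)$p
    pt_ <- correlate_trait(x, y)$p
    abs(pp - pt_)
  })
  expect_lt(max(diffs), 0.05)
  expect_lt(mean(diffs), 0.02)
})
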