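test_that("reliability threshold is mean plus three sample sd", {
  expect_equal(reliability_threshold(c(6, 7, 8)), 10)       # mean 7, sd 1
  expect_equal(reliability_threshold(rep(5, 10)), 5)        # sd 0
  set.seed(1)
  v <- rnorm(50, 5, 0.5)
  expect_equal(reliability_threshold(v), reliability_threshold(sample(v)))
  expect_equal(reliability_threshold(v), mean(v) + 3 * sd(v))
  expect_error(reliability_threshold(5), "at least 2")
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(21)
  for (m in 2:6) {
    p <- round(runif(m), 3)
    expect_equal(adjust_fdr(p), bh_bruteforce(p))
  }
  # order preservation: q-ordering never inverts the p-ordering
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("moderated F handles the no-signal and limiting regimes", {
  # identical replicate values per line and across lines: F = 0, p = 1
  set.seed(4)
  x <- rbind(const = rep(3, 8),
             matrix(rnorm(40, 8, 0.3), 5, 8))
  rownames(x)[-1] <- paste0("g", 1:5)
  lines <- rep(c("A", "B"), each = 4)
  fit <- moderated_f_test(x, lines)
  expect_equal(fit$table$F[1], 0)
  expect_equal(fit$table$p[1], 1)
  expect_gt(fit$prior$s0sq, 0)

  # d0 -> Inf regime: equals ordinary F with the pooled common variance
  fitInf <- moderated_f_test(x, lines, d0_override = Inf)
  pooled <- mean(fit$table$s2)
  msb <- fit$table$F * fit$table$stilde2
  expect_equal(fitInf$table$F, msb / pooled, tolerance = 1e-12)

  # all variances identical: prior estimation falls back to d0 = Inf
  xx <- matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4, byrow = TRUE)
  colnames(xx) <- paste0("s", 1:4)
  fit2 <- moderated_f_test(xx, c("A", "A", "B", "B"))
  expect_identical(fit2$prior$d0, Inf)

  expect_error(moderated_f_test(x, rep(c("A", "B"), 4)[1:7]), "every column")
  expect_error(moderated_f_test(x[, 1:5], c("A", "A", "A", "A", "B")),
               "at least 2 replicates")
})

test_that("moderated F with d0 forced to zero equals the ordinary F-test", {
  set.seed(12)
  lines <- rep(paste0("L", 1:3), each = 3)
  x <- matrix(rnorm(20 * 9, 8, 0.5), 20, 9)
  x[1:5, ] <- x[1:5, ] + outer(runif(5, 0.5, 1.5), rep(rnorm(3), each = 3))
  rownames(x) <- paste0("g", 1:20)
  f0 <- moderated_f_test(x, lines, d0_override = 0)
  oracle <- t(vapply(seq_len(nrow(x)), function(i) {
    a <- anova(lm(x[i, ] ~ factor(lines)))
    c(a[["F value"]][1], a[["Pr(>F)"]][1])
  }, numeric(2)))
  expect_equal(f0$table$F, oracle[, 1], tolerance = 1e-10)
  expect_equal(f0$table$p, oracle[, 2], tolerance = 1e-10)
})

test_that("moderated F and prior agree with the established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(42)
  G <- 200; lines <- rep(paste0("L", 1:4), each = 3)
  sds <- sqrt(0.05 * 4 / rchisq(G, 4))
  x <- matrix(rnorm(G * 12, 8, rep(sds, 12)), G, 12)
  x[1:40, ] <- x[1:40, ] + outer(rnorm(40), rep(rnorm(4), each = 3))
  rownames(x) <- paste0("g", 1:G)
  fit <- moderated_f_test(x, lines)
  lf <- limma::eBayes(limma::lmFit(x, stats::model.matrix(~factor(lines))))
  tt <- limma::topTable(lf, coef = 2:4, number = Inf, sort.by = "none")
  expect_equal(fit$prior$d0, lf$df.prior, tolerance = 1e-8)
  expect_equal(fit$prior$s0sq, lf$s2.prior, tolerance = 1e-8)
  expect_equal(fit$table$F, tt$F, tolerance = 1e-8)
  expect_equal(fit$table$p, tt$P.Value, tolerance = 1e-8)
})

test_that("the differential screen applies each filter as constructed", {
  # four engineered probes: one survivor, one failing each filter
  set.seed(8)
  lines <- rep(c("F01", "D01"), each = 3)
  base <- function(a, b, sd = 0.05) c(rnorm(3, a, sd), rnorm(3, b, sd))
  x <- rbind(
    pass = base(9.0, 10.0),            # bright, large fc, tight variance
    dim  = base(3.0, 4.0),             # below the spike-in threshold
    flat = base(9.5, 9.5),             # no fold change
    loud = base(9.0, 10.0, sd = 3.0),  # large fc but hopeless variance
    spikeA = rnorm(6, 5, 0.2),
    spikeB = rnorm(6, 5, 0.2),
    spikeC = rnorm(6, 5, 0.2)
  )
  expr <- toy_expression(x, lines, groups = c(F01 = "flint", D01 = "dent"),
                         spike = c("spikeA", "spikeB", "spikeC"))
  de <- select_differential(expr, hc_config())
  tab <- de$table
  expect_setequal(tab$probe_id, c("pass", "dim", "flat", "loud"))
  expect_true(tab$de_pass[tab$probe_id == "pass"])
  expect_false(tab$reliable[tab$probe_id == "dim"])
  expect_false(tab$fc_pass[tab$probe_id == "flat"])
  expect_false(tab$q_pass[tab$probe_id == "loud"])
  expect_identical(de_probes(de), "pass")
  # spike-ins never enter the DE table or set
  expect_false(any(grepl("spike", tab$probe_id)))
})

test_that("raising thresholds never grows the differential set", {
  sim <- generate_dataset(small_gencfg(), seed = 2)
  base <- de_probes(select_differential(sim$expr, hc_config()))
  harder_fc <- de_probes(select_differential(sim$expr, hc_config(fc_min = 1.6)))
  harder_int <- de_probes(select_differential(sim$expr, hc_config(intensity_min = 9.5)))
  expect_true(all(harder_fc %in% base))
  expect_true(all(harder_int %in% base))
  expect_lte(length(harder_fc), length(base))
  expect_lte(length(harder_int), length(base))
})

test_that("per-hybrid counts match brute-force enumeration", {
  set.seed(31)
  lines <- rep(c("F01", "F02", "D01", "D02"), each = 3)
  groups <- c(F01 = "flint", F02 = "flint", D01 = "dent", D02 = "dent")
  x <- matrix(rnorm(15 * 12, 9, 0.1), 15, 12)
  # five probes with distinct pairwise patterns; D02 duplicates F02's profile
  eff <- rbind(c(0, 2, 0, 0), c(2, 0, 0, 0), c(0, 0, 2, 0),
               c(1, 1, 0, 0), c(0, 3, 3, 0))
  for (i in 1:5) x[i, ] <- x[i, ] + rep(eff[i, ], each = 3)
  rownames(x) <- paste0("g", 1:15)
  x <- rbind(x, spike1 = rnorm(12, 5, 0.2), spike2 = rnorm(12, 5, 0.2))
  expr <- toy_expression(x, lines, groups, spike = c("spike1", "spike2"))
  design <- data.frame(hybrid_id = c("F01xD01", "F02xD02"),
                       flint_parent = c("F01", "F02"),
                       dent_parent = c("D01", "D02"))
  cfg <- hc_config()
  de <- select_differential(expr, cfg)
  counts <- per_hybrid_de_counts(de, design, cfg)

  # brute-force oracle: recompute the nested rule per hybrid from scratch
  nest <- nested_pairwise_tests(de$fit, cbind(design$flint_parent, design$dent_parent))
  de_set <- de_probes(de)
  oracle <- sapply(1:2, function(j) {
    q <- bh_bruteforce(nest$p[, j])
    sum(q[match(de_set, rownames(nest$p))] <= cfg$fdr_de &
          nest$abs_log2fc[match(de_set, rownames(nest$p)), j] > log2(cfg$fc_min))
  })
  expect_equal(counts$n_de, as.integer(oracle))
  # counts are bounded by the global DE set size
  expect_true(all(counts$n_de <= length(de_set)))
  expect_equal(attr(counts, "pct_of_probes"),
               100 * mean(counts$n_de) / nrow(de$table))
  # a design pairing two lines with identical profiles counts nothing
  same <- data.frame(hybrid_id = "same", flint_parent = "F01", dent_parent = "F01")
  cnt_same <- per_hybrid_de_counts(de, same, cfg)
  expect_equal(cnt_same$n_de, 0L)
  # a design naming an unknown line errors
  bad <- data.frame(hybrid_id = "h", flint_parent = "F09", dent_parent = "D01")
  expect_error(per_hybrid_de_counts(de, bad, cfg), "F09")
})

test_that("the spike-in calibration diagnostic is reported", {
  sim <- generate_dataset(small_gencfg(), seed = 6)
  de <- select_differential(sim$expr, hc_config())
  expect_true(is.finite(de$spikein_min_q))
  expect_gte(de$spikein_min_q, 0)
  expect_lte(de$spikein_min_q, 1)
})
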