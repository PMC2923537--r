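make_cortab <- function(ids, p, r = 0.5, trait = "PY") {
  data.frame(probe_id = ids, trait = trait, r = r,
             t = NA_real_, p = p, q = pmin(1, p * length(p)),
             undefined = FALSE, stringsAsFactors = FALSE)
}

# Toy chain with exact sample correlations:
#   g1 (step 1) -- 0.95 -- g2 -- 0.95 -- g3, while r(g1, g3) = 0.85 < 0.9;
#   g4 is co-expressed above the gate but fails the step-2 significance gate;
#   g5 is significant but co-expressed with nobody.
toy_chain <- function() {
  coefs <- rbind(
    g1 = c(1, 0, 0, 0, 0),
    g2 = c(0.95, sqrt(1 - 0.95^2), 0, 0, 0),
    g3 = c(0.85, 0.45637, sqrt(1 - 0.85^2 - 0.45637^2), 0, 0),
    g4 = c(0.95, 0, 0, sqrt(1 - 0.95^2), 0),
    g5 = c(0.30, 0, 0, 0, sqrt(1 - 0.3^2))
  )
  L <- exact_cor_rows(coefs, n = 24)
  cors <- make_cortab(rownames(L), p = c(1e-5, 0.005, 0.005, 0.02, 0.005))
  list(L = L, cors = cors)
}

test_that("two-step selection chains transitively through co-expression", {
  fx <- toy_chain()
  expect_equal(cor(fx$L["g1", ], fx$L["g2", ]), 0.95, tolerance = 1e-12)
  expect_equal(cor(fx$L["g2", ], fx$L["g3", ]), 0.95, tolerance = 1e-4)
  expect_equal(cor(fx$L["g1", ], fx$L["g3", ]), 0.85, tolerance = 1e-12)

  sel <- select_trait_genes(fx$cors, fx$L, "yield", hc_config())
  m <- sel$members
  expect_setequal(m$probe_id, c("g1", "g2", "g3"))
  expect_equal(m$step[m$probe_id == "g1"], 1L)
  expect_equal(m$iteration[m$probe_id == "g2"], 1L)
  expect_equal(m$certifier[m$probe_id == "g2"], "g1")
  expect_equal(m$iteration[m$probe_id == "g3"], 2L)
  expect_equal(m$certifier[m$probe_id == "g3"], "g2")
  expect_equal(m$r_to_certifier[m$probe_id == "g3"], 0.95, tolerance = 1e-4)
  expect_equal(sel$n_iterations, 3L)     # final iteration adds nothing

  # the candidate-pool gate: g4 is never added despite r > 0.9 with g2
  expect_false("g4" %in% m$probe_id)
  expect_true(verify_fixpoint(sel, fx$cors, fx$L, hc_config()))
})

test_that("an empty step 1 yields an empty selection", {
  fx <- toy_chain()
  cors <- fx$cors
  cors$p <- pmax(cors$p, 0.001)   # nothing below alpha_step1
  sel <- select_trait_genes(cors, fx$L, "yield", hc_config())
  expect_equal(nrow(sel$members), 0L)
  expect_equal(sel$n_iterations, 0L)
})

test_that("selection is invariant to candidate order and monotone in the gate", {
  sim <- generate_dataset(small_gencfg(), seed = 13)
  L <- compute_midparent(line_means(sim$expr), sim$design)
  set.seed(5)
  keep <- unique(c(sim$truth$modules$probe_id,
                   sample(rownames(L), 150)))
  L <- L[keep, ]
  cors <- correlate_all(L, sim$traits, which = c("PY", "HY"))
  sel <- select_trait_genes(cors, L, "yield", hc_config())

  set.seed(99)
  perm <- sample(nrow(L))
  cors_perm <- cors[sample(nrow(cors)), ]
  sel_perm <- select_trait_genes(cors_perm, L[perm, ], "yield", hc_config())
  expect_setequal(sel$members$probe_id, sel_perm$members$probe_id)
  expect_equal(sel$n_iterations, sel_perm$n_iterations)

  # relaxing the co-expression gate never shrinks the set
  sel_loose <- select_trait_genes(cors, L, "yield", hc_config(r_coexpr = 0.8))
  expect_true(all(sel$members$probe_id %in% sel_loose$members$probe_id))

  # step-1 members are always in the final set, and the set is a fixpoint
  expect_true(all(sel$members$probe_id[sel$members$step == 1L] %in%
                    sel$members$probe_id))
  expect_true(verify_fixpoint(sel, cors, L, hc_config()))

  # removing a step-2 member breaks the fixpoint certificate
  if (any(sel$members$step == 2L)) {
    broken <- sel
    drop <- which(broken$members$step == 2L)[1L]
    broken$members <- broken$members[-drop, ]
    expect_false(verify_fixpoint(broken, cors, L, hc_config()))
  }
})

test_that("gdmc selection gates on PD only", {
  fx <- toy_chain()
  cors_pd <- make_cortab(rownames(fx$L), p = c(1e-5, 0.005, 0.5, 0.5, 0.5),
                         trait = "PD")
  cors_py <- make_cortab(rownames(fx$L), p = rep(1e-6, 5), trait = "PY")
  sel <- select_trait_genes(rbind(cors_pd, cors_py), fx$L, "gdmc", hc_config())
  expect_setequal(sel$members$probe_id, c("g1", "g2"))
})

test_that("interaction accounting flags opposite signs", {
  mk_sel <- function(ids, steps, signs, trait) {
    structure(list(trait = trait,
                   members = data.frame(probe_id = ids, step = steps,
                                        iteration = 0L, r = 0.5, p = 1e-5,
                                        sign = signs, certifier = NA,
                                        r_to_certifier = NA,
                                        stringsAsFactors = FALSE),
                   n_iterations = 1L, thresholds = list()),
              class = "hc_selection")
  }
  a <- mk_sel(c("g1", "g2", "g3"), c(1L, 1L, 2L), c("P", "N", "P"), "yield")
  b <- mk_sel(c("g4", "g5"), c(1L, 1L), c("P", "N"), "gdmc")
  expect_equal(nrow(interaction_genes(a, b)), 0L)

  b2 <- mk_sel(c("g1", "g3"), c(1L, 1L), c("N", "P"), "gdmc")
  inter <- interaction_genes(a, b2)
  s <- attr(inter, "summary")
  expect_equal(s$n_overlap, 2L)
  expect_equal(s$n_opposite, 1L)           # g1 flips, g3 does not
  expect_equal(s$n_step1_both, 1L)         # g3 entered a via step 2
  expect_equal(s$n_step2_any, 1L)
  expect_true(inter$opposite_sign[inter$probe_id == "g1"])
})

test_that("shared causal genes are recovered as opposite-sign interactions", {
  cfg <- small_gencfg(trait_coupling = 0.65)
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    sim <- generate_dataset(cfg, seed = s)
    L <- compute_midparent(line_means(sim$expr), sim$design)
    ids <- unique(sim$truth$modules$probe_id)
    cors <- correlate_all(L[ids, ], sim$traits, which = c("PY", "HY", "PD"))
    sy <- select_trait_genes(cors, L[ids, ], "yield", hc_config())
    sg <- select_trait_genes(cors, L[ids, ], "gdmc", hc_config())
    inter <- interaction_genes(sy, sg)
    tr <- sim$truth$causal
    shared <- intersect(tr$probe_id[tr$trait == "yield"],
                        tr$probe_id[tr$trait == "gdmc"])
    hits <- hits + sum(shared %in% inter$probe_id[inter$opposite_sign])
    total <- total + length(shared)
  }
  expect_gte(hits / total, 0.8)
})

test_that("step 2 catches significant co-members that step 1 misses", {
  cfg <- small_gencfg(trait_coupling = 0.65)
  added <- 0L; total <- 0L
  for (s in 1:15) {
    sim <- generate_dataset(cfg, seed = 100 + s)
    L <- compute_midparent(line_means(sim$expr), sim$design)
    mods <- sim$truth$modules
    cors <- correlate_all(L, sim$traits, which = c("PY", "HY"))
    sel <- select_trait_genes(cors, L, "yield", hc_config())
    yield_ids <- sim$truth$causal$probe_id[sim$truth$causal$trait == "yield"]
    ymods <- unique(mods$module_id[mods$probe_id %in% yield_ids])
    com <- mods$probe_id[mods$role == "comember" & mods$module_id %in% ymods]
    best_p <- vapply(split(cors$p, cors$probe_id), min, numeric(1))
    band <- com[best_p[com] >= 1e-4 & best_p[com] < 0.01]
    total <- total + length(band)
    added <- added + sum(band %in% sel$members$probe_id[sel$members$step == 2L])
  }
  expect_gt(total, 0)
  expect_gte(added / total, 0.5)
})
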