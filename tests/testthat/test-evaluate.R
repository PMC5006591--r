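test_that("z-score matches hand-computed cases", {
  expect_equal(compute_zscore(4, c(1, 2, 3)), 2)      # sd([1,2,3]) = 1
  expect_equal(compute_zscore(2, c(1, 2, 3)), 0)      # equals the mean
  expect_warning(z <- compute_zscore(6, c(5, 5, 5)), "zero spread")
  expect_true(is.na(z))
  expect_error(compute_zscore(1, 2), "at least 2")
})

test_that("population sd and pooled-similar variants are available", {
  expect_equal(compute_zscore(4, c(1, 2, 3), sd_type = "population"),
               2 / (sqrt(2 / 3)))
  zp <- compute_zscore(4, c(1, 2, 3), include_similar = TRUE)
  expect_equal(zp, (4 - 2.5) / sd(c(1, 2, 3, 4)))
})

test_that("z is invariant under affine transforms of all scores", {
  set.seed(5)
  cross <- rnorm(8)
  sim <- 2.5
  z0 <- compute_zscore(sim, cross)
  expect_equal(compute_zscore(100 * sim + 7, 100 * cross + 7), z0)
})

test_that("evaluate_pairset equals a flat-loop recomputation", {
  study <- tiny_study()
  ps <- study$pairset
  gen <- anchor_generic_set()
  mats <- list(blosum62 = gen$blosum62, vt160_syn = gen$vt160_syn)
  res <- evaluate_pairset(ps, mats)
  ids <- names(ps)
  for (mn in names(mats)) {
    for (i in seq_along(ids)) {
      sim <- nw_score(ps[[i]]$s, ps[[i]]$s_prime, mats[[mn]], 10, 1)
      cross <- vapply(setdiff(seq_along(ids), i), function(j)
        nw_score(ps[[i]]$s, ps[[j]]$s_prime, mats[[mn]], 10, 1), numeric(1))
      z <- (sim - mean(cross)) / sd(cross)
      row <- res[res$matrix == mn & res$topology == ids[i], ]
      expect_equal(row$z, z)
      expect_equal(row$similar_score, sim)
    }
  }
  # report totals: |topologies| x |matrices| cells
  expect_equal(nrow(res), length(ids) * length(mats))
})

test_that("z-scores are invariant to consistent 100x scaling of matrix and gaps", {
  study <- tiny_study()
  ps <- study$pairset
  b62 <- anchor_blosum62()
  z1 <- evaluate_pairset(ps, list(m = b62), gap_open = 10, gap_extend = 1)
  z100 <- evaluate_pairset(ps, list(m = 100 * b62), gap_open = 1000,
                           gap_extend = 100)
  expect_equal(z1$z, z100$z)
})

test_that("percent improvement uses the absolute baseline denominator", {
  study <- tiny_study()
  tms <- lapply(names(study$bundles), function(t)
    fit_topology_matrix(study$bundles[[t]], 3, t))
  names(tms) <- names(study$bundles)
  rep <- zscore_report(study$pairset, tms, anchor_blosum62(),
                       weights = c(0, 5, 15))
  pt <- rep$per_topology
  expect_equal(pt$pct_improvement,
               100 * (pt$max_z - pt$best_generic_z) / abs(pt$best_generic_z))
  # worked examples of the convention
  expect_equal(100 * (1.5 - 1.0) / abs(1.0), 50)
  expect_equal(100 * (1.0 - (-0.1)) / abs(-0.1), 1100)
})

test_that("the report's structure matches the benchmark protocol", {
  study <- tiny_study()
  tms <- lapply(names(study$bundles), function(t)
    fit_topology_matrix(study$bundles[[t]], 3, t))
  names(tms) <- names(study$bundles)
  gen <- anchor_generic_set()
  rep <- zscore_report(study$pairset, tms, gen$blosum62, gen[-1],
                       weights = c(0, 2, 8))
  pt <- rep$per_topology
  n <- length(study$pairset)
  expect_equal(nrow(pt), n)
  # weight-0 combined equals the anchor z exactly
  zt <- rep$z_table
  expect_equal(zt$z[zt$matrix == "combined_w0"],
               zt$z[zt$matrix == "blosum62"])
  # improved <=> strictly above every generic
  gens <- c("blosum62", "vt160_syn", "vtml200_syn")
  for (i in seq_len(n)) {
    gz <- vapply(gens, function(g)
      zt$z[zt$matrix == g][i], numeric(1))
    expect_equal(pt$improved[i], pt$max_z[i] > max(gz))
  }
  # best weight reported among the positive grid
  expect_true(all(pt$best_weight %in% c(2, 8)))
  # ratio curve is 1 at weight 0 for every class
  rc <- rep$ratio_curve
  expect_equal(rc$ratio[rc$weight == 0], rep(1, length(unique(rc$class))))
  # cross-score count per topology is |topologies| - 1 by construction
  expect_equal(nrow(zt), (length(gens) + 3) * n)
})

test_that("sweep emits one ratio row per cutoff x weight x class", {
  study <- tiny_study(n_topologies = 4, length = 40)
  sw <- sweep_parameters(study$bundles, study$pairset, cutoffs = c(1, 3),
                         weights = c(0, 5, 10))
  bc <- sw$by_class
  expect_equal(nrow(bc),
               2 * 3 * length(unique(bc$class)))
  expect_equal(length(sw$errors), 0)
  # weight-0 rows are identically ratio 1
  expect_true(all(abs(bc$ratio[bc$weight == 0] - 1) < 1e-12))
  # each (cutoff, weight) cell matches a manual single-run invocation
  tms <- lapply(names(study$bundles), function(t)
    fit_topology_matrix(study$bundles[[t]], 3, t))
  names(tms) <- names(study$bundles)
  rep <- zscore_report(study$pairset, tms, anchor_blosum62(),
                       weights = c(0, 5, 10))
  manual <- rep$ratio_curve
  got <- bc[bc$cutoff == 3, c("class", "weight", "mean_z", "ratio")]
  rownames(got) <- NULL
  rownames(manual) <- NULL
  expect_equal(got, manual[, c("class", "weight", "mean_z", "ratio")])
})

test_that("missing training bundles are a usage error", {
  study <- tiny_study(n_topologies = 4, length = 40)
  expect_error(sweep_parameters(study$bundles[-1], study$pairset, 3),
               "no training bundle")
})
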