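make_toy_msta <- function(seqs, rows, coords) {
  chains <- lapply(seq_along(seqs), function(i)
    structure_chain(paste0("s", i), strsplit(seqs[i], "")[[1]], coords[[i]]))
  msta(chains, rows)
}

test_that("identical superposed structures give diagonal-only counts", {
  xyz <- cbind(c(0, 3.8, 7.6), 0, 0)
  m <- make_toy_msta(c("AGC", "AGC"), c("AGC", "AGC"), list(xyz, xyz))
  cs <- count_substitutions(m, 3)
  expect_equal(cs$table["A", "A"], 1L)
  expect_equal(cs$table["G", "G"], 1L)
  expect_equal(cs$table["C", "C"], 1L)
  expect_equal(sum(cs$table[, "-"]), 0L)
  expect_equal(cs$n_events, 3L)
})

test_that("residue pairs beyond the cutoff count as gaps, not substitutions", {
  m <- make_toy_msta(c("A", "R"), c("A", "R"),
                     list(cbind(0, 0, 0), cbind(3.5, 0, 0)))
  cs <- count_substitutions(m, 3)
  expect_equal(cs$table["A", "R"], 0L)
  expect_equal(cs$table["A", "-"], 1L)
  expect_equal(cs$table["R", "-"], 1L)
  # same column within a larger cutoff becomes a substitution
  cs2 <- count_substitutions(m, 4)
  expect_equal(cs2$table["A", "R"], 1L)
  expect_equal(cs2$table["R", "A"], 1L)
  expect_equal(sum(cs2$table[, "-"]), 0L)
})

test_that("single-sided columns charge one gap to the residue present", {
  xyz1 <- cbind(c(0, 3.8), 0, 0)
  m <- make_toy_msta(c("AG", "A"), c("AG", "A-"),
                     list(xyz1, cbind(0, 0, 0)))
  cs <- count_substitutions(m, 3)
  expect_equal(cs$table["A", "A"], 1L)
  expect_equal(cs$table["G", "-"], 1L)
  expect_equal(cs$n_events, 2L)
})

test_that("counting matches the brute-force pair-by-column oracle", {
  for (seed in 1:6) {
    fam <- make_family(family_spec(n_structures = 4, length = 10,
                                   seed = seed, indel_rate = 0.15,
                                   jitter_sigma = 1.5))
    for (cutoff in c(1, 3, 8)) {
      cs <- count_substitutions(fam$msta, cutoff)
      expect_identical(cs$table, brute_count_table(fam, cutoff))
    }
  }
})

test_that("X residues are unalignable and contribute to no count cell", {
  xyz <- cbind(c(0, 3.8, 7.6), 0, 0)
  m <- make_toy_msta(c("AXC", "AGC"), c("AXC", "AGC"), list(xyz, xyz))
  cs <- count_substitutions(m, 3)
  # column 2: s1 has X (absent) -> G of s2 pairs with GAP
  expect_equal(cs$table["G", "-"], 1L)
  expect_equal(cs$table["G", "G"], 0L)
  expect_equal(cs$n_events, 3L)
})

test_that("event conservation and cutoff monotonicity hold on seeded fixtures", {
  for (seed in 1:10) {
    fam <- make_family(family_spec(n_structures = 3, length = 30,
                                   seed = seed, indel_rate = 0.1))
    idx <- fam$msta$index
    prev_aa <- NULL; prev_gap <- NULL
    for (cutoff in c(0.5, 1.5, 3, 6, 50)) {
      cs <- count_substitutions(fam$msta, cutoff)
      tab <- cs$table
      aa_events <- (sum(tab[1:20, 1:20]) + sum(diag(tab[1:20, 1:20]))) / 2
      both_gap_events <- (sum(tab[1:20, "-"]) - one_sided_events(idx)) / 2
      expect_equal(aa_events + both_gap_events + one_sided_events(idx),
                   cs$n_events)
      expect_equal(cs$table, t(cs$table))
      expect_equal(tab["-", "-"], 0L)
      if (!is.null(prev_aa)) {
        expect_true(all(tab[1:20, 1:20] >= prev_aa))
        expect_true(all(tab[1:20, "-"] <= prev_gap))
      }
      prev_aa <- tab[1:20, 1:20]
      prev_gap <- tab[1:20, "-"]
    }
    # at a cutoff beyond any inter-pair distance, the only gap events left
    # are one-sided columns
    cs_inf <- count_substitutions(fam$msta, 1e6)
    one_sided <- 0L
    ns <- nrow(idx)
    for (i in seq_len(ns - 1)) for (j in seq(i + 1, ns)) {
      a <- !is.na(idx[i, ]); b <- !is.na(idx[j, ])
      one_sided <- one_sided + sum(xor(a, b))
    }
    expect_equal(sum(cs_inf$table[1:20, "-"]), one_sided)
  }
})

test_that("exact event-count identity holds against the alignment index", {
  fam <- make_family(family_spec(n_structures = 4, length = 40, seed = 3,
                                 indel_rate = 0.1))
  idx <- fam$msta$index
  ns <- nrow(idx)
  expected <- 0L
  for (i in seq_len(ns - 1)) for (j in seq(i + 1, ns)) {
    a <- !is.na(idx[i, ]); b <- !is.na(idx[j, ])
    expected <- expected + sum(a | b)
  }
  cs <- count_substitutions(fam$msta, 3)
  expect_equal(cs$n_events, expected)  # no X residues in generated families
})

test_that("normalization follows the replacement-ratio rule", {
  aa <- rownames(count_substitutions(
    make_family(family_spec(seed = 1, length = 10))$msta, 3)$table)
  tab <- matrix(0L, 21, 21, dimnames = list(aa, aa))
  tab["C", "R"] <- tab["R", "C"] <- 2L
  tab["C", "C"] <- 3L
  tab["C", "-"] <- tab["-", "C"] <- 1L
  hm <- normalize_counts(tab)
  # raw M[C][R] = 2 / (3 + 1) = 0.5; reverse direction R->C has a zero
  # denominator (R was only ever replaced by C) -> 0; symmetrized mean 0.25
  expect_equal(hm$values["C", "R"], (0.5 + 0) / 2)
  expect_equal(hm$values["R", "C"], hm$values["C", "R"])
  # gap column: C -> gap = 1 / (2 + 3) = 0.2
  expect_equal(hm$gap_row[["C"]], 0.2)
})

test_that("all-zero counts normalize to an all-zero matrix", {
  aa <- c(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"), "-")
  tab <- matrix(0L, 21, 21, dimnames = list(aa, aa))
  hm <- normalize_counts(tab)
  expect_true(all(hm$values == 0))
  expect_true(all(hm$gap_row == 0))
})

test_that("normalization equals independent recomputation on random tables", {
  set.seed(99)
  for (rep in 1:5) {
    fam <- make_family(family_spec(n_structures = 4, length = 25,
                                   seed = 200 + rep))
    tab <- count_substitutions(fam$msta, 3)$table
    hm <- normalize_counts(tab)
    oracle <- brute_normalize(tab)
    expect_equal(hm$values, oracle$values)
    expect_equal(hm$gap_row, oracle$gap_row, ignore_attr = TRUE)
  }
})

test_that("topology aggregation sums then max-normalizes to 1", {
  fam1 <- make_family(family_spec(seed = 31, length = 40))
  fam2 <- make_family(family_spec(seed = 32, length = 40))
  h1 <- normalize_counts(count_substitutions(fam1$msta, 3))
  h2 <- normalize_counts(count_substitutions(fam2$msta, 3))
  tm <- aggregate_topology(list(h1, h2), "1.10.40")
  total <- h1$values + h2$values
  expect_equal(max(tm$values), 1)
  expect_equal(tm$values, total / max(total))
  expect_equal(tm$gap_row, (h1$gap_row + h2$gap_row) / max(total))
  expect_equal(tm$n_homology_levels, 2L)
})

test_that("a single off-scale entry is rescaled so the max is exactly 1", {
  h <- normalize_counts(count_substitutions(
    make_family(family_spec(seed = 41, length = 30))$msta, 3))
  h$values[] <- 0
  h$values["L", "I"] <- h$values["I", "L"] <- 0.25
  h$gap_row[] <- 0.1
  tm <- aggregate_topology(list(h), "t")
  expect_equal(tm$values["L", "I"], 1)
  expect_equal(unique(tm$gap_row), 0.4)
})

test_that("fit_topology_matrix is count -> normalize -> aggregate", {
  fams <- lapply(51:52, function(s)
    make_family(family_spec(seed = s, length = 40)))
  tm <- fit_topology_matrix(lapply(fams, `[[`, "msta"), cutoff = 3,
                            topology_id = "1.10.8")
  byhand <- aggregate_topology(lapply(fams, function(f)
    normalize_counts(count_substitutions(f$msta, 3))), "1.10.8")
  expect_equal(tm$values, byhand$values)
  expect_equal(tm$topology_id, "1.10.8")
  expect_equal(coef(tm), tm$values)
})

test_that("usage errors are raised for degenerate inputs", {
  fam <- make_family(family_spec(seed = 1, length = 20))
  expect_error(count_substitutions(fam$msta, -1), "positive")
  expect_error(aggregate_topology(list()), "at least one")
})
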