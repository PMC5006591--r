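#' Specification for a synthetic superposed structure family
#'
#' Describes one synthetic protein family: an ancestor sequence whose
#' descendants mutate with a planted topology-specific substitution
#' preference, threaded onto an ideal alpha-helix backbone (rise 1.5 A per
#' residue, 100 degree turn, radius 2.3 A — textbook helix constants) with
#' independent Gaussian coordinate jitter emulating superposition error.
#' Same spec + seed always yields bit-identical output.
#'
#' @param n_structures number of structures in the family (>= 2).
#' @param length number of residues in the ancestor (>= 3).
#' @param jitter_sigma per-coordinate Gaussian jitter sd in Angstroms.
#' @param background_sub_rate per-site substitution probability per
#'   descendant.
#' @param preferred_pairs list of `c(aa1, aa2, factor)` triples: exchanges
#'   between aa1 and aa2 are enriched by `factor` (>= 1) over background,
#'   in both directions.
#' @param indel_rate per-site deletion probability per descendant (deletions
#'   relative to the ancestor create alignment gaps).
#' @param seed integer RNG seed.
#' @param topology_id,class labels carried into downstream reports; `class`
#'   is one of `"mainly-alpha"`, `"mainly-beta"`, `"alpha-beta"`.
#' @return a `family_spec` object.
#' @export
family_spec <- function(n_structures = 4L, length = 120L, jitter_sigma = 0.5,
                        background_sub_rate = 0.3,
                        preferred_pairs = list(c("E", "K", 5)),
                        indel_rate = 0.05, seed = 1L,
                        topology_id = "1.10.1", class = "mainly-alpha") {
  if (length < 3L) stop_usage("'length' must be at least 3")
  if (n_structures < 2L) stop_usage("'n_structures' must be at least 2")
  if (background_sub_rate < 0 || background_sub_rate > 1 ||
      indel_rate < 0 || indel_rate > 1)
    stop_usage("rates must lie in [0, 1]")
  for (p in preferred_pairs) {
    if (length(p) != 3L || !(p[1] %in% AA20) || !(p[2] %in% AA20) ||
        as.numeric(p[3]) < 1)
      stop_usage("preferred_pairs entries must be c(aa1, aa2, factor >= 1)")
  }
  structure(list(n_structures = as.integer(n_structures),
                 length = as.integer(length),
                 jitter_sigma = jitter_sigma,
                 background_sub_rate = background_sub_rate,
                 preferred_pairs = preferred_pairs,
                 indel_rate = indel_rate, seed = as.integer(seed),
                 topology_id = as.character(topology_id),
                 class = match.arg(class, c("mainly-alpha", "mainly-beta",
                                            "alpha-beta"))),
            class = "family_spec")
}

# Ideal alpha-helix C-alpha coordinates for n consecutive positions.
helix_backbone <- function(n, rise = 1.5, turn_deg = 100, radius = 2.3) {
  ang <- (seq_len(n) - 1L) * turn_deg * pi / 180
  cbind(x = radius * cos(ang), y = radius * sin(ang),
        z = (seq_len(n) - 1L) * rise)
}

# Draw a replacement for `aa` from the background distribution with the
# spec's preferred exchanges enriched.
mutate_residue <- function(aa, preferred_pairs) {
  others <- setdiff(AA20, aa)
  w <- setNames(rep(1, length(others)), others)
  for (p in preferred_pairs) {
    if (p[1] == aa && p[2] %in% others) w[p[2]] <- as.numeric(p[3])
    if (p[2] == aa && p[1] %in% others) w[p[1]] <- as.numeric(p[3])
  }
  sample(others, 1L, prob = w)
}

# Ancestor sequence is a function of the spec seed alone, so that held-out
# test pairs (make_pairset) descend from the same ancestor as the training
# structures without sharing any other randomness.
family_ancestor <- function(spec) {
  with_seed(spec$seed, sample(AA20, spec$length, replace = TRUE))
}

# Mutate the ancestor at per-site `rate`; returns the descendant sequence.
descend <- function(ancestor, rate, preferred_pairs) {
  s <- ancestor
  hit <- runif(length(s)) < rate
  for (k in which(hit)) s[k] <- mutate_residue(s[k], preferred_pairs)
  s
}

#' Generate a synthetic superposed structure family
#'
#' Samples an ancestor sequence, derives `n_structures` descendants under the
#' planted substitution preferences, deletes sites at `indel_rate` (creating
#' alignment gaps), and places every retained residue on the shared ideal
#' helix backbone with Gaussian jitter. The output satisfies the consistency
#' contract of [msta]/[load_msta]: rows are mutually aligned by construction
#' (all structures index the same ancestral columns).
#'
#' @param spec a [family_spec].
#' @return list with `chains` (list of [structure_chain]), `rows` (gapped
#'   alignment strings), `msta` (the assembled [msta]), `ancestor`, `spec`.
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  ancestor <- family_ancestor(spec)
  L <- spec$length
  backbone <- helix_backbone(L)
  with_seed(spec$seed + 1L, {
    chains <- vector("list", spec$n_structures)
    rows <- character(spec$n_structures)
    for (i in seq_len(spec$n_structures)) {
      s <- descend(ancestor, spec$background_sub_rate, spec$preferred_pairs)
      keep <- runif(L) >= spec$indel_rate
      if (sum(keep) < 1L) keep[1] <- TRUE
      row <- s
      row[!keep] <- GAP
      ca <- backbone[keep, , drop = FALSE] +
        matrix(rnorm(3L * sum(keep), sd = spec$jitter_sigma), ncol = 3L)
      id <- sprintf("%s_h%02d", gsub("[^0-9A-Za-z]", "_", spec$topology_id), i)
      chains[[i]] <- structure_chain(id, s[keep], ca)
      rows[i] <- paste(row, collapse = "")
    }
    list(chains = chains, rows = rows, msta = msta(chains, rows),
         ancestor = paste(ancestor, collapse = ""), spec = spec)
  })
}

#' Generate held-out test pairs for a set of synthetic families
#'
#' For each family, two fresh descendants of the family ancestor are drawn at
#' the requested per-site divergence; they form the structurally-similar pair
#' for that topology. These sequences use RNG streams disjoint from
#' [make_family], so they never appear in the matrix-training alignments.
#' The pairwise identity of each similar pair is checked against
#' `identity_ceiling` (default 30 percent, the remote-homology regime); a
#' warning reports any pair above it.
#'
#' @param specs list of [family_spec] objects (>= 3, so every query has at
#'   least two cross pairs).
#' @param divergence per-site substitution rate applied independently to each
#'   held-out descendant.
#' @param identity_ceiling maximum tolerated fractional identity of a
#'   similar pair.
#' @return a `pairset`: list of per-topology entries `topology_id`, `class`,
#'   `s`, `s_prime`, `identity`.
#' @export
make_pairset <- function(specs, divergence = 0.7, identity_ceiling = 0.3) {
  if (length(specs) < 3L) stop_usage("need at least 3 family specs")
  entries <- lapply(specs, function(spec) {
    stopifnot(inherits(spec, "family_spec"))
    ancestor <- family_ancestor(spec)
    with_seed(spec$seed + 2L, {
      s1 <- descend(ancestor, divergence, spec$preferred_pairs)
      s2 <- descend(ancestor, divergence, spec$preferred_pairs)
      ident <- mean(s1 == s2)
      if (ident >= identity_ceiling)
        warning("similar pair for '", spec$topology_id, "' has identity ",
                sprintf("%.1f%%", 100 * ident), " (ceiling ",
                sprintf("%.0f%%", 100 * identity_ceiling), ")",
                call. = FALSE)
      list(topology_id = spec$topology_id, class = spec$class,
           s = paste(s1, collapse = ""), s_prime = paste(s2, collapse = ""),
           identity = ident)
    })
  })
  ids <- vapply(entries, `[[`, character(1), "topology_id")
  if (anyDuplicated(ids)) stop_usage("duplicate topology ids in specs")
  names(entries) <- ids
  structure(entries, class = "pairset")
}

#' @export
print.pairset <- function(x, ...) {
  cat("<pairset> ", length(x), " topologies\n", sep = "")
  for (e in x)
    cat(sprintf("  %-12s %-12s identity %.1f%%\n", e$topology_id, e$class,
                100 * e$identity))
  invisible(x)
}

# Residue-exchange pool used to give each synthetic topology its own planted
# preference (chemically plausible exchanges).
PREFERRED_POOL <- list(
  c("E", "K"), c("D", "E"), c("I", "L"), c("I", "V"), c("K", "R"),
  c("S", "T"), c("F", "Y"), c("N", "D"), c("Q", "E"), c("A", "S"),
  c("M", "L"), c("H", "Q"), c("W", "F"), c("C", "S"), c("G", "A"),
  c("T", "A"), c("V", "M"), c("R", "Q"), c("Y", "H"), c("P", "A"))

#' Build a full synthetic study: training families plus held-out pairs
#'
#' Creates `n_topologies` synthetic topologies, each with its own planted
#' residue-exchange preference (drawn from a fixed pool of chemically
#' plausible exchanges), `n_homology` training families per topology, and a
#' held-out [make_pairset] at the requested divergence. This is the study
#' design used by the package's discrimination benchmark.
#'
#' @param n_topologies number of topologies (>= 3).
#' @param n_homology homology-level families per topology.
#' @param seed master seed; per-family seeds are derived deterministically.
#' @param enrichment planted-exchange enrichment factor.
#' @param divergence held-out pair divergence (see [make_pairset]).
#' @param ... further arguments passed to [family_spec] (e.g. `length`,
#'   `n_structures`, `jitter_sigma`).
#' @return list with `specs`, `bundles` (named list: topology id -> list of
#'   training [msta]s), `pairset`.
#' @export
make_study <- function(n_topologies = 10L, n_homology = 1L, seed = 1L,
                       enrichment = 5, divergence = 0.7, ...) {
  if (n_topologies < 3L) stop_usage("need at least 3 topologies")
  if (n_topologies > length(PREFERRED_POOL))
    stop_usage("at most ", length(PREFERRED_POOL), " topologies supported")
  classes <- rep(c("mainly-alpha", "mainly-beta", "alpha-beta"),
                 length.out = n_topologies)
  specs <- vector("list", n_topologies)
  bundles <- vector("list", n_topologies)
  for (i in seq_len(n_topologies)) {
    pp <- PREFERRED_POOL[[i]]
    tid <- sprintf("%d.10.%d", match(classes[i], c("mainly-alpha",
                                                   "mainly-beta",
                                                   "alpha-beta")), i)
    specs[[i]] <- family_spec(seed = seed * 1000L + i * 10L,
                              preferred_pairs = list(c(pp[1], pp[2],
                                                       enrichment)),
                              topology_id = tid, class = classes[i], ...)
    bundles[[i]] <- lapply(seq_len(n_homology), function(h) {
      hs <- specs[[i]]
      hs$seed <- hs$seed + h - 1L
      make_family(hs)$msta
    })
  }
  names(bundles) <- vapply(specs, `[[`, character(1), "topology_id")
  list(specs = specs, bundles = bundles,
       pairset = make_pairset(specs, divergence = divergence))
}

#' Synthetic generic anchor matrices
#'
#' Returns the three generic matrices used by the benchmark: the real
#' Blosum62 plus two deterministic synthetic generics (rescaled Blosum62
#' variants, labelled `_syn`) standing in for evolutionary-distance-aware
#' matrices of the VT family. The synthetic generics differ from Blosum62 in
#' their score-to-gap-penalty ratio, which is what matters to the benchmark's
#' best-generic baseline.
#'
#' @return named list of three labelled 24x24 integer matrices.
#' @export
anchor_generic_set <- function() {
  b <- anchor_blosum62()
  vt <- round(1.15 * b); attr(vt, "name") <- "vt160_syn"
  vtml <- round(0.85 * b); attr(vtml, "name") <- "vtml200_syn"
  list(blosum62 = b, vt160_syn = vt, vtml200_syn = vtml)
}

#' Write a family bundle to disk (PDB + aligned FASTA)
#'
#' Serializes a generated family as Mustang-style output: one PDB file per
#' structure (CA-only ATOM records, already in the common frame) and one
#' gapped FASTA alignment, so the round trip through [load_msta] can be
#' exercised.
#'
#' @param fam output of [make_family].
#' @param dir output directory (created if needed).
#' @return invisibly, list with `fasta` and `pdbs` paths.
#' @export
write_family_bundle <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdbs <- character(length(fam$chains))
  for (i in seq_along(fam$chains)) {
    ch <- fam$chains[[i]]
    path <- file.path(dir, paste0(ch$id, ".pdb"))
    resid3 <- vapply(ch$seq, function(a)
      if (a == "X") "UNK" else bio3d::aa123(a), character(1))
    bio3d::write.pdb(file = path, xyz = as.numeric(t(ch$ca)),
                     resno = seq_along(ch$seq), resid = resid3,
                     elety = rep("CA", length(ch$seq)),
                     chain = rep("A", length(ch$seq)))
    pdbs[i] <- path
  }
  fasta <- file.path(dir, "alignment.fasta")
  ids <- vapply(fam$chains, `[[`, character(1), "id")
  writeLines(as.vector(rbind(paste0(">", ids), fam$rows)), fasta)
  invisible(list(fasta = fasta, pdbs = pdbs))
}
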