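# Independent oracles used across the suite. These deliberately share no code
# with the package internals they check.

# Exhaustive enumeration of every global alignment of a and b; the affine
# cost of each maximal gap run of length k is open + k * ext. Feasible for
# sequences up to length ~6.
enum_align_score <- function(a, b, m, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  if (length(av) == 0L && length(bv) == 0L) return(0)
  best <- -Inf
  rec <- function(i, j, ops) {
    if (i > length(av) && j > length(bv)) {
      sc <- 0
      r <- rle(ops)
      ii <- 0; jj <- 0
      for (g in seq_along(r$lengths)) {
        op <- r$values[g]; len <- r$lengths[g]
        if (op == "M") {
          for (q in seq_len(len)) {
            ii <- ii + 1; jj <- jj + 1
            sc <- sc + m[av[ii], bv[jj]]
          }
        } else {
          sc <- sc - (open + len * ext)
          if (op == "X") ii <- ii + len else jj <- jj + len
        }
      }
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) rec(i + 1, j + 1, c(ops, "M"))
    if (i <= length(av)) rec(i + 1, j, c(ops, "X"))
    if (j <= length(bv)) rec(i, j + 1, c(ops, "Y"))
  }
  rec(1L, 1L, character(0))
  best
}

# Brute-force substitution/gap counting straight off the gapped rows and
# chain coordinates, one (pair, column) event at a time.
brute_count_table <- function(fam, cutoff) {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  labs <- c(aa20, "-")
  tab <- matrix(0L, 21, 21, dimnames = list(labs, labs))
  rows <- lapply(fam$rows, function(r) strsplit(r, "")[[1]])
  ns <- length(rows)
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      ri <- rows[[i]]; rj <- rows[[j]]
      pi <- 0L; pj <- 0L
      for (col in seq_along(ri)) {
        ai <- ri[col]; aj <- rj[col]
        if (ai != "-") pi <- pi + 1L
        if (aj != "-") pj <- pj + 1L
        present_i <- ai != "-" && ai != "X"
        present_j <- aj != "-" && aj != "X"
        if (present_i && present_j) {
          d <- sqrt(sum((fam$chains[[i]]$ca[pi, ] -
                         fam$chains[[j]]$ca[pj, ])^2))
          if (d <= cutoff) {
            tab[ai, aj] <- tab[ai, aj] + 1L
            if (ai != aj) tab[aj, ai] <- tab[aj, ai] + 1L
          } else {
            tab[ai, "-"] <- tab[ai, "-"] + 1L; tab["-", ai] <- tab["-", ai] + 1L
            tab[aj, "-"] <- tab[aj, "-"] + 1L; tab["-", aj] <- tab["-", aj] + 1L
          }
        } else if (present_i) {
          tab[ai, "-"] <- tab[ai, "-"] + 1L; tab["-", ai] <- tab["-", ai] + 1L
        } else if (present_j) {
          tab[aj, "-"] <- tab[aj, "-"] + 1L; tab["-", aj] <- tab["-", aj] + 1L
        }
      }
    }
  }
  tab
}

# Normalization recomputed cell by cell from the definition.
brute_normalize <- function(tab) {
  aa20 <- rownames(tab)[1:20]
  raw <- tab * 0
  for (a in rownames(tab)) {
    for (b in colnames(tab)) {
      denom <- sum(tab[a, setdiff(colnames(tab), b)])
      raw[a, b] <- if (denom > 0) tab[a, b] / denom else 0
    }
  }
  block <- raw[aa20, aa20]
  list(values = (block + t(block)) / 2, gap_row = raw[aa20, "-"])
}

# Tiny hand-rolled PDB writer for fixtures (fixed-width ATOM records).
write_tiny_pdb <- function(path, resid, x, y, z, elety = "CA",
                           restype = NULL) {
  if (is.null(restype)) restype <- rep("ALA", length(x))
  lines <- vapply(seq_along(x), function(i)
    sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, elety, restype[i], resid[i], x[i], y[i], z[i]), character(1))
  writeLines(c(lines, "END"), path)
  path
}

# Number of (pair, column) events where exactly one structure has a residue.
one_sided_events <- function(idx) {
  ns <- nrow(idx)
  total <- 0L
  for (i in seq_len(ns - 1)) for (j in seq(i + 1, ns)) {
    total <- total + sum(xor(!is.na(idx[i, ]), !is.na(idx[j, ])))
  }
  total
}

# Canonical small study used by the evaluation tests.
tiny_study <- function(seed = 11, n_topologies = 5, n_homology = 2,
                       length = 60) {
  make_study(n_topologies = n_topologies, n_homology = n_homology,
             seed = seed, length = length)
}
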