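#' Count substitutions and gaps in a superposed multi-structure alignment
#'
#' For every unordered pair of structures and every alignment column, a pair
#' of residues whose C-alpha atoms lie within `cutoff` Angstroms counts as a
#' substitution (symmetric cell of the 21x21 table, diagonal for conserved
#' positions). If the two residues are further apart than the cutoff, or only
#' one structure has a residue in the column, the event is recorded against
#' the GAP class instead: one (residue, GAP) increment per residue present.
#' Columns where both structures are gapped contribute nothing. `"X"` cells
#' (non-standard residues) are unalignable and are treated as absent.
#'
#' @param m an [msta] with at least two structures.
#' @param cutoff C-alpha distance cutoff in Angstroms (> 0). Typical values:
#'   3 for mainly-alpha and mainly-beta folds, 4 for alpha-beta.
#' @return an object of class `subst_counts`: list with `table` (symmetric
#'   21x21 integer matrix, labels `c(AA20, "-")`), `n_events`,
#'   `n_pairs_examined` and `cutoff`.
#' @export
count_substitutions <- function(m, cutoff) {
  if (!inherits(m, "msta")) stop_usage("'m' must be an msta object")
  ns <- nrow(m$index)
  if (ns < 2L) stop_usage("need at least 2 structures, got ", ns)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop_usage("'cutoff' must be a single positive distance in Angstroms")

  labs <- c(AA20, GAP)
  tab <- matrix(0L, 21L, 21L, dimnames = list(labs, labs))
  n_events <- 0L
  ncolm <- ncol(m$index)
  # per-structure: aa code and coordinates mapped to alignment columns
  aa_cols <- matrix(NA_character_, ns, ncolm)
  xyz_cols <- vector("list", ns)
  for (i in seq_len(ns)) {
    idx <- m$index[i, ]
    has <- !is.na(idx)
    aa <- rep(NA_character_, ncolm)
    aa[has] <- m$chains[[i]]$seq[idx[has]]
    aa[!is.na(aa) & aa == "X"] <- NA  # unalignable, treated as absent
    aa_cols[i, ] <- aa
    xyz <- matrix(NA_real_, ncolm, 3L)
    xyz[has, ] <- m$chains[[i]]$ca[idx[has], , drop = FALSE]
    xyz_cols[[i]] <- xyz
  }

  for (i in seq_len(ns - 1L)) {
    for (j in seq(i + 1L, ns)) {
      a <- aa_cols[i, ]; b <- aa_cols[j, ]
      both <- !is.na(a) & !is.na(b)
      one_a <- !is.na(a) & is.na(b)
      one_b <- is.na(a) & !is.na(b)
      if (any(both)) {
        d2 <- rowSums((xyz_cols[[i]][both, , drop = FALSE] -
                       xyz_cols[[j]][both, , drop = FALSE])^2)
        near <- d2 <= cutoff^2
        for (k in which(near)) {
          ai <- a[both][k]; bj <- b[both][k]
          tab[ai, bj] <- tab[ai, bj] + 1L
          if (ai != bj) tab[bj, ai] <- tab[bj, ai] + 1L
        }
        for (k in which(!near)) {
          ai <- a[both][k]; bj <- b[both][k]
          tab[ai, GAP] <- tab[ai, GAP] + 1L; tab[GAP, ai] <- tab[GAP, ai] + 1L
          tab[bj, GAP] <- tab[bj, GAP] + 1L; tab[GAP, bj] <- tab[GAP, bj] + 1L
        }
      }
      for (aa in a[one_a]) {
        tab[aa, GAP] <- tab[aa, GAP] + 1L; tab[GAP, aa] <- tab[GAP, aa] + 1L
      }
      for (aa in b[one_b]) {
        tab[aa, GAP] <- tab[aa, GAP] + 1L; tab[GAP, aa] <- tab[GAP, aa] + 1L
      }
      n_events <- n_events + sum(both) + sum(one_a) + sum(one_b)
    }
  }
  structure(list(table = tab, n_events = n_events,
                 n_pairs_examined = ns * (ns - 1L) %/% 2L,
                 cutoff = cutoff),
            class = "subst_counts")
}

#' @export
print.subst_counts <- function(x, ...) {
  cat("<subst_counts> cutoff ", x$cutoff, " A, ",
      x$n_events, " events over ", x$n_pairs_examined,
      " structure pair(s)\n", sep = "")
  invisible(x)
}

#' Normalize a substitution count table
#'
#' Each count C(a,b) is divided by the number of times a was replaced by
#' anything other than b (including conserved a-a events and a-GAP events).
#' The raw ratio matrix is asymmetric; the 20x20 block is symmetrized by the
#' arithmetic mean (M + t(M))/2. The GAP column is normalized by the same
#' rule and carried alongside as metadata (`gap_row`).
#'
#' @param counts a `subst_counts` object (or bare 21x21 labelled matrix).
#' @return list with `values` (symmetric 20x20), `gap_row` (length-20), and
#'   `cutoff`; class `homology_matrix`.
#' @export
normalize_counts <- function(counts) {
  tab <- if (inherits(counts, "subst_counts")) counts$table else counts
  labs <- c(AA20, GAP)
  if (!identical(dim(tab), c(21L, 21L)) && !identical(dim(tab), c(21, 21)))
    stop_usage("expected a 21x21 count table")
  raw <- matrix(0, 21L, 21L, dimnames = list(labs, labs))
  rs <- rowSums(tab)
  for (a in labs) {
    denom <- rs[a] - tab[a, ]          # sum over y != b of C[a,y], per b
    nz <- denom > 0
    raw[a, nz] <- tab[a, nz] / denom[nz]
  }
  block <- raw[AA20, AA20]
  values <- (block + t(block)) / 2
  structure(list(values = values, gap_row = raw[AA20, GAP],
                 cutoff = if (inherits(counts, "subst_counts")) counts$cutoff
                          else NA_real_),
            class = "homology_matrix")
}

#' Aggregate homology-level matrices into a topology-level matrix
#'
#' Element-wise sum of the normalized homology-level matrices, then the whole
#' table is scaled so the maximum of the 20x20 block equals 1 (gap row scaled
#' by the same factor). An all-zero sum yields an all-zero matrix with a
#' warning.
#'
#' @param hmats list of `homology_matrix` objects from [normalize_counts].
#' @param topology_id CATH T-level label (e.g. `"1.10.40"`).
#' @return a `topology_matrix` object; see [fit_topology_matrix].
#' @export
aggregate_topology <- function(hmats, topology_id = "topology") {
  if (length(hmats) == 0L) stop_usage("need at least one homology-level matrix")
  total <- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
  gap <- setNames(numeric(20L), AA20)
  cutoffs <- numeric(0)
  for (h in hmats) {
    if (!inherits(h, "homology_matrix"))
      stop_usage("all elements must be homology_matrix objects")
    total <- total + h$values
    gap <- gap + h$gap_row
    cutoffs <- c(cutoffs, h$cutoff)
  }
  mx <- max(total)
  if (mx > 0) {
    total <- total / mx
    gap <- gap / mx
  } else {
    warning("all-zero topology matrix for '", topology_id, "'", call. = FALSE)
  }
  structure(list(topology_id = as.character(topology_id), values = total,
                 gap_row = gap, n_homology_levels = length(hmats),
                 cutoff = if (length(unique(cutoffs)) == 1L) cutoffs[1]
                          else NA_real_),
            class = "topology_matrix")
}

#' Fit a topology-level substitution matrix from structure alignments
#'
#' The estimator at the heart of the package: each homology-level
#' multi-structure alignment is reduced to a substitution/gap count table
#' under the C-alpha distance cutoff ([count_substitutions]), normalized to
#' replacement ratios ([normalize_counts]), and the homology-level matrices
#' are summed and max-normalized into a single topology-level matrix
#' ([aggregate_topology]). Normalization precedes summation so that large
#' families do not dominate purely by pair count.
#'
#' @param mstas a single [msta] or a list of them, one per homology level of
#'   the topology.
#' @param cutoff C-alpha distance cutoff in Angstroms; see
#'   [count_substitutions].
#' @param topology_id label for the fitted topology.
#' @return an object of class `topology_matrix`: `values` (20x20, entries in
#'   [0,1], max 1 when nonzero), `gap_row`, `topology_id`,
#'   `n_homology_levels`, `cutoff`.
#' @examples
#' fam <- make_family(family_spec(n_structures = 3, length = 40, seed = 1))
#' tm <- fit_topology_matrix(fam$msta, cutoff = 3)
#' tm
#' coef(tm)[1:4, 1:4]
#' @export
fit_topology_matrix <- function(mstas, cutoff, topology_id = "topology") {
  if (inherits(mstas, "msta")) mstas <- list(mstas)
  if (length(mstas) == 0L) stop_usage("no homology-level alignments supplied")
  hmats <- lapply(mstas, function(m) normalize_counts(count_substitutions(m, cutoff)))
  aggregate_topology(hmats, topology_id)
}

#' @export
print.topology_matrix <- function(x, ...) {
  cat("<topology_matrix> ", x$topology_id, " (cutoff ",
      format(x$cutoff), " A, ", x$n_homology_levels,
      " homology level(s))\n", sep = "")
  nz <- sum(x$values > 0)
  cat("  20x20 block: ", nz, " nonzero cells, max ",
      format(max(x$values), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary topology_matrix
summary.topology_matrix <- function(object, n = 5, ...) {
  v <- object$values
  off <- v
  diag(off) <- NA
  ord <- order(off, decreasing = TRUE, na.last = NA)
  pairs <- arrayInd(ord, dim(off))
  keep <- pairs[, 1] < pairs[, 2]
  pairs <- pairs[keep, , drop = FALSE][seq_len(min(n, sum(keep))), , drop = FALSE]
  top <- data.frame(a = AA20[pairs[, 1]], b = AA20[pairs[, 2]],
                    value = off[pairs])
  diag_top <- sort(diag(v), decreasing = TRUE)[seq_len(min(n, 20))]
  out <- list(topology_id = object$topology_id, cutoff = object$cutoff,
              n_homology_levels = object$n_homology_levels,
              top_offdiagonal = top, top_diagonal = diag_top,
              mean_gap = mean(object$gap_row))
  class(out) <- "summary.topology_matrix"
  out
}

#' @export
print.summary.topology_matrix <- function(x, ...) {
  cat("Topology-level substitution matrix: ", x$topology_id, "\n", sep = "")
  cat("  cutoff: ", format(x$cutoff), " A; homology levels: ",
      x$n_homology_levels, "\n", sep = "")
  cat("  strongest off-diagonal preferences:\n")
  for (i in seq_len(nrow(x$top_offdiagonal)))
    cat(sprintf("    %s <-> %s  %.4f\n", x$top_offdiagonal$a[i],
                x$top_offdiagonal$b[i], x$top_offdiagonal$value[i]))
  cat("  most conserved residues: ",
      paste(names(x$top_diagonal), collapse = " "), "\n", sep = "")
  cat(sprintf("  mean gap propensity: %.4f\n", x$mean_gap))
  invisible(x)
}

#' @export
#' @method coef topology_matrix
coef.topology_matrix <- function(object, ...) object$values

#' @export
#' @method plot topology_matrix
plot.topology_matrix <- function(x, main = x$topology_id, ...) {
  v <- x$values[, rev(seq_len(20)), drop = FALSE]
  graphics::image(seq_len(20), seq_len(20), v, axes = FALSE,
                  xlab = "", ylab = "", main = main, ...)
  graphics::axis(1, at = seq_len(20), labels = AA20, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(20), labels = rev(AA20), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
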