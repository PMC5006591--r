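#' Discrimination z-score for one structurally similar pair
#'
#' z = (similar score - mean(cross scores)) / sd(cross scores). The cross
#' population is the query aligned against the partners of all other
#' topologies; the similar pair's own score is excluded from the mean/sd, and
#' the sample (n-1) standard deviation is used (both configurable).
#'
#' @param similar_score alignment score of the structurally similar pair.
#' @param cross_scores numeric vector (length >= 2) of cross-pair scores.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param include_similar if `TRUE`, the similar score is pooled into the
#'   mean/sd population.
#' @return the z-score, or `NA` (with a warning) when the cross scores have
#'   zero spread.
#' @export
compute_zscore <- function(similar_score, cross_scores,
                           sd_type = c("sample", "population"),
                           include_similar = FALSE) {
  sd_type <- match.arg(sd_type)
  if (length(cross_scores) < 2L)
    stop_usage("need at least 2 cross scores")
  pop <- if (include_similar) c(similar_score, cross_scores) else cross_scores
  mu <- mean(pop)
  s <- stats::sd(pop)
  if (sd_type == "population") s <- s * sqrt((length(pop) - 1) / length(pop))
  if (!is.finite(s) || s == 0) {
    warning("zero spread in cross scores; z-score undefined", call. = FALSE)
    return(NA_real_)
  }
  (similar_score - mu) / s
}

# Score every (query, partner) combination of a pairset under one matrix.
# Returns n x n matrix: row i = query S_i, column j = partner S'_j.
score_grid <- function(pairset, m, gap_open, gap_extend) {
  n <- length(pairset)
  g <- matrix(NA_real_, n, n,
              dimnames = list(names(pairset), names(pairset)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      g[i, j] <- nw_score(pairset[[i]]$s, pairset[[j]]$s_prime, m,
                          gap_open, gap_extend)
    }
  }
  g
}

# z-scores per topology from a score grid: diagonal vs off-diagonal row-wise.
grid_zscores <- function(g, ...) {
  vapply(seq_len(nrow(g)), function(i)
    compute_zscore(g[i, i], g[i, -i], ...), numeric(1))
}

#' Evaluate a set of matrices on a pairset
#'
#' For every topology i and every matrix, the query S_i is aligned against
#' its own partner S_i' (similar pair) and against every other topology's
#' partner S_j' (cross pairs); the discrimination z-score is computed per
#' topology. Matrices may be shared across topologies (a plain matrix, e.g.
#' a generic anchor) or topology-specific (a named list keyed by topology
#' id, e.g. combined fold-specific matrices).
#'
#' @param pairset a `pairset` from [make_pairset] (>= 3 topologies).
#' @param matrices named list; each element is a labelled square matrix or a
#'   named list of per-topology matrices.
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 1).
#' @param ... passed to [compute_zscore].
#' @return data.frame with columns `topology`, `class`, `matrix`, `z`,
#'   `similar_score`.
#' @export
evaluate_pairset <- function(pairset, matrices, gap_open = 10,
                             gap_extend = 1, ...) {
  if (!inherits(pairset, "pairset")) stop_usage("'pairset' must be a pairset")
  if (length(pairset) < 3L) stop_usage("need at least 3 topologies")
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    stop_usage("'matrices' must be a named list")
  ids <- names(pairset)
  cls <- vapply(pairset, `[[`, character(1), "class")
  out <- list()
  for (mn in names(matrices)) {
    mm <- matrices[[mn]]
    if (is.matrix(mm)) {
      g <- score_grid(pairset, mm, gap_open, gap_extend)
      z <- grid_zscores(g, ...)
      sim <- diag(g)
    } else {
      miss <- setdiff(ids, names(mm))
      if (length(miss) > 0L)
        stop_usage("matrix set '", mn, "' missing topologies: ",
                   paste(miss, collapse = ", "))
      z <- sim <- numeric(length(ids))
      for (i in seq_along(ids)) {
        mi <- mm[[ids[i]]]
        cross <- vapply(setdiff(seq_along(ids), i), function(j)
          nw_score(pairset[[i]]$s, pairset[[j]]$s_prime, mi,
                   gap_open, gap_extend), numeric(1))
        sim[i] <- nw_score(pairset[[i]]$s, pairset[[i]]$s_prime, mi,
                           gap_open, gap_extend)
        z[i] <- compute_zscore(sim[i], cross, ...)
      }
    }
    out[[mn]] <- data.frame(topology = ids, class = cls, matrix = mn,
                            z = z, similar_score = sim,
                            row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Full discrimination report: generics vs weighted fold-specific matrices
#'
#' Runs the benchmark protocol: every generic matrix and, for each weight in
#' `weights`, the per-topology combined matrix (anchor + weight x topology
#' matrix) are evaluated on the pairset. Per topology it reports the best
#' weight, the maximum combined z, the percent improvement over the best
#' generic (absolute-value denominator, so improvements from negative
#' baselines are well defined), and an improved flag (combined best strictly
#' exceeds every generic's z). Per class it reports mean z-scores, the
#' fraction of topologies improved, the optimized weight (argmax of the
#' class-mean z) and the mean-z ratio curve against the anchor.
#'
#' @param pairset a `pairset`.
#' @param topo_matrices named list of `topology_matrix` objects (or bare
#'   20x20 matrices), keyed by topology id.
#' @param anchor the anchor matrix combined with the topology matrices.
#' @param generics named list of generic matrices used as the baseline; the
#'   anchor is added automatically if absent.
#' @param weights weight grid; 0 (the anchor itself) anchors the ratio
#'   curve, best-weight statistics are taken over the positive weights.
#' @param gap_open,gap_extend affine gap penalties.
#' @return a `zscore_report` with elements `per_topology`, `per_class`,
#'   `ratio_curve`, `z_table`, `weights`.
#' @export
zscore_report <- function(pairset, topo_matrices, anchor,
                          generics = list(), weights = 0:30,
                          gap_open = 10, gap_extend = 1) {
  ids <- names(pairset)
  anchor_name <- attr(anchor, "name") %||% "anchor"
  if (!(anchor_name %in% names(generics))) {
    generics <- c(setNames(list(anchor), anchor_name), generics)
  }
  miss <- setdiff(ids, names(topo_matrices))
  if (length(miss) > 0L)
    stop_usage("topo_matrices missing topologies: ",
               paste(miss, collapse = ", "))

  mats <- generics
  for (w in weights) {
    mats[[paste0("combined_w", w)]] <- setNames(lapply(ids, function(tid)
      combine_matrices(anchor, topo_matrices[[tid]], w)$values), ids)
  }
  zt <- evaluate_pairset(pairset, mats, gap_open, gap_extend)

  cls <- vapply(pairset, `[[`, character(1), "class")
  gen_z <- sapply(names(generics), function(g)
    zt$z[zt$matrix == g][match(ids, zt$topology[zt$matrix == g])])
  if (is.null(dim(gen_z))) gen_z <- matrix(gen_z, nrow = length(ids))
  colnames(gen_z) <- names(generics)
  wpos <- weights[weights > 0]
  comb_z <- sapply(wpos, function(w)
    zt$z[zt$matrix == paste0("combined_w", w)])
  if (is.null(dim(comb_z))) comb_z <- matrix(comb_z, nrow = length(ids))

  best_gen <- apply(gen_z, 1, max, na.rm = TRUE)
  best_idx <- apply(comb_z, 1, which.max)
  max_z <- comb_z[cbind(seq_along(ids), best_idx)]
  best_weight <- wpos[best_idx]
  pct <- 100 * (max_z - best_gen) / abs(best_gen)
  # "improved" = combined best strictly beats every generic, i.e. their max
  improved <- max_z > best_gen
  per_topology <- data.frame(topology = ids, class = cls, gen_z,
                             best_generic_z = best_gen,
                             best_weight = best_weight, max_z = max_z,
                             pct_improvement = pct, improved = improved,
                             row.names = NULL, check.names = FALSE)

  # class-level: mean z per weight, optimized weight, ratio curve vs anchor
  anchor_z <- gen_z[, anchor_name]
  classes <- unique(cls)
  ratio_curve <- do.call(rbind, lapply(classes, function(cl) {
    sel <- cls == cl
    mz <- vapply(weights, function(w) {
      zz <- zt$z[zt$matrix == paste0("combined_w", w)][sel]
      mean(zz, na.rm = TRUE)
    }, numeric(1))
    data.frame(class = cl, weight = weights, mean_z = mz,
               ratio = mz / mean(anchor_z[sel], na.rm = TRUE))
  }))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    sel <- cls == cl
    rc <- ratio_curve[ratio_curve$class == cl & ratio_curve$weight > 0, ]
    data.frame(class = cl, n = sum(sel),
               mean_z_anchor = mean(anchor_z[sel], na.rm = TRUE),
               mean_z_best_generic = mean(best_gen[sel], na.rm = TRUE),
               mean_max_z = mean(max_z[sel], na.rm = TRUE),
               fraction_improved = mean(improved[sel], na.rm = TRUE),
               optimized_weight = rc$weight[which.max(rc$mean_z)],
               optimized_mean_z = max(rc$mean_z), row.names = NULL)
  }))

  structure(list(per_topology = per_topology, per_class = per_class,
                 ratio_curve = ratio_curve, z_table = zt,
                 weights = weights, anchor_name = anchor_name),
            class = "zscore_report")
}

#' @export
print.zscore_report <- function(x, ...) {
  cat("<zscore_report> ", nrow(x$per_topology), " topologies, anchor ",
      x$anchor_name, "\n", sep = "")
  pt <- x$per_topology
  cat(sprintf("  %-12s %-12s %8s %8s %6s %8s %s\n", "topology", "class",
              "gen_z", "max_z", "w*", "impr%", "improved"))
  for (i in seq_len(nrow(pt)))
    cat(sprintf("  %-12s %-12s %8.2f %8.2f %6d %8.1f %s\n",
                pt$topology[i], pt$class[i], pt$best_generic_z[i],
                pt$max_z[i], pt$best_weight[i], pt$pct_improvement[i],
                if (isTRUE(pt$improved[i])) "yes" else "no"))
  cat(sprintf("  fraction improved: %.2f\n", mean(pt$improved, na.rm = TRUE)))
  invisible(x)
}

#' @export
#' @method summary zscore_report
summary.zscore_report <- function(object, ...) {
  cat("Per-class discrimination summary (anchor ", object$anchor_name,
      "):\n", sep = "")
  print(object$per_class, row.names = FALSE, digits = 3)
  invisible(object$per_class)
}

#' Sweep structure-alignment cutoffs and combination weights
#'
#' Rebuilds the topology matrices at every cutoff, combines them with the
#' anchor at every weight and evaluates the pairset — the protocol behind
#' cutoff-selection and weight-selection curves. Errors in any (cutoff)
#' cell are recorded and the sweep continues.
#'
#' @param bundles named list: topology id -> list of training [msta]s
#'   (homology levels).
#' @param pairset held-out test pairs.
#' @param cutoffs numeric vector of C-alpha cutoffs (Angstroms).
#' @param weights weight grid (0 included for the anchor baseline).
#' @param anchor anchor matrix.
#' @param generics named list of baseline generic matrices.
#' @param gap_open,gap_extend affine gap penalties.
#' @return a `sweep_result`: `by_class` (cutoff x weight x class mean z and
#'   ratio vs anchor), `by_topology` (per cutoff: best weight and max z per
#'   topology), `errors`.
#' @export
sweep_parameters <- function(bundles, pairset, cutoffs, weights = 0:30,
                             anchor = anchor_blosum62(), generics = list(),
                             gap_open = 10, gap_extend = 1) {
  miss <- setdiff(names(pairset), names(bundles))
  if (length(miss) > 0L)
    stop_usage("no training bundle for topologies: ",
               paste(miss, collapse = ", "))
  by_class <- list(); by_topology <- list(); errors <- list()
  for (cutoff in cutoffs) {
    res <- tryCatch({
      tms <- lapply(bundles[names(pairset)], fit_topology_matrix,
                    cutoff = cutoff)
      for (tid in names(tms)) tms[[tid]]$topology_id <- tid
      rep <- zscore_report(pairset, tms, anchor, generics, weights,
                           gap_open, gap_extend)
      by_class[[length(by_class) + 1L]] <-
        cbind(cutoff = cutoff, rep$ratio_curve)
      by_topology[[length(by_topology) + 1L]] <-
        cbind(cutoff = cutoff,
              rep$per_topology[, c("topology", "class", "best_weight",
                                   "max_z", "pct_improvement", "improved")])
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res))
      errors[[as.character(cutoff)]] <- res
  }
  structure(list(by_class = do.call(rbind, by_class),
                 by_topology = do.call(rbind, by_topology),
                 errors = errors),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ",
      length(unique(x$by_class$cutoff)), " cutoff(s) x ",
      length(unique(x$by_class$weight)), " weight(s)\n", sep = "")
  agg <- stats::aggregate(ratio ~ cutoff, data = x$by_class, FUN = max)
  cat("  best mean-z ratio vs anchor, by cutoff:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("    %4.1f A  %.3f\n", agg$cutoff[i], agg$ratio[i]))
  if (length(x$errors) > 0)
    cat("  errors at cutoffs: ", paste(names(x$errors), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
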