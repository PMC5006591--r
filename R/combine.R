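#' The Blosum62 anchor matrix
#'
#' Returns the standard Blosum62 substitution matrix (from Biostrings) over
#' the NCBI 24-letter alphabet (A R N D C Q E G H I L K M F P S T W Y V B Z
#' X *), the form psiblast consumes.
#'
#' @return 24x24 labelled integer matrix with attribute `name = "blosum62"`.
#' @export
anchor_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[NCBI24, NCBI24]
  storage.mode(m) <- "double"
  attr(m, "name") <- "blosum62"
  m
}

#' Combine a generic anchor matrix with a topology-level matrix
#'
#' The final fold-specific scoring matrix is the generic anchor plus the
#' topology-level matrix scaled by a weight:
#' `combined = anchor + weight * topology`, element-wise over the shared
#' 20-residue alphabet. Anchor entries for residues outside the 20 standard
#' amino acids (B, Z, X, *) pass through unchanged.
#'
#' @param anchor labelled square numeric matrix covering the 20 standard
#'   residues (e.g. [anchor_blosum62], or [read_matrix] output).
#' @param topo a `topology_matrix` (see [fit_topology_matrix]) or a bare
#'   labelled 20x20 matrix.
#' @param weight nonnegative weight on the topology component. The useful
#'   range is 1-30; weight 0 returns the anchor unchanged.
#' @return a `combined_matrix` object: `values` (same alphabet as anchor,
#'   real-valued working form), `anchor_name`, `topology_id`, `weight`.
#' @export
combine_matrices <- function(anchor, topo, weight) {
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0)
    stop_usage("'weight' must be a single nonnegative number")
  if (is.null(rownames(anchor)) || nrow(anchor) != ncol(anchor))
    stop_usage("'anchor' must be a labelled square matrix")
  miss <- setdiff(AA20, rownames(anchor))
  if (length(miss) > 0L)
    stop_data("anchor is missing standard residue(s): ",
              paste(miss, collapse = ", "))
  tv <- if (inherits(topo, "topology_matrix")) topo$values else topo
  if (!identical(sort(rownames(tv)), sort(AA20)))
    stop_usage("topology matrix must be labelled over the 20 standard residues")
  values <- anchor
  attr(values, "name") <- NULL
  values[AA20, AA20] <- anchor[AA20, AA20] + weight * tv[AA20, AA20]
  structure(list(values = values,
                 anchor_name = attr(anchor, "name") %||% "anchor",
                 topology_id = if (inherits(topo, "topology_matrix"))
                   topo$topology_id else "topology",
                 weight = weight),
            class = "combined_matrix")
}

#' @export
print.combined_matrix <- function(x, ...) {
  cat("<combined_matrix> ", x$anchor_name, " + ", format(x$weight), " x ",
      x$topology_id, "  (", nrow(x$values), "-letter alphabet)\n", sep = "")
  invisible(x)
}

#' Export a combined matrix as an integer NCBI BLAST matrix
#'
#' Two export profiles are provided. `"psiblast"` rounds the working values
#' to the nearest integer — the net effect of scaling by 100 at build time
#' and dividing by 100 before feeding psiblast — and is the profile to use
#' as a drop-in `-matrix` replacement. `"scaled"` multiplies by `scale`
#' (default 100) before rounding, to preserve the minor variations of the
#' real-valued matrix; an optional `cap` clamps entries from above.
#'
#' @param m a `combined_matrix` in working (real) form.
#' @param profile `"psiblast"` or `"scaled"`.
#' @param scale integer multiplier for the `"scaled"` profile.
#' @param cap optional integer ceiling applied after scaling (`"scaled"`
#'   profile only); `NULL` disables clamping.
#' @return labelled square integer matrix over the anchor's alphabet, with
#'   attribute `name`.
#' @export
export_blast_matrix <- function(m, profile = c("psiblast", "scaled"),
                                scale = 100L, cap = NULL) {
  profile <- match.arg(profile)
  if (!inherits(m, "combined_matrix"))
    stop_usage("'m' must be a combined_matrix")
  v <- m$values
  if (!all(is.finite(v))) stop_data("non-finite values in combined matrix")
  out <- switch(profile,
    psiblast = round(v),
    scaled = {
      s <- round(scale * v)
      if (!is.null(cap)) s <- pmin(s, cap)
      s
    })
  storage.mode(out) <- "double"   # integer-valued; write_matrix emits ints
  attr(out, "name") <- paste0(m$anchor_name, "_", m$topology_id,
                              "_w", format(m$weight))
  out
}

#' Write a topology matrix with its JSON sidecar
#'
#' Serializes the 20x20 block (plus gap row) as an NCBI-style matrix file and
#' writes `<path>.json` with the provenance metadata (topology id, cutoff,
#' number of homology levels, normalization state).
#'
#' @param tm a `topology_matrix`.
#' @param path output path for the matrix file.
#' @return `path`, invisibly.
#' @export
write_topology_matrix <- function(tm, path) {
  if (!inherits(tm, "topology_matrix")) stop_usage("'tm' must be a topology_matrix")
  m <- rbind(cbind(tm$values, `-` = tm$gap_row),
             `-` = c(tm$gap_row, 0))
  colnames(m) <- c(AA20, GAP)
  write_matrix(m, path, comment = paste0("topology ", tm$topology_id,
                                         " cutoff ", format(tm$cutoff), " A"))
  meta <- list(topology_id = tm$topology_id, cutoff = tm$cutoff,
               n_homology_levels = tm$n_homology_levels,
               normalized = TRUE, max_value = max(tm$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a topology matrix written by [write_topology_matrix]
#'
#' @param path path to the matrix file (the `.json` sidecar is read if
#'   present).
#' @return a `topology_matrix`.
#' @export
read_topology_matrix <- function(path) {
  m <- read_matrix(path)
  if (!all(c(AA20, GAP) %in% rownames(m)))
    stop_data("not a topology matrix file: ", path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  structure(list(topology_id = meta$topology_id %||% attr(m, "name"),
                 values = m[AA20, AA20],
                 gap_row = m[AA20, GAP],
                 n_homology_levels = meta$n_homology_levels %||% NA_integer_,
                 cutoff = meta$cutoff %||% NA_real_),
            class = "topology_matrix")
}
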