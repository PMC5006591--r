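#' Construct a structure chain (ordered C-alpha trace)
#'
#' A `structure_chain` holds the ordered residues of one protein domain with
#' their C-alpha coordinates, already superposed into the common frame shared
#' by its alignment bundle (as emitted by multiple structure aligners such as
#' Mustang). Coordinates are taken as-is; no superposition is performed here.
#'
#' @param id chain identifier, unique within an alignment bundle.
#' @param seq character vector of one-letter residue codes (20 standard amino
#'   acids or `"X"` for non-standard residues).
#' @param ca numeric matrix, `length(seq)` x 3, of C-alpha coordinates in
#'   Angstroms.
#' @param resno optional original residue numbers, kept as metadata only.
#' @return an object of class `structure_chain`.
#' @export
structure_chain <- function(id, seq, ca, resno = NULL) {
  seq <- as.character(seq)
  ca <- as.matrix(ca)
  if (length(seq) == 0L) stop_data("structure chain '", id, "' has no residues")
  if (nrow(ca) != length(seq) || ncol(ca) != 3L)
    stop_data("coordinate matrix must be length(seq) x 3")
  if (!all(is.finite(ca))) stop_data("non-finite C-alpha coordinates in '", id, "'")
  bad <- !(seq %in% c(AA20, "X"))
  if (any(bad))
    stop_data("unknown residue code(s): ", paste(unique(seq[bad]), collapse = ", "))
  dimnames(ca) <- list(NULL, c("x", "y", "z"))
  structure(list(id = as.character(id), seq = seq, ca = ca,
                 resno = resno %||% seq_along(seq)),
            class = "structure_chain")
}

#' @export
print.structure_chain <- function(x, ...) {
  cat("<structure_chain> ", x$id, ": ", length(x$seq), " residues\n", sep = "")
  cat("  ", paste(head(x$seq, 40), collapse = ""),
      if (length(x$seq) > 40) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.structure_chain <- function(x) length(x$seq)

#' Read the C-alpha trace of one chain from a PDB file
#'
#' Reads ATOM records (first MODEL only) via bio3d and extracts the C-alpha
#' trace of one chain. Residues lacking a CA atom are skipped with a warning;
#' non-standard residues (e.g. MSE) map to `"X"` and are treated as
#' unalignable downstream.
#'
#' @param path path to a PDB-format file.
#' @param chain optional chain identifier; default is the first chain
#'   encountered (CATH domains are single-chain extracts).
#' @return a [structure_chain].
#' @export
read_pdb_ca <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop_data("PDB parse error in '", path, "': ",
                                  conditionMessage(e)))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop_data("no ATOM records in '", path, "'")
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stop_data("chain '", chain, "' not found in '", path, "'")

  # one residue per (resno, insert); keep file order
  key <- paste(atoms$resno, atoms$insert)
  keys <- unique(key)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
  missing_ca <- setdiff(keys, paste(ca$resno, ca$insert))
  if (length(missing_ca) > 0L)
    warning(length(missing_ca), " residue(s) without a CA atom skipped in '",
            basename(path), "'", call. = FALSE)
  if (nrow(ca) == 0L) stop_data("no CA atoms in '", path, "'")

  # only the 20 standard residue types are alignable; everything else
  # (MSE, UNK, modified residues, ...) becomes X
  std3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  aa <- unname(std3[ca$resid])
  aa[is.na(aa)] <- "X"
  id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  structure_chain(id, aa, cbind(ca$x, ca$y, ca$z), resno = ca$resno)
}

# ---------------------------------------------------------------------------
# NCBI BLAST matrix format
# ---------------------------------------------------------------------------

#' Read an NCBI BLAST-format substitution matrix file
#'
#' The format is whitespace-separated: `#` comment lines, a header row of
#' residue labels, then one labelled row per residue (as consumed by blastp,
#' psiblast and friends).
#'
#' @param path path to the matrix file.
#' @return a labelled square numeric matrix with attribute `name` (basename).
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_data("matrix file '", path, "' has no table")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- length(header)
  body <- lines[-1]
  vals <- matrix(NA_real_, n, n, dimnames = list(header, header))
  seen <- character(0)
  for (ln in body) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != n + 1L)
      stop_data("row '", f[1], "' has ", length(f) - 1L,
                " values, expected ", n)
    lab <- f[1]
    if (!(lab %in% header)) stop_data("unknown residue label '", lab, "'")
    vals[lab, ] <- suppressWarnings(as.numeric(f[-1]))
    seen <- c(seen, lab)
  }
  miss <- setdiff(header, seen)
  if (length(miss) > 0L)
    stop_data("missing row(s) for: ", paste(miss, collapse = ", "))
  if (anyNA(vals)) stop_data("non-numeric entries in '", path, "'")
  attr(vals, "name") <- sub("\\.[^.]*$", "", basename(path))
  vals
}

#' Write a substitution matrix in NCBI BLAST format
#'
#' Integer-valued matrices are written as integers (exact round trip through
#' [read_matrix]); real-valued matrices with 6 decimals.
#'
#' @param m labelled square numeric matrix.
#' @param path output path.
#' @param comment optional comment line(s) written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, comment = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || is.null(rownames(m)))
    stop_usage("write_matrix needs a labelled square matrix")
  if (!all(is.finite(m))) stop_data("non-finite matrix values")
  labs <- rownames(m)
  is_int <- all(m == round(m))
  fmt <- function(v) if (is_int) sprintf("%d", as.integer(round(v)))
                     else sprintf("%.6f", v)
  cells <- matrix(fmt(m), nrow(m))
  width <- max(nchar(cells), nchar(labs)) + 1L
  pad <- function(s) formatC(s, width = width)
  out <- character(0)
  if (!is.null(comment)) out <- paste0("# ", comment)
  out <- c(out, paste0(" ", paste(pad(labs), collapse = "")))
  for (i in seq_along(labs))
    out <- c(out, paste0(labs[i], paste(pad(cells[i, ]), collapse = "")))
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Multi-structure alignment bundles
# ---------------------------------------------------------------------------

#' Build a multi-structure alignment from gapped rows and chains
#'
#' Column-indexed correspondence of residues across two or more superposed
#' structures (one CATH homology level). Cell (structure, column) is either a
#' residue index into that chain or `NA` (gap).
#'
#' @param chains list of [structure_chain] objects.
#' @param rows character vector of equal-length gapped sequences, one per
#'   chain, gap character `-`; the ungapped content of row i must equal the
#'   residue sequence of chain i.
#' @return an object of class `msta` with fields `chains`, `rows`, and `index`
#'   (n_structures x n_columns integer matrix of residue indices, `NA` = gap).
#' @export
msta <- function(chains, rows) {
  if (length(chains) != length(rows))
    stop_data("number of alignment rows (", length(rows),
              ") != number of structures (", length(chains), ")")
  ids <- vapply(chains, function(ch) ch$id, character(1))
  if (anyDuplicated(ids)) stop_data("duplicate structure ids in bundle")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop_data("alignment rows differ in length")
  ncol <- widths[1]
  idx <- matrix(NA_integer_, length(chains), ncol,
                dimnames = list(ids, NULL))
  for (i in seq_along(chains)) {
    cells <- strsplit(rows[i], "")[[1]]
    res <- cells != GAP
    ungapped <- cells[res]
    chseq <- chains[[i]]$seq
    if (length(ungapped) != length(chseq)) {
      stop_data("row '", ids[i], "': ungapped length ", length(ungapped),
                " != structure length ", length(chseq))
    }
    mism <- which(ungapped != chseq)
    if (length(mism) > 0L)
      stop_data("row '", ids[i], "': residue mismatch at ungapped position ",
                mism[1], " ('", ungapped[mism[1]], "' vs '",
                chseq[mism[1]], "')")
    idx[i, res] <- seq_len(sum(res))
  }
  structure(list(chains = chains, rows = as.character(rows), index = idx),
            class = "msta")
}

#' @export
print.msta <- function(x, ...) {
  cat("<msta> ", nrow(x$index), " structures x ", ncol(x$index),
      " columns\n", sep = "")
  for (i in seq_along(x$chains))
    cat("  ", rownames(x$index)[i], ": ",
        substr(x$rows[i], 1, 60),
        if (nchar(x$rows[i]) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Load a Mustang-style multi-structure alignment bundle
#'
#' Reads a gapped FASTA alignment plus the matching superposed PDB files and
#' checks their mutual consistency (every FASTA record has a structure; the
#' ungapped row equals the chain's C-alpha sequence).
#'
#' @param alignment_fasta path to aligned FASTA (gap character `-`).
#' @param structure_paths character vector of PDB paths; each file's basename
#'   (without extension) must match one FASTA record id.
#' @return an [msta] object.
#' @export
load_msta <- function(alignment_fasta, structure_paths) {
  aln <- Biostrings::readAAStringSet(alignment_fasta)
  if (length(aln) < 2L) stop_data("alignment has fewer than 2 records")
  rows <- toupper(as.character(aln))
  ids <- sub("\\s.*$", "", names(aln))
  chains <- lapply(structure_paths, read_pdb_ca)
  names(chains) <- vapply(chains, function(ch) ch$id, character(1))
  miss <- setdiff(ids, names(chains))
  if (length(miss) > 0L)
    stop_data("no structure file for alignment record(s): ",
              paste(miss, collapse = ", "))
  msta(chains[ids], unname(rows))
}
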