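#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Clustal files into a light `msa` object. Sequences
#' are upper-cased; records keep file order; a ragged alignment is an error.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (by extension), `"fasta"` or `"clustal"`.
#' @return An `msa`: list with `ids`, `seqs` (aligned strings with `-` gaps)
#'   and `width`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      fa = "fasta", fasta = "fasta", afa = "fasta", fna = "fasta",
      aln = "clustal", clu = "clustal", clustal = "clustal",
      stop("cannot infer alignment format from '.", ext, "'"))
  }
  a <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) stop("failed to parse ", format, " alignment '",
                             path, "': ", conditionMessage(e)))
  seqs <- as.character(Biostrings::unmasked(a))
  new_msa(names(seqs), unname(seqs))
}

#' Construct an alignment object from aligned strings
#'
#' @param ids Unique sequence identifiers.
#' @param seqs Aligned sequences of equal width (gap character `-`).
#' @return An `msa` object.
#' @export
new_msa <- function(ids, seqs) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  w <- unique(nchar(seqs))
  if (length(w) != 1)
    stop("ragged alignment: record '",
         ids[which(nchar(seqs) != nchar(seqs[1]))[1]],
         "' has a different width")
  structure(list(ids = ids, seqs = unname(seqs), width = w), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$ids), "sequences x", x$width, "columns\n")
  invisible(x)
}

#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$ids
  m
}

#' Map alignment columns to ungapped reference positions
#'
#' @param a An `msa`.
#' @param ref_id Identifier of the reference sequence.
#' @return data.frame with `column` (alignment column) and `position`
#'   (1-based ungapped reference position); a bijection over non-gap
#'   reference columns.
#' @export
map_to_reference <- function(a, ref_id) {
  i <- match(ref_id, a$ids)
  if (is.na(i)) stop("reference id '", ref_id, "' not in alignment")
  ch <- strsplit(a$seqs[i], "")[[1]]
  cols <- which(ch != "-")
  data.frame(column = cols, position = seq_along(cols))
}

#' Absolutely conserved reference positions within a clade
#'
#' A reference position is absolutely conserved when every clade member
#' carries the identical residue in that alignment column; a gap anywhere in
#' the clade counts as a mismatch. Adding sequences to the clade can only
#' shrink the result.
#'
#' @param a An `msa`.
#' @param ref_id Reference sequence id (positions are reported in its
#'   ungapped numbering).
#' @param clade Ids of the clade members to compare against the reference;
#'   default: every other sequence in the alignment.
#' @return List with `count` and `positions` (integer vector).
#' @export
absolute_conservation <- function(a, ref_id, clade = NULL) {
  if (is.null(clade)) clade <- setdiff(a$ids, ref_id)
  if (length(clade) == 0) stop("empty clade")
  missing <- setdiff(clade, a$ids)
  if (length(missing) > 0)
    stop("clade id(s) not in alignment: ", paste(missing, collapse = ", "))
  m <- as.matrix.msa(a)
  ref <- m[ref_id, ]
  sub <- m[clade, , drop = FALSE]
  ok <- colSums(sub != rep(ref, each = nrow(sub))) == 0 & ref != "-"
  mp <- map_to_reference(a, ref_id)
  positions <- mp$position[match(which(ok), mp$column)]
  positions <- sort(positions[!is.na(positions)])
  list(count = length(positions), positions = positions)
}

#' Identity-fraction conservation profile binned on a 1-9 scale
#'
#' For each ungapped reference position, the fraction of non-reference
#' sequences whose aligned character equals the reference residue (gaps
#' mismatch), binned as ceiling(9 x fraction) clipped to [1, 9]. This is a
#' deliberately simple identity-based stand-in for evolutionary-rate
#' conservation scores, preserving the conventional 1-9 colour scale for
#' structure painting.
#'
#' @param a An `msa` with at least 2 sequences.
#' @param ref_id Reference sequence id.
#' @return A `conservation_profile`: data.frame with `position`, `column`,
#'   `ref_char`, `identity_fraction`, `bin`.
#' @export
identity_bins <- function(a, ref_id) {
  if (length(a$ids) < 2) stop("need at least 2 sequences")
  others <- setdiff(a$ids, ref_id)
  m <- as.matrix.msa(a)
  ref <- m[ref_id, ]
  sub <- m[others, , drop = FALSE]
  frac <- colMeans(sub == rep(ref, each = nrow(sub)))
  mp <- map_to_reference(a, ref_id)
  out <- data.frame(position = mp$position, column = mp$column,
                    ref_char = ref[mp$column],
                    identity_fraction = frac[mp$column],
                    bin = pmin(9L, pmax(1L, as.integer(
                      ceiling(9 * frac[mp$column])))))
  rownames(out) <- NULL
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment (via Biostrings) under a named
#' substitution matrix, where a gap run of length L costs
#' gap_open + gap_extend x L. Percent identity is matches over alignment
#' columns.
#'
#' @param seq_a,seq_b Protein sequences (one-letter).
#' @param substitution Substitution matrix name (e.g. `"BLOSUM62"`) or a
#'   numeric matrix.
#' @param gap_open,gap_extend Affine gap parameters (positive costs).
#' @return List with `aligned_a`, `aligned_b` (gapped strings), `score` and
#'   `percent_identity`.
#' @export
global_align <- function(seq_a, seq_b, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 1) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) stop("empty sequence")
  mat <- if (is.matrix(substitution)) substitution else {
    e <- new.env()
    ok <- tryCatch({
      utils::data(list = substitution, package = "Biostrings", envir = e)
      TRUE
    }, warning = function(w) FALSE, error = function(e2) FALSE)
    if (!ok || !exists(substitution, envir = e))
      stop("unknown substitution matrix '", substitution, "'")
    get(substitution, envir = e)
  }
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  aa <- as.character(Biostrings::pattern(pa))
  bb <- as.character(Biostrings::subject(pa))
  ca <- strsplit(aa, "")[[1]]; cb <- strsplit(bb, "")[[1]]
  cols <- !(ca == "-" & cb == "-")
  pid <- 100 * sum(ca == cb & ca != "-" & cols) / sum(cols)
  list(aligned_a = aa, aligned_b = bb, score = Biostrings::score(pa),
       percent_identity = pid)
}

#' Paint conservation bins onto a structure's B-factors
#'
#' Residue B-factors are set to the profile's 1-9 bin at the matching
#' author-numbered position; positions absent from the profile get the
#' sentinel (-1).
#'
#' @param s A `structure3d`.
#' @param profile A `conservation_profile` from [identity_bins()].
#' @param chain Restrict painting to one chain (`NULL`: all).
#' @param sentinel Value for unmapped residues.
#' @return The structure with B-factors replaced.
#' @export
paint_conservation <- function(s, profile, chain = NULL, sentinel = -1) {
  paint_residues(s, profile$position, profile$position, profile$bin,
                 chain, sentinel)
}
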