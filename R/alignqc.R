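#' Read an aligned FASTA file
#'
#' Loads aligned nucleotide sequences (gap \code{-} and ambiguity codes
#' allowed; \code{U} is converted to \code{T}) and checks the alignment
#' invariants: equal row lengths and unique labels.
#'
#' @param path FASTA file.
#' @return a \code{Biostrings::DNAStringSet} of equal-width rows.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  aln <- Biostrings::DNAStringSet(seqs)
  names(aln) <- names(raw)
  .validate_alignment(aln)
  aln
}

.validate_alignment <- function(aln) {
  if (!length(aln)) stop("empty alignment")
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("alignment rows differ in length")
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment labels must be present and unique")
  invisible(aln)
}

#' Write an alignment to FASTA
#' @param aln a \code{DNAStringSet}.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln, path)
  invisible(path)
}

#' Trim alignment ends by missing-data fraction
#'
#' Implements the dataset-curation rule applied to the SSU rRNA matrices:
#' scanning inward from each end of the alignment, a column is removed
#' while its missing-data fraction (gaps and \code{N}) is strictly greater
#' than \code{max_missing}; scanning stops at the first compliant column on
#' each side.  Interior columns are never touched, and a column with
#' exactly the threshold fraction (e.g. 3 of 5 rows at the default 0.6) is
#' retained.  The operation is idempotent.
#'
#' @param aln a \code{DNAStringSet} alignment (see
#'   \code{\link{read_alignment}}).
#' @param max_missing proportion in (0, 1); default 0.6.
#' @return list with \code{alignment} (trimmed \code{DNAStringSet}),
#'   \code{removed_left}, \code{removed_right} (original column indices),
#'   and \code{threshold}.
#' @export
trim_alignment_ends <- function(aln, max_missing = 0.6) {
  .validate_alignment(aln)
  if (max_missing <= 0 || max_missing >= 1)
    stop("max_missing must be strictly between 0 and 1")
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  frac <- colMeans(m == "-" | m == "N" | m == ".")
  ncol_aln <- length(frac)
  left <- 0L
  while (left < ncol_aln && frac[left + 1L] > max_missing) left <- left + 1L
  right <- 0L
  while (right < ncol_aln - left && frac[ncol_aln - right] > max_missing)
    right <- right + 1L
  keep <- seq.int(left + 1L, ncol_aln - right)
  if (!length(keep)) stop("trimming would remove every column")
  trimmed <- Biostrings::subseq(aln, start = left + 1L,
                                end = ncol_aln - right)
  list(alignment = trimmed,
       removed_left = if (left) seq_len(left) else integer(0),
       removed_right = if (right) seq.int(ncol_aln - right + 1L, ncol_aln)
                       else integer(0),
       threshold = max_missing)
}

#' Pairwise percent identity
#'
#' In \code{"global-aligned"} mode the two sequences must already be
#' aligned to equal length: identity = identical columns / compared
#' columns x 100, where columns gapped in both rows are excluded and a gap
#' against a base counts as a compared, non-identical column.  In
#' \code{"local"} mode gaps are stripped and a blast-like local alignment
#' (Smith-Waterman via \code{Biostrings::pairwiseAlignment}) is scored as
#' identities / local alignment length x 100, the definition behind
#' reported BLASTn best-hit similarities.  The definition used is attached
#' as the \code{"definition"} attribute.  The measure is symmetric and
#' bounded in [0, 100].
#'
#' @param a,b nucleotide sequences (strings or \code{DNAString}s).
#' @param mode \code{"global-aligned"} (default) or \code{"local"}.
#' @return numeric percentage with a \code{"definition"} attribute.
#' @export
percent_identity <- function(a, b, mode = c("global-aligned", "local")) {
  mode <- match.arg(mode)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  a <- gsub("U", "T", a, fixed = TRUE); b <- gsub("U", "T", b, fixed = TRUE)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (mode == "global-aligned") {
    if (nchar(a) != nchar(b))
      stop("global-aligned mode requires equal-length (pre-aligned) sequences")
    ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
    compared <- !(ca %in% c("-", ".") & cb %in% c("-", "."))
    if (!any(compared)) stop("no comparable columns")
    pid <- 100 * sum(ca[compared] == cb[compared] &
                       !(ca[compared] %in% c("-", "."))) / sum(compared)
    def <- "identical columns / non gap-gap columns x 100 (pre-aligned)"
  } else {
    a2 <- gsub("[-.]", "", a); b2 <- gsub("[-.]", "", b)
    if (!nzchar(a2) || !nzchar(b2)) stop("empty sequence after gap removal")
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a2), Biostrings::DNAString(b2), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    pid <- Biostrings::nmatch(pa) / Biostrings::nchar(pa) * 100
    def <- "identities / local (Smith-Waterman) alignment length x 100"
  }
  structure(pid, definition = def)
}
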