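## Sequence and alignment containers + FASTA I/O.
##
## Sequences keep their original upper/lowercase characters: uppercase marks
## core-block (reliably aligned) positions in benchmark references, and the
## scoring functions rely on it.  Gap characters '-' and '.' are both accepted
## on input; '.' is normalized to '-'.

#' Protein sequence set
#'
#' A light container for unaligned protein sequences. Residue case is
#' preserved (uppercase = core block); gap characters are not allowed.
#'
#' @param seqs character vector of residue strings.
#' @param ids character vector of identifiers (full headers are kept; matching
#'   uses the id up to the first whitespace, see [seq_keys()]).
#' @return An object of class `aa_seqs`: a list with elements `id` and `seq`.
#' @export
aa_seqs <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  stopifnot(length(ids) == length(seqs))
  seqs <- as.character(seqs)
  validate_residues(seqs, ids, allow_gaps = FALSE)
  structure(list(id = as.character(ids), seq = unname(seqs)),
            class = "aa_seqs")
}

#' Protein alignment
#'
#' Equal-width gapped rows. Case is preserved; '.' gaps are normalized to '-'.
#'
#' @param rows character vector of gapped rows.
#' @param ids identifiers, parallel to `rows`.
#' @return An object of class `aa_aln` with elements `id`, `row`, `width`.
#' @export
aa_aln <- function(rows, ids = NULL) {
  if (is.null(ids)) ids <- names(rows)
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  stopifnot(length(ids) == length(rows))
  rows <- gsub(".", "-", as.character(rows), fixed = TRUE)
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("ragged alignment: row widths ", paste(sort(w), collapse = ", "))
  validate_residues(rows, ids, allow_gaps = TRUE)
  structure(list(id = as.character(ids), row = unname(rows), width = w),
            class = "aa_aln")
}

validate_residues <- function(seqs, ids, allow_gaps) {
  ok <- AA_ALPHABET_FULL
  if (allow_gaps) ok <- c(ok, "-", ".")
  for (k in seq_along(seqs)) {
    ch <- toupper(strsplit(seqs[[k]], "", fixed = TRUE)[[1L]])
    bad <- which(!(ch %in% ok))
    if (length(bad))
      stop(sprintf("invalid character '%s' in record '%s' at position %d",
                   ch[bad[1L]], ids[[k]], bad[1L]))
  }
  invisible(TRUE)
}

#' @export
print.aa_seqs <- function(x, ...) {
  cat(sprintf("aa_seqs: %d sequences (lengths %d-%d)\n", length(x$id),
              min(nchar(x$seq)), max(nchar(x$seq))))
  invisible(x)
}

#' @export
print.aa_aln <- function(x, ...) {
  cat(sprintf("aa_aln: %d rows x %d columns\n", length(x$id), x$width))
  invisible(x)
}

#' @export
length.aa_seqs <- function(x) length(x$id)

#' @export
length.aa_aln <- function(x) length(x$id)

#' Matching keys for identifiers
#'
#' Identifiers are matched between test and reference alignments by the header
#' text up to the first whitespace (full headers are preserved for output).
#'
#' @param x an `aa_seqs` or `aa_aln` object, or a character vector of ids.
#' @return character vector of keys.
#' @export
seq_keys <- function(x) {
  ids <- if (is.character(x)) x else x$id
  sub("\\s.*$", "", ids)
}

#' Remove gaps from alignment rows
#'
#' @param x an `aa_aln` object.
#' @return an `aa_seqs` object with gap characters removed, case preserved.
#' @export
ungap <- function(x) {
  stopifnot(inherits(x, "aa_aln"))
  aa_seqs(gsub("-", "", x$row, fixed = TRUE), x$id)
}

#' Per-residue core-block mask
#'
#' @param x an `aa_seqs` or `aa_aln` object.
#' @return list of logical vectors, TRUE where the character is uppercase
#'   (core block). Gap positions in alignments are NA.
#' @export
case_mask <- function(x) {
  s <- if (inherits(x, "aa_aln")) x$row else x$seq
  lapply(str_chars(s), function(ch) {
    m <- ch %in% c(LETTERS)
    m[ch == "-"] <- NA
    m
  })
}

#' Alignment as a character matrix
#'
#' @param x an `aa_aln` object.
#' @param upper uppercase all residues first.
#' @return character matrix, rows = sequences.
#' @export
aln_matrix <- function(x, upper = TRUE) {
  s <- if (upper) toupper(x$row) else x$row
  matrix(unlist(str_chars(s)), nrow = length(s), ncol = x$width, byrow = TRUE)
}

#' Read a FASTA file
#'
#' Headers are kept verbatim; residue case is preserved; '.' gaps are
#' normalized to '-'. With `aligned = TRUE` all records must have equal width.
#'
#' @param path file path.
#' @param aligned logical; read as an alignment (gaps allowed).
#' @return an [aa_seqs] or [aa_aln] object.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(set)
  ids <- names(set)
  if (aligned) aa_aln(seqs, ids) else aa_seqs(seqs, ids)
}

#' Write sequences or an alignment to FASTA
#'
#' Round-trips through [read_fasta()] exactly, including case and gaps.
#'
#' @param x an [aa_seqs] or [aa_aln] object.
#' @param path output path.
#' @param line_width residues per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, line_width = 60L) {
  stopifnot(line_width >= 1L)
  s <- if (inherits(x, "aa_aln")) x$row else if (inherits(x, "aa_seqs")) x$seq
       else stop("x must be aa_seqs or aa_aln")
  if (length(s) == 0L) stop("no records to write")
  set <- Biostrings::BStringSet(s)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

#' Project a multiple alignment onto a pair of rows
#'
#' An n-row alignment induces (n^2 - n)/2 pairwise alignments; this extracts
#' one of them, optionally dropping columns where both rows are gaps.
#'
#' @param msa an [aa_aln] object.
#' @param i,j distinct row indices.
#' @param drop_double_gaps drop columns that are gaps in both rows.
#' @return a 2-row [aa_aln].
#' @export
project_pair <- function(msa, i, j, drop_double_gaps = TRUE) {
  stopifnot(inherits(msa, "aa_aln"))
  n <- length(msa$id)
  if (i < 1L || i > n || j < 1L || j > n) stop("row index out of range")
  if (i == j) stop("row indices must differ")
  a <- strsplit(msa$row[[i]], "", fixed = TRUE)[[1L]]
  b <- strsplit(msa$row[[j]], "", fixed = TRUE)[[1L]]
  if (drop_double_gaps) {
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
  }
  aa_aln(c(paste(a, collapse = ""), paste(b, collapse = "")),
         msa$id[c(i, j)])
}
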