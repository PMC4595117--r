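## Benchmark scoring with core-block semantics.
##
## Residue identity across test and reference is keyed by ungapped residue
## index, never by column, so alignments with different gap placements are
## comparable. Only uppercase reference residues (core blocks) are scored by
## default; case in the test alignment is ignored.

# per-cell ungapped residue index (NA at gaps)
residue_index_matrix <- function(mat) {
  t(apply(mat != "-", 1L, cumsum)) * ifelse(mat != "-", 1L, NA_integer_)
}

# reorder test rows to match ref by id key and verify residue contents
match_alignments <- function(test, ref) {
  stopifnot(inherits(test, "aa_aln"), inherits(ref, "aa_aln"))
  kt <- seq_keys(test); kr <- seq_keys(ref)
  m <- match(kr, kt)
  if (anyNA(m))
    stop("sequence '", kr[which(is.na(m))[1L]], "' missing from test alignment")
  test <- aa_aln(test$row[m], test$id[m])
  ut <- toupper(gsub("-", "", test$row, fixed = TRUE))
  ur <- toupper(gsub("-", "", ref$row, fixed = TRUE))
  bad <- which(ut != ur)
  if (length(bad))
    stop("residue content differs for sequence '", kr[bad[1L]], "'")
  test
}

# shared scaffolding for the pair-based scores
score_context <- function(test, ref, core_only) {
  test <- match_alignments(test, ref)
  rmat <- aln_matrix(ref, upper = FALSE)
  tmat <- aln_matrix(test)
  rres <- rmat != "-"
  core <- matrix(rmat %in% LETTERS, nrow(rmat)) & rres
  elig <- if (core_only) core else rres
  P_ref <- residue_index_matrix(aln_matrix(ref))
  # test column holding residue p of row i
  tpos <- lapply(seq_len(nrow(tmat)), function(i) which(tmat[i, ] != "-"))
  # TC[i, c]: test column of the ref residue at (i, c)
  TC <- P_ref
  for (i in seq_len(nrow(TC))) {
    idx <- !is.na(P_ref[i, ])
    TC[i, idx] <- tpos[[i]][P_ref[i, idx]]
  }
  # core flag per residue index
  coreflag <- lapply(seq_len(nrow(rmat)), function(i) {
    f <- logical(sum(rres[i, ]))
    f[P_ref[i, rres[i, ]]] <- core[i, rres[i, ]]
    f
  })
  list(test = test, rmat = rmat, tmat = tmat, elig = elig, TC = TC,
       P_ref = P_ref, coreflag = coreflag, tpos = tpos)
}

pairs_of <- function(k) k * (k - 1) / 2

# reference pairs recovered by the test (numerator shared by Q and M)
count_ref_and_correct <- function(ctx) {
  total <- 0; correct <- 0
  for (cc in seq_len(ncol(ctx$elig))) {
    rows <- which(ctx$elig[, cc])
    k <- length(rows)
    if (k < 2L) next
    total <- total + pairs_of(k)
    r <- rle(sort(ctx$TC[rows, cc]))
    correct <- correct + sum(pairs_of(r$lengths))
  }
  c(total = total, correct = correct)
}

#' Enumerate residue-residue homology pairs of an alignment
#'
#' One pair per column and unordered row pair with residues in both rows
#' (both uppercase when `core_only`), keyed by ungapped residue indices.
#'
#' @param aln an [aa_aln].
#' @param core_only restrict to uppercase (core-block) residues.
#' @return data.frame with columns `row_i`, `pos_i`, `row_j`, `pos_j`.
#' @export
homology_pairs <- function(aln, core_only = FALSE) {
  mat <- aln_matrix(aln, upper = FALSE)
  res <- mat != "-"
  elig <- if (core_only) res & matrix(mat %in% LETTERS, nrow(mat)) else res
  P <- residue_index_matrix(aln_matrix(aln))
  out <- list()
  for (cc in seq_len(ncol(mat))) {
    rows <- which(elig[, cc])
    if (length(rows) < 2L) next
    cmb <- utils::combn(rows, 2L)
    out[[length(out) + 1L]] <- data.frame(
      row_i = cmb[1L, ], pos_i = P[cbind(cmb[1L, ], cc)],
      row_j = cmb[2L, ], pos_j = P[cbind(cmb[2L, ], cc)])
  }
  if (!length(out))
    return(data.frame(row_i = integer(), pos_i = integer(),
                      row_j = integer(), pos_j = integer()))
  do.call(rbind, out)
}

#' Q-score (sensitivity)
#'
#' Fraction of reference residue-residue homologies (core blocks only by
#' default) that are also aligned in the test alignment.
#'
#' @param test,ref [aa_aln] objects over the same sequences (matched by id up
#'   to whitespace).
#' @param core_only score only uppercase reference residues.
#' @return fraction in `[0, 1]` (NA if the reference has no scorable pairs).
#' @export
qscore <- function(test, ref, core_only = TRUE) {
  ctx <- score_context(test, ref, core_only)
  n <- count_ref_and_correct(ctx)
  if (n["total"] == 0) return(NA_real_)
  unname(n["correct"] / n["total"])
}

#' Modeler score (precision)
#'
#' Fraction of test-alignment homologies (restricted to residues inside
#' reference core blocks) that are also aligned in the reference. Correct
#' alignment of a single position yields a perfect M-score; under-alignment
#' is not penalized. Undefined (NA) when the test has no scorable pairs.
#'
#' @inheritParams qscore
#' @export
mscore <- function(test, ref, core_only = TRUE) {
  ctx <- score_context(test, ref, core_only)
  n <- count_ref_and_correct(ctx)
  denom <- 0
  for (cc in seq_len(ncol(ctx$tmat))) {
    rows <- which(ctx$tmat[, cc] != "-")
    if (core_only) {
      Pt <- vapply(rows, function(i) sum(ctx$tmat[i, seq_len(cc)] != "-"),
                   integer(1L))
      rows <- rows[mapply(function(i, p) ctx$coreflag[[i]][p], rows, Pt)]
    }
    denom <- denom + pairs_of(length(rows))
  }
  if (denom == 0) return(NA_real_)
  unname(n["correct"] / denom)
}

#' Total-column score
#'
#' Fraction of reference core columns (columns with at least one uppercase
#' residue) whose residues are all placed in a single test column.
#'
#' @inheritParams qscore
#' @export
tcscore <- function(test, ref, core_only = TRUE) {
  ctx <- score_context(test, ref, core_only)
  has_core <- colSums(ctx$elig) > 0
  cols <- which(if (core_only) has_core else colSums(ctx$rmat != "-") > 0)
  if (!length(cols)) return(NA_real_)
  ok <- vapply(cols, function(cc) {
    rows <- which(ctx$rmat[, cc] != "-")
    tc <- ctx$TC[rows, cc]
    length(unique(tc)) == 1L
  }, logical(1L))
  mean(ok)
}

#' Cline shift score
#'
#' Near-miss-tolerant accuracy: each aligned residue pair earns
#' `(1 + epsilon) / (1 + shift) - epsilon` where `shift` is the column
#' displacement of its partner relative to the other alignment (credit 0 if
#' neither residue is aligned there), summed symmetrically over test-vs-ref
#' and ref-vs-test and divided by the total number of pairs. Equals 1 iff
#' the alignments agree on all scored residues; large shifts approach
#' `-epsilon`.
#'
#' @inheritParams qscore
#' @param epsilon over-alignment penalty (default 0.2).
#' @export
cline_shift <- function(test, ref, epsilon = 0.2, core_only = TRUE) {
  ctx <- score_context(test, ref, core_only)
  n <- nrow(ctx$rmat)
  P_ref <- ctx$P_ref
  P_test <- residue_index_matrix(ctx$tmat)
  num <- 0; den <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keepfun <- function(pi, pj)
      ctx$coreflag[[i]][pi] & ctx$coreflag[[j]][pj]
    rp <- pair_map(P_ref, ctx$rmat != "-", i, j,
                   keep = if (core_only) keepfun)
    tp <- pair_map(P_test, ctx$tmat != "-", i, j,
                   keep = if (core_only) keepfun)
    dir <- function(a, b) {
      if (!length(a$pi)) return(c(0, 0))
      via_i <- b$j_of_i[a$pi]          # partner of residue i in the other aln
      via_j <- b$i_of_j[a$pj]
      s1 <- (1 + epsilon) / (1 + abs(a$pj - via_i)) - epsilon
      s2 <- (1 + epsilon) / (1 + abs(a$pi - via_j)) - epsilon
      cr <- pmax(s1, s2, na.rm = TRUE)
      cr[is.na(via_i) & is.na(via_j)] <- 0
      c(sum(cr), length(cr))
    }
    a <- dir(tp, rp); b <- dir(rp, tp)
    num <- num + a[1L] + b[1L]
    den <- den + a[2L] + b[2L]
  }
  if (den == 0) return(NA_real_)
  num / den
}

# aligned residue pairs of rows (i, j) plus partner lookup vectors; `keep`
# filters which pairs are *scored*, but the partner lookups always reflect
# the full alignment relation
pair_map <- function(P, elig, i, j, keep = NULL) {
  both <- which(elig[i, ] & elig[j, ])
  pi <- P[i, both]; pj <- P[j, both]
  ni <- max(P[i, ], 0, na.rm = TRUE); nj <- max(P[j, ], 0, na.rm = TRUE)
  j_of_i <- rep(NA_integer_, ni); i_of_j <- rep(NA_integer_, nj)
  j_of_i[pi] <- pj; i_of_j[pj] <- pi
  if (!is.null(keep)) {
    k <- keep(pi, pj)
    pi <- pi[k]; pj <- pj[k]
  }
  list(pi = pi, pj = pj, j_of_i = j_of_i, i_of_j = i_of_j)
}

#' Secondary-structure identity of a pairwise label alignment
#'
#' Columns where both rows carry the same non-gap 8-state DSSP label,
#' normalized by the maximum number of matches possible given the two label
#' multisets (sum over labels of the smaller count).
#'
#' @param pairwise a 2-row alignment of 8-state label strings; an [aa_aln]
#'   is not required -- any list with two equal-length strings in `$row` or a
#'   character vector of length 2 works.
#' @return fraction in `[0, 1]`, or NA when no match is possible.
#' @export
ss_identity <- function(pairwise) {
  rows <- if (is.character(pairwise)) pairwise else pairwise$row
  stopifnot(length(rows) == 2L, nchar(rows[1L]) == nchar(rows[2L]))
  ok <- c("H", "G", "I", "E", "B", "T", "S", "C", "-", " ")
  a <- strsplit(toupper(rows[1L]), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(rows[2L]), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(c(a, b)), ok)
  if (length(bad)) stop("invalid DSSP label '", bad[1L], "'")
  a[a == " "] <- "C"; b[b == " "] <- "C"
  matches <- sum(a != "-" & a == b)
  ta <- table(a[a != "-"]); tb <- table(b[b != "-"])
  labs <- union(names(ta), names(tb))
  denom <- sum(vapply(labs, function(l) {
    min(ifelse(is.na(ta[l]), 0, ta[l]), ifelse(is.na(tb[l]), 0, tb[l]))
  }, numeric(1L)))
  if (denom == 0) return(NA_real_)
  matches / denom
}

#' Score a test alignment against a reference
#'
#' Convenience wrapper computing all benchmark statistics at once.
#'
#' @inheritParams cline_shift
#' @return data.frame with `q`, `m`, `tc`, `cline` and `pairs_scored` (the
#'   number of reference core pairs).
#' @export
score_alignment <- function(test, ref, epsilon = 0.2, core_only = TRUE) {
  ctx <- score_context(test, ref, core_only)
  n <- count_ref_and_correct(ctx)
  data.frame(q = qscore(test, ref, core_only),
             m = mscore(test, ref, core_only),
             tc = tcscore(test, ref, core_only),
             cline = cline_shift(test, ref, epsilon, core_only),
             pairs_scored = unname(n["total"]))
}
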