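# Slow, independent re-implementations used as oracles. These deliberately
# avoid the package's fast code paths: scores are computed from first
# principles (explicit pair enumeration, direct counting) so agreement is
# meaningful.

# brute-force Q/M/TC by enumerating homology pairs as (row_i, pos_i, row_j,
# pos_j) sets from the raw row strings
brute_pairs <- function(aln, core_only) {
  rows <- lapply(aln$row, function(r) strsplit(r, "", fixed = TRUE)[[1L]])
  n <- length(rows)
  out <- character()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pi <- 0L; pj <- 0L
    for (cc in seq_along(rows[[i]])) {
      a <- rows[[i]][cc]; b <- rows[[j]][cc]
      if (a != "-") pi <- pi + 1L
      if (b != "-") pj <- pj + 1L
      if (a == "-" || b == "-") next
      if (core_only && !(a %in% LETTERS && b %in% LETTERS)) next
      out <- c(out, paste(i, pi, j, pj))
    }
  }
  out
}

brute_qscore <- function(test, ref, core_only = TRUE) {
  ord <- match(seq_keys(ref), seq_keys(test))
  test <- aa_aln(test$row[ord], test$id[ord])
  rp <- brute_pairs(ref, core_only)
  tp <- brute_pairs(test, core_only = FALSE)
  if (!length(rp)) return(NA_real_)
  mean(rp %in% tp)
}

brute_mscore <- function(test, ref, core_only = TRUE) {
  ord <- match(seq_keys(ref), seq_keys(test))
  test <- aa_aln(test$row[ord], test$id[ord])
  rp <- brute_pairs(ref, core_only)
  tp <- brute_pairs(test, core_only = FALSE)
  if (core_only) {
    # residue core flags from the reference rows
    coreflag <- lapply(ref$row, function(r) {
      ch <- strsplit(r, "", fixed = TRUE)[[1L]]
      ch[ch != "-"] %in% LETTERS
    })
    keep <- vapply(strsplit(tp, " ", fixed = TRUE), function(v) {
      coreflag[[as.integer(v[1L])]][as.integer(v[2L])] &&
        coreflag[[as.integer(v[3L])]][as.integer(v[4L])]
    }, logical(1L))
    tp <- tp[keep]
  }
  if (!length(tp)) return(NA_real_)
  mean(tp %in% rp)
}

brute_tcscore <- function(test, ref, core_only = TRUE) {
  ord <- match(seq_keys(ref), seq_keys(test))
  test <- aa_aln(test$row[ord], test$id[ord])
  rmat <- ctxalign::aln_matrix(ref, upper = FALSE)
  tmat <- ctxalign::aln_matrix(test)
  tpos <- lapply(seq_len(nrow(tmat)), function(i) which(tmat[i, ] != "-"))
  cols <- which(apply(rmat, 2L, function(col)
    if (core_only) any(col %in% LETTERS) else any(col != "-")))
  if (!length(cols)) return(NA_real_)
  ok <- vapply(cols, function(cc) {
    tcs <- integer()
    for (i in seq_len(nrow(rmat))) {
      if (rmat[i, cc] == "-") next
      p <- sum(rmat[i, seq_len(cc)] != "-")
      tcs <- c(tcs, tpos[[i]][p])
    }
    length(unique(tcs)) == 1L
  }, logical(1L))
  mean(ok)
}

# brute-force Cline shift: explicit per-residue partner search in the rows
brute_cline <- function(test, ref, epsilon = 0.2, core_only = TRUE) {
  ord <- match(seq_keys(ref), seq_keys(test))
  test <- aa_aln(test$row[ord], test$id[ord])
  chars <- function(aln) lapply(aln$row, function(r)
    strsplit(r, "", fixed = TRUE)[[1L]])
  rr <- chars(ref); tt <- chars(test)
  n <- length(rr)
  corep <- lapply(rr, function(ch) ch[ch != "-"] %in% LETTERS)
  # partner of residue p of row i w.r.t. row j in alignment `rows`
  partner <- function(rows, i, j, p) {
    ci <- rows[[i]]; cj <- rows[[j]]
    pos <- which(cumsum(ci != "-") == p & ci != "-")[1L]
    if (is.na(pos) || cj[pos] == "-") return(NA_integer_)
    sum(cj[seq_len(pos)] != "-")
  }
  num <- 0; den <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pairs_in <- function(rows, use_core) {
      ci <- rows[[i]]; cj <- rows[[j]]
      res <- list()
      pi <- 0L; pj <- 0L
      for (cc in seq_along(ci)) {
        if (ci[cc] != "-") pi <- pi + 1L
        if (cj[cc] != "-") pj <- pj + 1L
        if (ci[cc] == "-" || cj[cc] == "-") next
        if (use_core && !(corep[[i]][pi] && corep[[j]][pj])) next
        res[[length(res) + 1L]] <- c(pi, pj)
      }
      res
    }
    credit <- function(p, other_rows) {
      qj <- partner(other_rows, i, j, p[1L])
      qi <- partner(other_rows, j, i, p[2L])
      s <- -Inf
      if (!is.na(qj)) s <- max(s, (1 + epsilon) / (1 + abs(p[2L] - qj)) - epsilon)
      if (!is.na(qi)) s <- max(s, (1 + epsilon) / (1 + abs(p[1L] - qi)) - epsilon)
      if (is.infinite(s)) 0 else s
    }
    tp <- pairs_in(tt, core_only); rp <- pairs_in(rr, core_only)
    for (p in tp) { num <- num + credit(p, rr); den <- den + 1 }
    for (p in rp) { num <- num + credit(p, tt); den <- den + 1 }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# random small alignment fixtures over the same sequences: take a reference
# alignment with random case, then rebuild a test alignment by randomly
# re-gapping the same ungapped sequences
random_aln_fixture <- function(n_rows = 3L, n_cols = 8L, p_gap = 0.25,
                               p_lower = 0.3) {
  repeat {
    mat <- matrix("-", n_rows, n_cols)
    for (i in seq_len(n_rows)) {
      res <- sample(c(TRUE, FALSE), n_cols, replace = TRUE,
                    prob = c(1 - p_gap, p_gap))
      if (!any(res)) res[sample.int(n_cols, 1L)] <- TRUE
      ch <- sample(LETTERS[1:20], sum(res), replace = TRUE)
      low <- runif(sum(res)) < p_lower
      ch[low] <- tolower(ch[low])
      mat[i, res] <- ch
    }
    keep <- colSums(mat != "-") > 0
    mat <- mat[, keep, drop = FALSE]
    if (ncol(mat) > 0L) break
  }
  rows <- apply(mat, 1L, paste, collapse = "")
  # map sampled letters onto valid residues (letters beyond the 20 do occur)
  fix <- function(s) chartr("BJOUXZbjouxz", "DLKCAEdlkcae", s)
  aa_aln(fix(rows), paste0("s", seq_len(n_rows)))
}

regap_rows <- function(ref, extra_cols = 2L) {
  mat <- ctxalign::aln_matrix(ref, upper = FALSE)
  n <- nrow(mat)
  res <- lapply(seq_len(n), function(i) mat[i, mat[i, ] != "-"])
  W <- max(vapply(res, length, 1L)) + sample.int(extra_cols + 1L, 1L) - 1L
  rows <- vapply(seq_len(n), function(i) {
    r <- res[[i]]
    out <- rep("-", W)
    out[sort(sample.int(W, length(r)))] <- r
    paste(out, collapse = "")
  }, character(1L))
  keep <- colSums(ctxalign::aln_matrix(aa_aln(rows, ref$id)) != "-") > 0
  rows <- vapply(strsplit(rows, "", fixed = TRUE), function(ch)
    paste(ch[keep], collapse = ""), character(1L))
  aa_aln(rows, ref$id)
}

# random ungapped protein string from the 20 standard residues
random_protein <- function(n, bg = NULL) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aas, n, replace = TRUE, prob = bg), collapse = "")
}
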