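## Profile construction and profile-profile alignment.
##
## Column score = sum_r sum_s fa(r) fb(s) SUB[r,s]
##              + ss_weight * sum_i sum_j pa(i) pb(j) M[i,j],
## scaled by the two column occupancies; SUB is a residue substitution matrix
## and M the 3x3 symmetric structure matrix, both in third-bits so the two
## terms share a unit. Gap costs are affine with position-specific modulation
## from the gap-context model (see src/align_dp.cpp for the exact semantics).

#' Gap cost parameters
#'
#' @param open nonnegative gap opening cost (third-bits), charged for the
#'   first column of a gap run.
#' @param extend nonnegative cost per additional gap column; must not exceed
#'   `open`.
#' @param terminal_factor multiplier in `[0, 1]` applied to gaps at either
#'   end of the alignment (overhangs are common in full-length inputs, so
#'   terminal gaps are cheaper but not free).
#' @return a list of class `gap_params`.
#' @export
gap_params <- function(open = 15, extend = 1, terminal_factor = 0.5) {
  stopifnot(open >= 0, extend >= 0, extend <= open,
            terminal_factor >= 0, terminal_factor <= 1)
  structure(list(open = open, extend = extend,
                 terminal_factor = terminal_factor), class = "gap_params")
}

#' Default substitution matrix in third-bits
#'
#' BLOSUM62 (shipped with Biostrings, in half-bits) restricted to the 20
#' standard residues and rescaled by 3/2 to third-bits.
#'
#' @return 20x20 symmetric numeric matrix (third-bits).
#' @export
default_substitution_matrix <- function() {
  if (!is.null(.ctx$submat)) return(.ctx$submat)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20] * 1.5
  .ctx$submat <- m
  m
}

#' Build a structure matrix from its 6 free parameters
#'
#' @param p numeric vector of length 6 in the order HH, HE, HC, EE, EC, CC.
#' @return symmetric 3x3 matrix with dimnames H/E/C.
#' @export
structure_matrix <- function(p) {
  stopifnot(length(p) == 6L)
  m <- matrix(0, 3L, 3L, dimnames = list(HEC, HEC))
  m["H", "H"] <- p[1]; m["H", "E"] <- m["E", "H"] <- p[2]
  m["H", "C"] <- m["C", "H"] <- p[3]; m["E", "E"] <- p[4]
  m["E", "C"] <- m["C", "E"] <- p[5]; m["C", "C"] <- p[6]
  m
}

#' Default structure matrix
#'
#' The 3x3 structure log-odds matrix shipped with the package, fitted with
#' [optimize_structure_matrix()] on synthetic families (see the package
#' vignette for the fitting setup).
#'
#' @return symmetric 3x3 matrix (third-bits).
#' @export
default_structure_matrix <- function() {
  path <- system.file("extdata", "structure_matrix_v1.txt",
                      package = "ctxalign", mustWork = TRUE)
  read_score_matrix(path)
}

#' Read / write a square score matrix
#'
#' Whitespace-separated square matrix with a header row of residue or state
#' names; comment lines start with '#' (units are declared there).
#'
#' @param path file path.
#' @param m matrix to write.
#' @return the matrix (read) or `path` (write).
#' @export
read_score_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE,
                                   comment.char = "#"))
  rownames(m) <- colnames(m)
  m
}

#' @rdname read_score_matrix
#' @export
write_score_matrix <- function(m, path) {
  con <- file(path, "w"); on.exit(close(con))
  cat("# units: third-bits\n", file = con)
  cat(paste(colnames(m), collapse = "\t"), "\n", sep = "", file = con)
  utils::write.table(format(m, digits = 8), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- profiles -------------------------------------------------------------

#' Henikoff position-based sequence weights
#'
#' At each column a residue type shared by k of the n non-gap rows
#' contributes 1/(types * k) to those rows; row weights are the mean over
#' columns where the row has a residue, normalized to sum to 1.
#'
#' @param aln an [aa_aln].
#' @return numeric vector of weights summing to 1.
#' @export
henikoff_weights <- function(aln) {
  mat <- aln_matrix(aln)
  n <- nrow(mat); W <- ncol(mat)
  if (n == 1L) return(1)
  letters_seen <- c(AA_ALPHABET_FULL, "-")
  code <- matrix(match(mat, letters_seen), n, W)
  gap_code <- length(letters_seen)
  cnt <- matrix(0L, gap_code, W)
  for (v in sort(unique(as.vector(code))))
    cnt[v, ] <- colSums(code == v)
  res_cnt <- cnt[-gap_code, , drop = FALSE]
  types <- colSums(res_cnt > 0L)
  colv <- rep(seq_len(W), each = n)
  denom <- matrix(cnt[cbind(as.vector(code), colv)] * types[colv], n, W)
  isres <- code != gap_code
  contrib <- matrix(0, n, W)
  contrib[isres] <- 1 / denom[isres]
  ncols <- rowSums(isres)
  w <- rowSums(contrib) / pmax(ncols, 1)
  if (sum(w) == 0) w <- rep(1, n)
  w / sum(w)
}

#' Build an alignment profile
#'
#' Per-column weighted residue frequencies (ambiguity codes are spread over
#' their candidate residues), gap fraction, and the weighted mean of the
#' member helix/sheet/coil probability triples -- the mechanism by which
#' structure predictions are averaged as sequences are progressively merged.
#'
#' @param aln an [aa_aln].
#' @param ss list of per-row probability matrices from [predict_hec()] (rows
#'   = ungapped residues of that alignment row).
#' @param weights per-sequence nonnegative weights (default Henikoff).
#' @return an object of class `aln_profile`.
#' @export
make_profile <- function(aln, ss, weights = NULL) {
  stopifnot(inherits(aln, "aa_aln"), length(ss) == length(aln$id))
  if (is.null(weights)) weights <- henikoff_weights(aln)
  stopifnot(length(weights) == length(aln$id), all(weights >= 0),
            sum(weights) > 0)
  weights <- weights / sum(weights)
  mat <- aln_matrix(aln)
  n <- nrow(mat); W <- ncol(mat)
  amb <- ambiguity_profile_map()

  freq <- matrix(0, 20L, W, dimnames = list(AA20, NULL))
  for (ch in unique(as.vector(mat))) {
    if (ch == "-") next
    wcol <- colSums(matrix(weights * (mat == ch), n, W))
    freq <- freq + amb[, ch] %o% wcol
  }
  wres <- colSums(matrix(weights * (mat != "-"), n, W))  # weight on residues
  occ <- wres
  nz <- occ > 0
  freq[, nz] <- sweep(freq[, nz, drop = FALSE], 2L, occ[nz], "/")

  hec <- matrix(0, 3L, W, dimnames = list(HEC, NULL))
  for (r in seq_len(n)) {
    cols <- which(mat[r, ] != "-")
    if (nrow(ss[[r]]) != length(cols))
      stop("secondary-structure profile length mismatch for row ", r)
    hec[, cols] <- hec[, cols] + weights[r] * t(ss[[r]])
  }
  hec[, nz] <- sweep(hec[, nz, drop = FALSE], 2L, colSums(hec[, nz,
                                                              drop = FALSE]),
                     "/")

  cons <- rep("X", W)
  cons[nz] <- AA20[apply(freq[, nz, drop = FALSE], 2L, which.max)]

  structure(list(freq = freq, hec = hec, occupancy = occ,
                 gap_fraction = 1 - occ, consensus = paste(cons, collapse = ""),
                 weights = weights, member_count = n,
                 aln = aln, ss = ss),
            class = "aln_profile")
}

#' @export
print.aln_profile <- function(x, ...) {
  cat(sprintf("alignment profile: %d sequences x %d columns\n",
              x$member_count, ncol(x$freq)))
  invisible(x)
}

#' Score a pair of profile columns
#'
#' @param a,b lists with elements `freq` (length-20 residue frequencies),
#'   `hec` (length-3 H/E/C probabilities) and `occ` (occupancy in `[0, 1]`).
#' @param S 20x20 substitution matrix (third-bits).
#' @param M 3x3 structure matrix (third-bits).
#' @param ss_weight weight of the structure term (default 1; the two terms
#'   already share third-bit units).
#' @return column score (third-bits).
#' @export
column_score <- function(a, b, S, M, ss_weight = 1) {
  (drop(a$freq %*% S %*% b$freq) +
     ss_weight * drop(a$hec %*% M %*% b$hec)) * a$occ * b$occ
}

# full score matrix between two profiles (BLAS)
profile_score_matrix <- function(pa, pb, S, M, ss_weight) {
  sub <- crossprod(pa$freq, S %*% pb$freq)
  str <- crossprod(pa$hec, M %*% pb$hec)
  (sub + ss_weight * str) * (pa$occupancy %o% pb$occupancy)
}

# context vectors for the DP kernel: raw flank sums per boundary, raw run
# scores and opposing-extension scores per column
profile_gap_context <- function(p, gc_model) {
  W <- ncol(p$freq)
  E <- gc_model$open_scores %*% p$freq        # 8 x W expected open scores
  flank <- numeric(W + 1L)                    # boundaries 0..W
  b <- 0:W
  for (k in seq_along(GAP_OFFSETS)) {
    m <- GAP_OFFSETS[k]
    cols <- if (m < 0L) b + m + 1L else b + m
    v <- cols >= 1L & cols <= W
    flank[v] <- flank[v] + E[k, cols[v]]
  }
  runv <- run_score_vector(p$consensus, gc_model)
  extv <- as.vector(gc_model$opposing_ext %*% p$freq)
  list(flank = flank, run = runv, ext = extv)
}

#' Align two profiles
#'
#' Global affine-gap optimum over [column_score()] with position-specific
#' opening/extension costs: base costs from `gp`, modulated (and clamped) by
#' the gap-context model evaluated on the profiles' expected flank scores,
#' consensus runs and opposing columns. Terminal gaps are charged
#' `open * terminal_factor`. Tie-breaking is diagonal > up > left.
#'
#' @param pa,pb [make_profile()] objects.
#' @param S substitution matrix; `M` structure matrix.
#' @param gp [gap_params()].
#' @param gc_model a `gap_context_model` ([neutral_gap_model()] disables
#'   context modulation).
#' @param ss_weight structure-term weight (0 disables the structure score).
#' @return list with `score` and `moves` (integer vector: 1 = both profiles
#'   advance, 2 = column from `pa` only, 3 = column from `pb` only). Every
#'   input column appears exactly once, in order.
#' @export
align_profiles <- function(pa, pb, S, M, gp, gc_model, ss_weight = 1) {
  stopifnot(inherits(pa, "aln_profile"), inherits(pb, "aln_profile"))
  if (ncol(pa$freq) == 0L || ncol(pb$freq) == 0L) stop("empty profile")
  sm <- profile_score_matrix(pa, pb, S, M, ss_weight)
  ca <- profile_gap_context(pa, gc_model)
  cb <- profile_gap_context(pb, gc_model)
  align_dp_cpp(sm, ca$flank, cb$flank, ca$run, cb$run, ca$ext, cb$ext,
               gp$open, gp$extend, gp$terminal_factor,
               gc_model$clamp_fraction)
}

#' Merge two alignments according to a move trace
#'
#' @param alnA,alnB [aa_aln] objects.
#' @param moves integer trace from [align_profiles()].
#' @return an [aa_aln] containing the rows of `alnA` then `alnB`.
#' @export
merge_alignments <- function(alnA, alnB, moves) {
  idxA <- cumsum(moves != 3L)
  idxB <- cumsum(moves != 2L)
  stopifnot(max(idxA) == alnA$width, max(idxB) == alnB$width)
  expand <- function(aln, idx, use) {
    mat <- aln_matrix(aln, upper = FALSE)
    rows <- apply(mat, 1L, function(ch) {
      out <- rep("-", length(use))
      out[use] <- ch[idx[use]]
      paste(out, collapse = "")
    })
    rows
  }
  rowsA <- expand(alnA, idxA, moves != 3L)
  rowsB <- expand(alnB, idxB, moves != 2L)
  aa_aln(c(rowsA, rowsB), c(alnA$id, alnB$id))
}

## ---- structure-matrix grid search ----------------------------------------

#' Grid-search the structure matrix
#'
#' Exhaustively evaluates symmetric 3x3 matrices whose 6 free parameters are
#' drawn from `grid`, aligning each training set and scoring the sum of mean
#' Q-score and mean M-score against the references; returns the argmax (ties:
#' first in scan order). Optional coordinate-wise refinement re-scans each
#' parameter over `grid` holding the others fixed.
#'
#' @param training_sets list of lists with elements `seqs` ([aa_seqs]) and
#'   `ref` ([aa_aln] with core blocks).
#' @param grid numeric vector of candidate parameter values.
#' @param gor a `gor_model` for secondary-structure prediction.
#' @param S substitution matrix; `gp` [gap_params()]; `gc_model` gap-context
#'   model.
#' @param ss_weight structure-term weight during evaluation.
#' @param refine number of coordinate-refinement sweeps after the full grid
#'   (default 0); when `full_grid = FALSE` only coordinate sweeps from the
#'   zero matrix are performed (g * 6 per sweep instead of g^6 evaluations).
#' @param full_grid evaluate all `length(grid)^6` combinations.
#' @param verbose log evaluations via `message()`.
#' @return the best matrix, with attributes `objective` and `evaluations`.
#' @export
optimize_structure_matrix <- function(training_sets, grid, gor, S, gp,
                                      gc_model, ss_weight = 1, refine = 0L,
                                      full_grid = TRUE, verbose = FALSE) {
  if (length(training_sets) == 0L) stop("empty training set")
  if (length(grid) == 0L) stop("empty grid")
  evals <- 0L
  objective <- function(p) {
    M <- structure_matrix(p)
    qs <- ms <- numeric(length(training_sets))
    for (k in seq_along(training_sets)) {
      ts <- training_sets[[k]]
      out <- align(ts$seqs, models = list(gor = gor, gap = gc_model,
                                          subst = S, struct = M),
                   gap_par = gp, ss_weight = ss_weight)
      qs[k] <- qscore(out, ts$ref)
      m <- mscore(out, ts$ref)
      ms[k] <- if (is.na(m)) 0 else m
    }
    evals <<- evals + 1L
    mean(qs) + mean(ms)
  }

  best_p <- rep(grid[1L], 6L)
  best_obj <- -Inf
  if (full_grid) {
    combos <- as.matrix(expand.grid(rep(list(grid), 6L)))
    for (r in seq_len(nrow(combos))) {
      o <- objective(combos[r, ])
      if (o > best_obj) { best_obj <- o; best_p <- combos[r, ] }
      if (verbose) message(sprintf("grid %d/%d obj %.4f", r, nrow(combos), o))
    }
  } else {
    best_p <- rep(0, 6L)
    best_obj <- objective(best_p)
    refine <- max(refine, 1L)
  }
  for (sweep in seq_len(refine)) {
    for (d in 1:6) {
      for (g in grid) {
        cand <- best_p; cand[d] <- g
        if (all(cand == best_p)) next
        o <- objective(cand)
        if (o > best_obj) { best_obj <- o; best_p <- cand }
      }
    }
  }
  out <- structure_matrix(unname(best_p))
  attr(out, "objective") <- best_obj
  attr(out, "evaluations") <- evals
  out
}
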