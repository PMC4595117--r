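## GOR-style single-sequence secondary-structure prediction.
##
## An information-theoretic predictor over the 3 states helix (H), sheet (E),
## coil (C). For each position, single-residue and residue-pair information
## terms are accumulated over a window of `half_window` residues to either
## side (GOR IV), then normalized against the background state distribution
## before conversion to probabilities (GOR V style). Scores are natural-log
## information values internally.

HEC <- c("H", "E", "C")

# window geometry for half_window = 7: 15 offsets, 105 offset pairs
gor_offsets <- function(hw) seq.int(-hw, hw)

gor_pair_index <- function(hw) {
  off <- gor_offsets(hw)
  idx <- t(utils::combn(off, 2L))          # m1 < m2
  colnames(idx) <- c("m1", "m2")
  idx
}

#' Reduce 8-state DSSP labels to 3 states
#'
#' Mapping: H = (G, H, I); E = E; C = everything else (B, T, S, C, blank).
#'
#' @param labels character vector of 8-state label strings (or single
#'   characters). Blank/space is treated as C.
#' @return character vector of the same shape over \{H, E, C\}.
#' @export
reduce_dssp8_to3 <- function(labels) {
  map <- c(H = "H", G = "H", I = "H", E = "E",
           B = "C", T = "C", S = "C", C = "C", "-" = "C", " " = "C")
  out <- vapply(str_chars(labels), function(ch) {
    m <- map[ch]
    if (anyNA(m))
      stop("invalid DSSP label '", ch[which(is.na(m))[1L]], "'")
    paste(m, collapse = "")
  }, character(1L))
  out
}

## internal: encode sequences + 3-state labels into padded integer vectors
gor_encode <- function(seqs, labels, hw) {
  pad <- rep(NA_integer_, hw)
  codes <- list(); labs <- list()
  for (k in seq_along(seqs)) {
    ch <- toupper(strsplit(seqs[[k]], "", fixed = TRUE)[[1L]])
    lb <- strsplit(labels[[k]], "", fixed = TRUE)[[1L]]
    if (length(ch) != length(lb))
      stop("sequence/label length mismatch in record ", k)
    codes[[k]] <- c(aa_codes(ch), pad)
    labs[[k]] <- c(match(lb, HEC), pad)
  }
  list(codes = c(pad, unlist(codes)), labels = c(pad, unlist(labs)))
}

#' Train a GOR secondary-structure model
#'
#' Estimates single-residue and residue-pair information tables
#' log(f(residue at offset | state) / f(residue at offset)) from a labeled
#' corpus. Single-residue cells receive a uniform pseudocount; the pair
#' tables receive the same total pseudocount mass distributed according to
#' the independence product of the smoothed single-residue frequencies, so a
#' pair cell with no observations scores approximately the sum of its two
#' single scores (up to a state-balance normalization term) and the
#' predictor degrades gracefully where pair data are sparse.
#'
#' @param seqs an [aa_seqs] object or character vector of residue strings.
#' @param labels character vector of 3-state (H/E/C) label strings, parallel
#'   to `seqs` (use [reduce_dssp8_to3()] for DSSP input).
#' @param pseudocount nonnegative count added to every cell (default 1).
#' @param half_window window radius in residues (default 7).
#' @return an object of class `gor_model`.
#' @export
train_gor <- function(seqs, labels, pseudocount = 1, half_window = 7L) {
  if (inherits(seqs, "aa_seqs")) seqs <- seqs$seq
  if (length(seqs) == 0L) stop("empty corpus")
  stopifnot(length(seqs) == length(labels), pseudocount >= 0)
  hw <- as.integer(half_window)
  noff <- 2L * hw + 1L
  pidx <- gor_pair_index(hw)
  npair <- nrow(pidx)

  enc <- gor_encode(seqs, labels, hw)
  lab <- enc$labels; cod <- enc$codes
  P <- which(!is.na(lab))
  if (!all(1:3 %in% lab[P])) stop("every state (H, E, C) must be observed")

  # single-residue counts: [state, offset, residue]
  cs <- numeric(3L * noff * 20L)
  offs <- gor_offsets(hw)
  labP <- lab[P]
  for (mi in seq_len(noff)) {
    r <- cod[P + offs[mi]]
    v <- !is.na(r)
    idx <- (labP[v] - 1L) * (noff * 20L) + (mi - 1L) * 20L + r[v]
    cs <- cs + tabulate(idx, nbins = 3L * noff * 20L)
  }
  cs <- array(cs, dim = c(20L, noff, 3L))      # filled residue-fastest
  cs <- aperm(cs, c(3L, 2L, 1L))               # -> [state, offset, residue]

  # residue-pair counts: [state, pair, r1 x r2]
  cp <- numeric(3L * npair * 400L)
  for (pi in seq_len(npair)) {
    r1 <- cod[P + pidx[pi, 1L]]
    r2 <- cod[P + pidx[pi, 2L]]
    v <- !is.na(r1) & !is.na(r2)
    idx <- (labP[v] - 1L) * (npair * 400L) + (pi - 1L) * 400L +
      (r1[v] - 1L) * 20L + r2[v]
    cp <- cp + tabulate(idx, nbins = 3L * npair * 400L)
  }
  cp <- array(cp, dim = c(400L, npair, 3L))
  cp <- aperm(cp, c(3L, 2L, 1L))               # -> [state, pair, respair]

  # single-residue tables: uniform pseudocount
  tot_s <- apply(cs, c(1L, 2L), sum)
  f_cond1 <- sweep(cs + pseudocount, c(1L, 2L), tot_s + 20 * pseudocount, "/")
  marg1 <- apply(cs, c(2L, 3L), sum)
  f_marg1 <- (marg1 + 3 * pseudocount) /
    (rowSums(marg1) + 60 * pseudocount)
  singles <- sweep(log(f_cond1), c(2L, 3L), log(f_marg1), "-")

  # pair tables: the pseudocount mass is distributed over cells according to
  # the independence product of the (smoothed) single-residue frequencies, so
  # an unobserved pair cell scores close to the sum of its two single scores
  # (exactly, up to a state-balance normalization constant) and the
  # combination formula degrades gracefully to the singles-only prediction
  # where pair data are sparse
  A <- 400 * pseudocount
  mi1 <- match(pidx[, 1L], offs); mi2 <- match(pidx[, 2L], offs)
  prior_c <- array(0, dim(cp))
  prior_m <- matrix(0, npair, 400L)
  for (pi in seq_len(npair)) {
    for (s in 1:3)
      prior_c[s, pi, ] <- as.vector(t(outer(f_cond1[s, mi1[pi], ],
                                            f_cond1[s, mi2[pi], ])))
    prior_m[pi, ] <- as.vector(t(outer(f_marg1[mi1[pi], ],
                                       f_marg1[mi2[pi], ])))
  }
  tot_p <- apply(cp, c(1L, 2L), sum)
  f_condp <- sweep(cp + A * prior_c, c(1L, 2L), tot_p + A, "/")
  margp <- apply(cp, c(2L, 3L), sum)
  f_margp <- sweep(margp + 3 * A * prior_m, 1L,
                   rowSums(margp) + 3 * A, "/")
  pairs <- sweep(log(f_condp), c(2L, 3L), log(f_margp), "-")

  bg_states <- tabulate(labP, 3L); bg_states <- bg_states / sum(bg_states)
  names(bg_states) <- HEC
  rc <- tabulate(cod[P][!is.na(cod[P])], 20L)
  bg_res <- setNames((rc + pseudocount) / sum(rc + pseudocount * 20), AA20)

  structure(list(
    half_window = hw,
    background = list(states = bg_states, residues = bg_res),
    singles = singles,
    pairs = pairs,
    pair_index = pidx,
    pseudocount = pseudocount,
    # GOR IV combination: (2/n) * sum(pair info) - ((n-2)/n) * sum(single
    # info), with n the number of in-range window positions at a site; equals
    # the plain sum of single informations whenever pair information
    # decomposes additively.
    combination = "gor4"
  ), class = "gor_model")
}

#' @export
print.gor_model <- function(x, ...) {
  cat("GOR secondary-structure model\n")
  cat(sprintf("  window: +/- %d residues (%d offsets, %d offset pairs)\n",
              x$half_window, 2 * x$half_window + 1, nrow(x$pair_index)))
  cat(sprintf("  background states: H %.3f  E %.3f  C %.3f\n",
              x$background$states[1], x$background$states[2],
              x$background$states[3]))
  cat(sprintf("  pseudocount: %g\n", x$pseudocount))
  invisible(x)
}

#' Predict helix/sheet/coil probabilities for one sequence
#'
#' Sums single and pair information over in-range window offsets with the
#' GOR IV combination, then converts the background-normalized state scores
#' to a probability triple per position (softmax over information scores,
#' which divides out the background state distribution).
#'
#' @param seq a residue string (or single-sequence [aa_seqs]).
#' @param model a [train_gor()] model.
#' @return numeric matrix, length(seq) x 3, columns H/E/C, rows summing to 1.
#' @export
predict_hec <- function(seq, model) {
  stopifnot(inherits(model, "gor_model"))
  if (inherits(seq, "aa_seqs")) {
    if (length(seq$seq) != 1L) stop("predict_hec takes one sequence")
    seq <- seq$seq
  }
  ch <- toupper(strsplit(seq, "", fixed = TRUE)[[1L]])
  L <- length(ch)
  if (L == 0L) stop("empty sequence")
  hw <- model$half_window
  cod <- c(rep(NA_integer_, hw), aa_codes(ch), rep(NA_integer_, hw))
  pos <- seq_len(L) + hw
  offs <- gor_offsets(hw)
  noff <- length(offs)

  ssum <- matrix(0, 3L, L)
  for (mi in seq_len(noff)) {
    r <- cod[pos + offs[mi]]
    v <- which(!is.na(r))
    if (!length(v)) next
    for (s in 1:3) ssum[s, v] <- ssum[s, v] + model$singles[s, mi, r[v]]
  }
  psum <- matrix(0, 3L, L)
  pidx <- model$pair_index
  for (pi in seq_len(nrow(pidx))) {
    r1 <- cod[pos + pidx[pi, 1L]]
    r2 <- cod[pos + pidx[pi, 2L]]
    v <- which(!is.na(r1) & !is.na(r2))
    if (!length(v)) next
    ri <- (r1[v] - 1L) * 20L + r2[v]
    for (s in 1:3) psum[s, v] <- psum[s, v] + model$pairs[s, pi, ri]
  }
  j <- seq_len(L)
  n <- pmin(L, j + hw) - pmax(1L, j - hw) + 1L
  comb <- sweep(psum, 2L, 2 / n, "*") - sweep(ssum, 2L, (n - 2) / n, "*")

  comb <- sweep(comb, 2L, apply(comb, 2L, max), "-")
  e <- exp(comb)
  pr <- t(sweep(e, 2L, colSums(e), "/"))
  colnames(pr) <- HEC
  pr
}

#' @rdname predict_hec
#' @param object a `gor_model`.
#' @param seqs sequences ([aa_seqs] or character vector).
#' @param ... unused.
#' @return for `predict.gor_model`, a list of probability matrices.
#' @export
predict.gor_model <- function(object, seqs, ...) {
  if (inherits(seqs, "aa_seqs")) seqs <- seqs$seq
  lapply(seqs, predict_hec, model = object)
}

#' Predict a 3-state string
#'
#' Argmax state per position. Ties resolve to C when C is among the tied
#' states (the majority background state), then H over E; the rule makes the
#' output deterministic.
#'
#' @inheritParams predict_hec
#' @return a character string over \{H, E, C\}.
#' @export
predict_hec_states <- function(seq, model) {
  pr <- predict_hec(seq, model)
  pick <- apply(pr, 1L, function(p) {
    tied <- which(p >= max(p) - 1e-12)
    if (3L %in% tied) 3L else min(tied)   # C first, then H over E
  })
  paste(HEC[pick], collapse = "")
}

## ---- model file I/O -------------------------------------------------------

#' Write / read a GOR model as plain text
#'
#' Tab-separated tables with a key-value header block (background
#' frequencies, window, pseudocount, combination weights).
#'
#' @param model a `gor_model`.
#' @param path file path.
#' @return `path` (write) or a `gor_model` (read).
#' @export
write_gor_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  wr <- function(...) cat(..., "\n", sep = "", file = con)
  wr("# gor_model v1")
  wr("# half_window\t", model$half_window)
  wr("# pseudocount\t", model$pseudocount)
  wr("# combination\t", model$combination,
     " (score = (2/n)*sum_pairs - ((n-2)/n)*sum_singles, n = in-range offsets)")
  wr("# background_states\t", paste(sprintf("%s=%.8g", HEC,
                                            model$background$states),
                                    collapse = "\t"))
  wr("# background_residues\t", paste(sprintf("%s=%.8g", AA20,
                                              model$background$residues),
                                      collapse = "\t"))
  offs <- gor_offsets(model$half_window)
  wr("SINGLES\tstate\toffset\tresidue\tscore")
  for (s in 1:3) for (mi in seq_along(offs)) {
    cat(paste("S", HEC[s], offs[mi], AA20,
              sprintf("%.8g", model$singles[s, mi, ]), sep = "\t"),
        sep = "\n", file = con)
  }
  wr("PAIRS\tstate\tm1\tm2\tres1\tres2\tscore")
  pidx <- model$pair_index
  rp <- expand.grid(r2 = AA20, r1 = AA20, stringsAsFactors = FALSE)
  rp <- rp[order(match(rp$r1, AA20), match(rp$r2, AA20)), ]
  for (s in 1:3) for (pi in seq_len(nrow(pidx))) {
    cat(paste("P", HEC[s], pidx[pi, 1L], pidx[pi, 2L], rp$r1, rp$r2,
              sprintf("%.8g", model$pairs[s, pi, ]), sep = "\t"),
        sep = "\n", file = con)
  }
  invisible(path)
}

#' @rdname write_gor_model
#' @export
read_gor_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)][1L]
    strsplit(sub(paste0("^# ", key, "\t"), "", ln), "\t")[[1L]]
  }
  hw <- as.integer(getv("half_window")[1L])
  pc <- as.numeric(getv("pseudocount")[1L])
  parse_kv <- function(v) {
    kv <- strsplit(v, "=", fixed = TRUE)
    setNames(as.numeric(vapply(kv, `[`, "", 2L)),
             vapply(kv, `[`, "", 1L))
  }
  bg_states <- parse_kv(getv("background_states"))
  bg_res <- parse_kv(getv("background_residues"))

  noff <- 2L * hw + 1L
  pidx <- gor_pair_index(hw)
  offs <- gor_offsets(hw)
  body <- lines[!startsWith(lines, "#")]
  sdf <- utils::read.table(text = body[startsWith(body, "S\t")], sep = "\t",
                           stringsAsFactors = FALSE)
  singles <- array(NA_real_, c(3L, noff, 20L))
  singles[cbind(match(sdf[[2L]], HEC), match(sdf[[3L]], offs),
                match(sdf[[4L]], AA20))] <- sdf[[5L]]
  pdf <- utils::read.table(text = body[startsWith(body, "P\t")], sep = "\t",
                           stringsAsFactors = FALSE)
  pkey <- paste(pidx[, 1L], pidx[, 2L])
  pairs <- array(NA_real_, c(3L, nrow(pidx), 400L))
  pairs[cbind(match(pdf[[2L]], HEC), match(paste(pdf[[3L]], pdf[[4L]]), pkey),
              (match(pdf[[5L]], AA20) - 1L) * 20L + match(pdf[[6L]], AA20))] <-
    pdf[[7L]]
  if (anyNA(singles) || anyNA(pairs)) stop("incomplete GOR model file")
  structure(list(half_window = hw,
                 background = list(states = bg_states[HEC],
                                   residues = bg_res[AA20]),
                 singles = singles, pairs = pairs, pair_index = pidx,
                 pseudocount = pc, combination = "gor4"),
            class = "gor_model")
}
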