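## Local-sequence-context model of gap likelihood.
##
## Gap opening is modulated by the residues at offsets -4..+4 (excluding the
## gap itself) in the strand that carries the gap; gap extension by the
## residue opposite the gap, position-independently; and two scalar run terms
## capture the effect of homopolymer runs in the opposing strand. All scores
## are log-odds in third-bits (log2 odds x 3): positive = gap more likely.
## The aligner subtracts the (clamped) modifier from the base cost, so the
## applied change never exceeds clamp_fraction (default 20 %) of the base.

GAP_OFFSETS <- c(-4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L)

#' Convert a probability ratio to third-bits
#'
#' `log(observed/background) * 3 / log(2)`. A doubling is exactly +3
#' third-bits.
#'
#' @param observed,background strictly positive probabilities (vectorized).
#' @return log-odds score(s) in third-bits.
#' @export
to_third_bits <- function(observed, background) {
  if (any(observed <= 0) || any(background <= 0))
    stop("probabilities must be strictly positive")
  log(observed / background) * 3 / log(2)
}

#' Detect homopolymer runs
#'
#' Maximal runs of identical residues of at least `min_len`.
#'
#' @param seq residue string.
#' @param min_len minimum run length (default 3).
#' @return data.frame with columns `start` (1-based), `length`, `residue`.
#' @export
detect_runs <- function(seq, min_len = 3L) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (!length(ch))
    return(data.frame(start = integer(), length = integer(),
                      residue = character(), stringsAsFactors = FALSE))
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len & r$values != "-"
  data.frame(start = (ends - r$lengths + 1L)[keep],
             length = r$lengths[keep],
             residue = r$values[keep], stringsAsFactors = FALSE)
}

# per-position run score for a gap opposite position p of `seq`:
#   penalty when a run (length >= 2) starts at p - 1  (gap right after the
#     start of an opposing run, the AA/A- configuration);
#   bonus   when p lies inside a run of length >= 3 (and is not the
#     after-start position).
run_score_vector <- function(seq, model) {
  L <- nchar(seq)
  v <- numeric(L)
  if (L == 0L) return(v)
  r3 <- detect_runs(seq, 3L)
  for (k in seq_len(nrow(r3))) {
    idx <- r3$start[k]:(r3$start[k] + r3$length[k] - 1L)
    v[idx] <- model$run_open_bonus
  }
  r2 <- detect_runs(seq, 2L)
  after <- r2$start + 1L
  after <- after[after <= L]
  v[after] <- model$run_after_penalty
  v
}

## ---- gap events -----------------------------------------------------------

#' Extract internal gap events from pairwise alignments
#'
#' Applies the estimation filters: terminal gaps are excluded; a pair must
#' exceed `min_identity` over its matched columns and all of its gap events
#' must be separated by at least `min_separation` columns, otherwise the pair
#' contributes nothing. Each retained maximal gap run becomes one event of
#' weight 1.
#'
#' @param pairs list of 2-row [aa_aln] alignments.
#' @param min_separation minimum columns between gap events (default 20).
#' @param min_identity identity over matched columns that a pair must exceed
#'   (default 0.5).
#' @param reverse_consistent also re-extract events from the reversed pair and
#'   keep only events found in both orientations (mitigation for repetitive
#'   regions).
#' @return list of gap events; each is a list with the two (uppercased) rows,
#'   `gap_start`/`gap_end` (1-based, inclusive), `gapped_row` (1 or 2) and
#'   `weight`. Filter counts are attached as attribute `dropped`.
#' @export
extract_gap_events <- function(pairs, min_separation = 20L,
                               min_identity = 0.5,
                               reverse_consistent = FALSE) {
  events <- list()
  dropped <- c(identity = 0L, separation = 0L)
  for (pr in pairs) {
    stopifnot(inherits(pr, "aa_aln"), length(pr$id) == 2L)
    a <- toupper(pr$row[[1L]]); b <- toupper(pr$row[[2L]])
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(b, "", fixed = TRUE)[[1L]]
    keep <- !(ca == "-" & cb == "-")
    ca <- ca[keep]; cb <- cb[keep]
    matched <- ca != "-" & cb != "-"
    if (!any(matched)) { dropped["identity"] <- dropped["identity"] + 1L; next }
    ident <- mean(ca[matched] == cb[matched])
    if (!(ident > min_identity)) {
      dropped["identity"] <- dropped["identity"] + 1L; next
    }
    runs <- pair_gap_runs(ca, cb)
    if (!nrow(runs)) next
    # separation between consecutive events (columns between end and the
    # next start, across both rows)
    if (nrow(runs) > 1L) {
      o <- order(runs$start)
      sep <- runs$start[o][-1L] - runs$end[o][-nrow(runs)] - 1L
      if (any(sep < min_separation)) {
        dropped["separation"] <- dropped["separation"] + 1L; next
      }
    }
    if (reverse_consistent) {
      w <- length(ca)
      rruns <- pair_gap_runs(rev(ca), rev(cb))
      rkey <- paste(w - rruns$end + 1L, w - rruns$start + 1L, rruns$row)
      ok <- paste(runs$start, runs$end, runs$row) %in% rkey
      runs <- runs[ok, , drop = FALSE]
    }
    A <- paste(ca, collapse = ""); B <- paste(cb, collapse = "")
    for (k in seq_len(nrow(runs))) {
      events[[length(events) + 1L]] <- list(
        rows = c(A, B), gap_start = runs$start[k], gap_end = runs$end[k],
        gapped_row = runs$row[k], weight = 1)
    }
  }
  attr(events, "dropped") <- dropped
  events
}

# internal gap runs (terminal runs excluded) of a 2-row alignment
pair_gap_runs <- function(ca, cb) {
  out <- data.frame(start = integer(), end = integer(), row = integer())
  w <- length(ca)
  for (row in 1:2) {
    g <- if (row == 1L) ca == "-" else cb == "-"
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values & starts > 1L & ends < w
    if (any(sel))
      out <- rbind(out, data.frame(start = starts[sel], end = ends[sel],
                                   row = row))
  }
  out
}

#' Expand a gap event into its equivalent placements
#'
#' A gap adjacent to repeated opposing residues can slide without changing
#' the column multiset (e.g. AA/A- and AA/-A); all such placements are
#' returned with the weight split evenly so total weight is conserved.
#'
#' @param event a gap event from [extract_gap_events()].
#' @return list of events whose weights sum to `event$weight`.
#' @export
expand_equivalent_placements <- function(event) {
  ca <- strsplit(event$rows[[1L]], "", fixed = TRUE)[[1L]]
  cb <- strsplit(event$rows[[2L]], "", fixed = TRUE)[[1L]]
  g <- if (event$gapped_row == 1L) ca else cb
  o <- if (event$gapped_row == 1L) cb else ca
  s <- event$gap_start; e <- event$gap_end
  len <- e - s + 1L
  colkey <- function(gv) sort(paste(gv, o))
  base_key <- colkey(g)
  shift <- function(gv, s2) {
    # place the same gap run at columns s2..s2+len-1, residues keep order
    res <- gv[gv != "-"]
    out <- character(length(gv))
    out[s2:(s2 + len - 1L)] <- "-"
    out[out != "-"] <- res
    out
  }
  placements <- list(c(s, e))
  for (dir in c(-1L, 1L)) {
    k <- 1L
    repeat {
      s2 <- s + dir * k
      if (s2 < 1L || s2 + len - 1L > length(g)) break
      cand <- shift(g, s2)
      if (!identical(colkey(cand), base_key)) break
      placements[[length(placements) + 1L]] <- c(s2, s2 + len - 1L)
      k <- k + 1L
    }
  }
  wt <- event$weight / length(placements)
  lapply(placements, function(p) {
    gv <- shift(g, p[1L])
    rows <- if (event$gapped_row == 1L)
      c(paste(gv, collapse = ""), paste(o, collapse = ""))
    else c(paste(o, collapse = ""), paste(gv, collapse = ""))
    list(rows = rows, gap_start = p[1L], gap_end = p[2L],
         gapped_row = event$gapped_row, weight = wt)
  })
}

## ---- estimation -----------------------------------------------------------

#' Estimate the gap-context model from gap events
#'
#' Weighted residue frequencies at offsets -4..+4 from the gap boundary (in
#' the gapped strand), and opposite the gap (in the ungapped strand), are
#' converted into log-odds in third-bits against the background frequencies.
#' The two run terms compare how often the first gap column sits inside /
#' right after the start of an opposing-strand run against the rate at which
#' arbitrary positions do.
#'
#' @param events list of gap events ([extract_gap_events()], optionally
#'   expanded with [expand_equivalent_placements()]).
#' @param background strictly positive residue frequencies (named, AA20).
#' @param clamp_fraction cap on the applied cost modulation, as a fraction of
#'   the base gap cost (default 0.20).
#' @param pseudocount weight added (spread over residues) to regularize
#'   frequencies (default 1).
#' @return an object of class `gap_context_model`.
#' @export
estimate_gap_model <- function(events, background = AA_BACKGROUND,
                               clamp_fraction = 0.2, pseudocount = 1) {
  if (length(events) == 0L) stop("no gap events")
  stopifnot(all(background > 0))
  background <- background[AA20] / sum(background[AA20])

  open_w <- matrix(0, nrow = length(GAP_OFFSETS), ncol = 20L,
                   dimnames = list(as.character(GAP_OFFSETS), AA20))
  ext_w <- setNames(numeric(20L), AA20)
  run_obs <- c(inside = 0, after = 0); run_tot <- 0
  bg_pos <- c(inside = 0, after = 0); bg_tot <- 0
  seen_opp <- new.env(parent = emptyenv())

  for (ev in events) {
    w <- ev$weight
    gi <- ev$gapped_row; oi <- 3L - gi
    grow <- strsplit(ev$rows[[gi]], "", fixed = TRUE)[[1L]]
    orow <- strsplit(ev$rows[[oi]], "", fixed = TRUE)[[1L]]
    u <- grow[grow != "-"]
    bp <- sum(grow[seq_len(ev$gap_start - 1L)] != "-")  # residues before gap
    for (k in seq_along(GAP_OFFSETS)) {
      m <- GAP_OFFSETS[k]
      idx <- if (m < 0L) bp + m + 1L else bp + m
      if (idx >= 1L && idx <= length(u)) {
        ri <- match(u[idx], AA20)
        if (!is.na(ri)) open_w[k, ri] <- open_w[k, ri] + w
      }
    }
    opp_in_gap <- orow[ev$gap_start:ev$gap_end]
    ri <- match(opp_in_gap, AA20)
    for (r in ri[!is.na(ri)]) ext_w[r] <- ext_w[r] + w

    # run context in the opposing strand at the first gap column
    oseq <- paste(orow[orow != "-"], collapse = "")
    p <- sum(orow[seq_len(ev$gap_start)] != "-")  # opposing ungapped index
    if (p >= 1L) {
      rs <- run_flags(oseq)
      run_tot <- run_tot + w
      if (rs$after[p]) run_obs["after"] <- run_obs["after"] + w
      else if (rs$inside[p]) run_obs["inside"] <- run_obs["inside"] + w
      if (!exists(oseq, envir = seen_opp, inherits = FALSE)) {
        assign(oseq, TRUE, envir = seen_opp)  # count each sequence once
        bg_tot <- bg_tot + nchar(oseq)
        bg_pos["after"] <- bg_pos["after"] + sum(rs$after)
        bg_pos["inside"] <- bg_pos["inside"] + sum(rs$inside & !rs$after)
      }
    }
  }

  pc <- pseudocount
  open_f <- sweep(open_w + pc / 20, 1L, rowSums(open_w) + pc, "/")
  open_scores <- to_third_bits(open_f, rep(background, each = nrow(open_f)))
  ext_f <- (ext_w + pc / 20) / (sum(ext_w) + pc)
  opposing_ext <- to_third_bits(ext_f, background)

  rate <- function(obs, tot) (obs + 1) / (tot + 2)
  run_open_bonus <- to_third_bits(rate(run_obs["inside"], run_tot),
                                  rate(bg_pos["inside"], bg_tot))
  run_after_penalty <- to_third_bits(rate(run_obs["after"], run_tot),
                                     rate(bg_pos["after"], bg_tot))

  structure(list(open_scores = open_scores,
                 opposing_ext = opposing_ext,
                 run_open_bonus = unname(run_open_bonus),
                 run_after_penalty = unname(run_after_penalty),
                 clamp_fraction = clamp_fraction,
                 background = background,
                 n_events = length(events)),
            class = "gap_context_model")
}

# logical flags per position of `seq`: inside a run >= 3; right after the
# start of a run >= 2
run_flags <- function(seq) {
  L <- nchar(seq)
  inside <- logical(L); after <- logical(L)
  r3 <- detect_runs(seq, 3L)
  for (k in seq_len(nrow(r3)))
    inside[r3$start[k]:(r3$start[k] + r3$length[k] - 1L)] <- TRUE
  r2 <- detect_runs(seq, 2L)
  a <- r2$start + 1L
  after[a[a <= L]] <- TRUE
  list(inside = inside, after = after)
}

#' A neutral (all-zero) gap-context model
#'
#' @param clamp_fraction clamp to store (default 0.2).
#' @return a `gap_context_model` whose every score is 0.
#' @export
neutral_gap_model <- function(clamp_fraction = 0.2) {
  structure(list(
    open_scores = matrix(0, length(GAP_OFFSETS), 20L,
                         dimnames = list(as.character(GAP_OFFSETS), AA20)),
    opposing_ext = setNames(numeric(20L), AA20),
    run_open_bonus = 0, run_after_penalty = 0,
    clamp_fraction = clamp_fraction,
    background = AA_BACKGROUND, n_events = 0L), class = "gap_context_model")
}

#' @export
print.gap_context_model <- function(x, ...) {
  cat("gap-context model (third-bits)\n")
  cat(sprintf("  fitted from %d events; clamp +/- %.0f%% of base cost\n",
              x$n_events, 100 * x$clamp_fraction))
  cat(sprintf("  run terms: bonus %+.2f, after-start %+.2f\n",
              x$run_open_bonus, x$run_after_penalty))
  cat("  strongest opening effects (offset -1):\n")
  s <- sort(x$open_scores["-1", ])
  cat(sprintf("    avoid: %s   favor: %s\n",
              paste(sprintf("%s %+.2f", names(head(s, 3)), head(s, 3)),
                    collapse = ", "),
              paste(sprintf("%s %+.2f", names(tail(s, 3)), tail(s, 3)),
                    collapse = ", ")))
  invisible(x)
}

## ---- applying the model ---------------------------------------------------

clamp_mod <- function(raw, base_cost, clamp_fraction) {
  if (is.null(base_cost)) return(raw)
  lim <- clamp_fraction * base_cost
  pmin(pmax(raw, -lim), lim)
}

#' Gap-opening modifier at a boundary
#'
#' Sums the per-offset opening scores over the in-range offsets -4..+4 around
#' `boundary` of the gapped strand, plus the run terms evaluated on the
#' opposing context. Positive values mean a gap is favored here; the caller
#' subtracts the modifier from its base opening cost. When `base_cost` is
#' given the result is clamped to +/- `clamp_fraction * base_cost`.
#'
#' @param seq residue string of the strand that would carry the gap.
#' @param boundary integer in `[0, nchar(seq)]`; the gap would open between
#'   residues `boundary` and `boundary + 1`.
#' @param model a `gap_context_model`.
#' @param opposing optional residue string of the opposing strand; the gap is
#'   taken to sit opposite its position `boundary + 1`.
#' @param base_cost optional base opening cost used for clamping.
#' @return modifier in third-bits.
#' @export
gap_open_modifier <- function(seq, boundary, model, opposing = NULL,
                              base_cost = NULL) {
  L <- nchar(seq)
  if (boundary < 0L || boundary > L) stop("boundary out of range")
  ch <- toupper(strsplit(seq, "", fixed = TRUE)[[1L]])
  raw <- 0
  for (k in seq_along(GAP_OFFSETS)) {
    m <- GAP_OFFSETS[k]
    idx <- if (m < 0L) boundary + m + 1L else boundary + m
    if (idx >= 1L && idx <= L) {
      ri <- match(ch[idx], AA20)
      if (!is.na(ri)) raw <- raw + model$open_scores[k, ri]
    }
  }
  if (!is.null(opposing) && nzchar(opposing)) {
    rv <- run_score_vector(toupper(opposing), model)
    p <- boundary + 1L
    if (p >= 1L && p <= length(rv)) raw <- raw + rv[p]
  }
  clamp_mod(raw, base_cost, model$clamp_fraction)
}

#' Gap-extension modifier
#'
#' Position-independent score for the residue opposite a gap column. Unknown
#' or ambiguity residues score 0.
#'
#' @param opposing_residue single residue character.
#' @param model a `gap_context_model`.
#' @param base_cost optional base extension cost used for clamping.
#' @return modifier in third-bits.
#' @export
gap_extension_modifier <- function(opposing_residue, model,
                                   base_cost = NULL) {
  ri <- match(toupper(opposing_residue), AA20)
  raw <- if (is.na(ri)) 0 else unname(model$opposing_ext[ri])
  clamp_mod(raw, base_cost, model$clamp_fraction)
}

## ---- model file I/O -------------------------------------------------------

#' Write / read a gap-context model as plain text
#'
#' @param model a `gap_context_model`.
#' @param path file path.
#' @return `path` (write) or a `gap_context_model` (read).
#' @export
write_gap_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  cat("# gap_context_model v1\n", file = con)
  cat(sprintf("# clamp_fraction\t%.8g\n", model$clamp_fraction), file = con)
  cat(sprintf("# run_open_bonus\t%.8g\n", model$run_open_bonus), file = con)
  cat(sprintf("# run_after_penalty\t%.8g\n", model$run_after_penalty),
      file = con)
  cat("# background\t",
      paste(sprintf("%s=%.8g", AA20, model$background[AA20]),
            collapse = "\t"), "\n", sep = "", file = con)
  for (k in seq_along(GAP_OFFSETS))
    cat(paste("OPEN", GAP_OFFSETS[k], AA20,
              sprintf("%.8g", model$open_scores[k, ]), sep = "\t"),
        sep = "\n", file = con)
  cat(paste("EXT", AA20, sprintf("%.8g", model$opposing_ext), sep = "\t"),
      sep = "\n", file = con)
  invisible(path)
}

#' @rdname write_gap_model
#' @export
read_gap_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getnum <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)][1L]
    as.numeric(sub(paste0("^# ", key, "\t"), "", ln))
  }
  bgln <- hdr[grepl("^# background\t", hdr)][1L]
  kv <- strsplit(strsplit(sub("^# background\t", "", bgln), "\t")[[1L]], "=")
  bg <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                 vapply(kv, `[`, "", 1L))
  body <- lines[!startsWith(lines, "#")]
  od <- utils::read.table(text = body[startsWith(body, "OPEN\t")], sep = "\t",
                          stringsAsFactors = FALSE)
  open_scores <- matrix(NA_real_, length(GAP_OFFSETS), 20L,
                        dimnames = list(as.character(GAP_OFFSETS), AA20))
  open_scores[cbind(match(od[[2L]], GAP_OFFSETS), match(od[[3L]], AA20))] <-
    od[[4L]]
  ed <- utils::read.table(text = body[startsWith(body, "EXT\t")], sep = "\t",
                          stringsAsFactors = FALSE)
  opposing_ext <- setNames(numeric(20L), AA20)
  opposing_ext[match(ed[[2L]], AA20)] <- ed[[3L]]
  structure(list(open_scores = open_scores, opposing_ext = opposing_ext,
                 run_open_bonus = getnum("run_open_bonus"),
                 run_after_penalty = getnum("run_after_penalty"),
                 clamp_fraction = getnum("clamp_fraction"),
                 background = bg[AA20], n_events = NA_integer_),
            class = "gap_context_model")
}
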