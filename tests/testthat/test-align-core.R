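test_that("gap parameter and structure matrix constructors validate input", {
  gp <- gap_params()
  expect_identical(gp$open, 15)
  expect_error(gap_params(open = -1), "open")
  expect_error(gap_params(open = 1, extend = 2), "extend")
  expect_error(gap_params(terminal_factor = 1.5), "terminal_factor")
  M <- structure_matrix(c(1, -2, -3, 4, -5, 6))
  expect_identical(M, t(M))
  expect_identical(M["H", "E"], -2)
  expect_identical(M["C", "E"], -5)
  expect_error(structure_matrix(1:5), "6")
})

test_that("score matrix files round-trip", {
  M <- structure_matrix(c(1.25, -2, -3, 4, -5.5, 6))
  tmp <- tempfile(fileext = ".txt")
  write_score_matrix(M, tmp)
  expect_equal(read_score_matrix(tmp), M, tolerance = 1e-7)
})

test_that("Henikoff weights match the direct per-column definition", {
  set.seed(61)
  for (k in 1:20) {
    aln <- random_aln_fixture(n_rows = sample(2:6, 1L),
                              n_cols = sample(4:10, 1L))
    w <- henikoff_weights(aln)
    # oracle: literal definition with table() per column
    mat <- aln_matrix(aln)
    n <- nrow(mat)
    contrib <- matrix(0, n, ncol(mat))
    for (cc in seq_len(ncol(mat))) {
      col <- mat[, cc]
      res <- col != "-"
      if (!any(res)) next
      tab <- table(col[res])
      for (i in which(res))
        contrib[i, cc] <- 1 / (length(tab) * tab[[col[i]]])
    }
    isres <- mat != "-"
    w0 <- rowSums(contrib) / pmax(rowSums(isres), 1L)
    w0 <- w0 / sum(w0)
    expect_equal(w, w0, tolerance = 1e-12)
  }
  # duplicated sequences share weight
  aln <- aa_aln(c("MKVW", "MKVW", "MAVW"), c("a", "b", "c"))
  w <- henikoff_weights(aln)
  expect_equal(w[1L], w[2L])
  expect_gt(w[3L], w[1L])
})

test_that("profiles hold weighted frequencies with ambiguity spreading", {
  ssH <- matrix(c(1, 0, 0), 4L, 3L, byrow = TRUE,
                dimnames = list(NULL, c("H", "E", "C")))
  aln <- aa_aln(c("MKB-", "MKD-", "MKNW", "M-NW"), letters[1:4])
  ss <- list(ssH[1:3, ], ssH[1:3, ], ssH, ssH[1:3, ])
  p <- make_profile(aln, ss, weights = rep(1, 4L))
  expect_s3_class(p, "aln_profile")
  expect_equal(colSums(p$freq), c(1, 1, 1, 1), tolerance = 1e-12)
  expect_equal(p$occupancy, c(1, 0.75, 1, 0.5), tolerance = 1e-12)
  expect_equal(p$gap_fraction, 1 - p$occupancy, tolerance = 1e-12)
  # column 3: one B spread over D/N by background, one D, two N
  bgD <- 0.0546 / (0.0546 + 0.0406)
  expect_equal(unname(p$freq["D", 3L]), (bgD + 1) / 4, tolerance = 1e-3)
  expect_equal(unname(p$freq["N", 3L]), (1 - bgD + 2) / 4, tolerance = 1e-3)
  # structure probabilities average to pure helix here
  expect_equal(unname(p$hec[, 1L]), c(1, 0, 0))
  expect_identical(substr(p$consensus, 1L, 2L), "MK")
})

test_that("column_score matches the explicit double loop", {
  set.seed(62)
  S <- matrix(rnorm(400), 20L, 20L); S <- (S + t(S)) / 2
  M <- structure_matrix(rnorm(6))
  fa <- runif(20L); fa <- fa / sum(fa)
  fb <- runif(20L); fb <- fb / sum(fb)
  ha <- runif(3L); ha <- ha / sum(ha)
  hb <- runif(3L); hb <- hb / sum(hb)
  a <- list(freq = fa, hec = ha, occ = 0.8)
  b <- list(freq = fb, hec = hb, occ = 0.5)
  ref <- 0
  for (r in 1:20) for (s in 1:20) ref <- ref + fa[r] * fb[s] * S[r, s]
  for (i in 1:3) for (j in 1:3) ref <- ref + 2 * ha[i] * hb[j] * M[i, j]
  expect_equal(column_score(a, b, S, M, ss_weight = 2), ref * 0.8 * 0.5,
               tolerance = 1e-12)
})

random_profile <- function(seq, model = NULL) {
  ss <- matrix(runif(3 * nchar(seq)), ncol = 3L)
  ss <- ss / rowSums(ss)
  colnames(ss) <- c("H", "E", "C")
  make_profile(aa_aln(seq, "x"), list(ss), weights = 1)
}

test_that("align_profiles equals exhaustive enumeration on tiny inputs", {
  set.seed(63)
  S <- default_substitution_matrix()
  M <- structure_matrix(c(1, -2, -1, 2, -1, 0.5))
  alpha <- c("A", "G", "L", "S")
  models <- list(neutral = neutral_gap_model())
  biased <- neutral_gap_model()
  biased$open_scores[] <- rnorm(160L, 0, 2)
  biased$opposing_ext[] <- rnorm(20L, 0, 1)
  biased$run_open_bonus <- 1.2; biased$run_after_penalty <- -1.8
  models$biased <- biased
  for (gc in models) for (k in 1:50) {
    a <- paste(sample(alpha, sample(1:6, 1L), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:6, 1L), replace = TRUE), collapse = "")
    pa <- random_profile(a); pb <- random_profile(b)
    gp <- gap_params(open = runif(1, 3, 10), extend = runif(1, 0.5, 2),
                     terminal_factor = runif(1))
    fit <- align_profiles(pa, pb, S, M, gp, gc)
    sm <- ctxalign:::profile_score_matrix(pa, pb, S, M, 1)
    ca <- ctxalign:::profile_gap_context(pa, gc)
    cb <- ctxalign:::profile_gap_context(pb, gc)
    en <- ctxalign:::enum_align_cpp(sm, ca$flank, cb$flank, ca$run, cb$run,
                                    ca$ext, cb$ext, gp$open, gp$extend,
                                    gp$terminal_factor, gc$clamp_fraction)
    expect_equal(fit$score, en$score, tolerance = 1e-9)
  }
})

test_that("the DP move trace reproduces its own reported score", {
  set.seed(64)
  S <- default_substitution_matrix()
  M <- structure_matrix(c(1, -2, -1, 2, -1, 0.5))
  gc <- neutral_gap_model()
  gc$open_scores[] <- rnorm(160L, 0, 2)
  for (k in 1:25) {
    pa <- random_profile(random_protein(sample(3:15, 1L)))
    pb <- random_profile(random_protein(sample(3:15, 1L)))
    gp <- gap_params(open = 8, extend = 1, terminal_factor = 0.5)
    fit <- align_profiles(pa, pb, S, M, gp, gc)
    sm <- ctxalign:::profile_score_matrix(pa, pb, S, M, 1)
    ca <- ctxalign:::profile_gap_context(pa, gc)
    cb <- ctxalign:::profile_gap_context(pb, gc)
    ps <- ctxalign:::score_path_cpp(fit$moves, sm, ca$flank, cb$flank,
                                    ca$run, cb$run, ca$ext, cb$ext, gp$open,
                                    gp$extend, gp$terminal_factor,
                                    gc$clamp_fraction)
    expect_equal(fit$score, ps, tolerance = 1e-9)
    expect_identical(sum(fit$moves != 3L), nrow(sm))
    expect_identical(sum(fit$moves != 2L), ncol(sm))
  }
})

test_that("merge_alignments preserves rows and inserts gaps per the trace", {
  a <- aa_aln(c("MKV", "M-V"), c("a", "b"))
  b <- aa_aln("KWV", "c")
  merged <- merge_alignments(a, b, c(2L, 1L, 1L, 3L))
  expect_identical(merged$row, c("MKV-", "M-V-", "-KWV"))
  expect_identical(merged$id, c("a", "b", "c"))
  expect_error(merge_alignments(a, b, c(1L, 1L)), "width")
})

test_that("terminal gaps are charged the cheaper terminal cost", {
  # identical cores with one extra head residue: with a low terminal factor
  # the optimum places the overhang as a terminal gap rather than mismatching
  S <- default_substitution_matrix()
  M <- structure_matrix(rep(0, 6L))
  gc <- neutral_gap_model()
  pa <- random_profile("WKKKKKK")
  pb <- random_profile("KKKKKK")
  fit <- align_profiles(pa, pb, S, M, gap_params(10, 1, 0.1), gc,
                        ss_weight = 0)
  expect_identical(fit$moves, c(2L, rep(1L, 6L)))
})
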