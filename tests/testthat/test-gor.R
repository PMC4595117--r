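test_that("DSSP 8-state labels reduce to H/E/C correctly", {
  expect_identical(reduce_dssp8_to3("HGIEBTSC"), "HHHECCCC")
  expect_identical(reduce_dssp8_to3(c("HH", "E C")), c("HH", "ECC"))
  expect_error(reduce_dssp8_to3("HQX"), "invalid DSSP label 'Q'")
})

make_tiny_corpus <- function(n_seq = 40L, len = 30L) {
  seqs <- character(n_seq); labs <- character(n_seq)
  for (k in seq_len(n_seq)) {
    st <- sample(c("H", "E", "C"), len, replace = TRUE,
                 prob = c(0.3, 0.2, 0.5))
    # helix enriched in A/E/L, sheet in V/I, coil background-ish
    res <- vapply(st, function(s) switch(s,
      H = sample(c("A", "E", "L", "K", "G"), 1L,
                 prob = c(0.3, 0.25, 0.25, 0.1, 0.1)),
      E = sample(c("V", "I", "F", "T", "G"), 1L,
                 prob = c(0.3, 0.3, 0.2, 0.1, 0.1)),
      C = sample(c("G", "P", "S", "N", "A"), 1L,
                 prob = c(0.25, 0.25, 0.2, 0.15, 0.15))), character(1L))
    seqs[k] <- paste(res, collapse = "")
    labs[k] <- paste(st, collapse = "")
  }
  list(seqs = seqs, labs = labs)
}

test_that("single-residue information scores match a direct counting oracle", {
  set.seed(31)
  cc <- make_tiny_corpus()
  pc <- 1
  model <- train_gor(cc$seqs, cc$labs, pseudocount = pc, half_window = 2L)

  # oracle: explicit scalar counting for every (state, offset, residue)
  HECo <- c("H", "E", "C")
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  offs <- -2:2
  cnt <- array(0, c(3, length(offs), 20))
  for (k in seq_along(cc$seqs)) {
    ch <- strsplit(cc$seqs[k], "")[[1L]]
    st <- strsplit(cc$labs[k], "")[[1L]]
    for (j in seq_along(ch)) for (mi in seq_along(offs)) {
      p <- j + offs[mi]
      if (p < 1 || p > length(ch)) next
      cnt[match(st[j], HECo), mi, match(ch[p], aas)] <-
        cnt[match(st[j], HECo), mi, match(ch[p], aas)] + 1
    }
  }
  cnt <- cnt + pc
  for (s in 1:3) for (mi in seq_along(offs)) for (r in 1:20) {
    f_cond <- cnt[s, mi, r] / sum(cnt[s, mi, ])
    f_marg <- sum(cnt[, mi, r]) / sum(cnt[, mi, ])
    expect_equal(model$singles[s, mi, r], log(f_cond / f_marg),
                 tolerance = 1e-12)
  }
})

test_that("pair information scores match a direct counting oracle", {
  set.seed(32)
  cc <- make_tiny_corpus(n_seq = 25L)
  pc <- 1
  model <- train_gor(cc$seqs, cc$labs, pseudocount = pc, half_window = 1L)
  # half_window 1: offsets -1,0,1; pairs (-1,0), (-1,1), (0,1)
  expect_identical(nrow(model$pair_index), 3L)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  HECo <- c("H", "E", "C")
  # oracle for pair (-1, +1): raw pair counts plus raw single counts at the
  # two offsets (the documented smoothing distributes the pair pseudocount
  # mass by the independence product of the smoothed single frequencies)
  cnt <- array(0, c(3, 400))
  s1 <- array(0, c(3, 2, 20))    # single counts at offsets -1 and +1
  for (k in seq_along(cc$seqs)) {
    ch <- strsplit(cc$seqs[k], "")[[1L]]
    st <- strsplit(cc$labs[k], "")[[1L]]
    for (j in seq_along(ch)) {
      si <- match(st[j], HECo)
      if (j > 1L) s1[si, 1L, match(ch[j - 1L], aas)] <-
          s1[si, 1L, match(ch[j - 1L], aas)] + 1
      if (j < length(ch)) s1[si, 2L, match(ch[j + 1L], aas)] <-
          s1[si, 2L, match(ch[j + 1L], aas)] + 1
      if (j > 1L && j < length(ch)) {
        ri <- (match(ch[j - 1L], aas) - 1L) * 20L + match(ch[j + 1L], aas)
        cnt[si, ri] <- cnt[si, ri] + 1
      }
    }
  }
  # smoothed single frequencies, conditional and marginal, per offset
  f_cond1 <- array(0, c(3, 2, 20)); f_marg1 <- matrix(0, 2, 20)
  for (o in 1:2) {
    for (s in 1:3)
      f_cond1[s, o, ] <- (s1[s, o, ] + pc) / (sum(s1[s, o, ]) + 20 * pc)
    f_marg1[o, ] <- (colSums(s1[, o, ]) + 3 * pc) / (sum(s1[, o, ]) + 60 * pc)
  }
  A <- 400 * pc
  pi2 <- which(model$pair_index[, "m1"] == -1L & model$pair_index[, "m2"] == 1L)
  for (ri in c(1L, 25L, 113L, 400L)) for (s in 1:3) {
    r1 <- (ri - 1L) %/% 20L + 1L
    r2 <- (ri - 1L) %% 20L + 1L
    prior_c <- f_cond1[s, 1L, r1] * f_cond1[s, 2L, r2]
    prior_m <- f_marg1[1L, r1] * f_marg1[2L, r2]
    f_cond <- (cnt[s, ri] + A * prior_c) / (sum(cnt[s, ]) + A)
    f_marg <- (sum(cnt[, ri]) + 3 * A * prior_m) / (sum(cnt) + 3 * A)
    expect_equal(model$pairs[s, pi2, ri], log(f_cond / f_marg),
                 tolerance = 1e-12)
  }
  # unobserved pair cells score near the sum of the two single scores (the
  # smoothing prior factorizes; a residual state-balance normalization term
  # keeps this from being exact)
  zero_cells <- which(colSums(cnt) == 0)
  if (length(zero_cells)) {
    ri <- zero_cells[1L]
    r1 <- (ri - 1L) %/% 20L + 1L
    r2 <- (ri - 1L) %% 20L + 1L
    for (s in 1:3)
      expect_equal(model$pairs[s, pi2, ri],
                   model$singles[s, 1L, r1] + model$singles[s, 3L, r2],
                   tolerance = 0.5)
  }
})

test_that("prediction combines windows as (2/n)*pairs - ((n-2)/n)*singles", {
  set.seed(33)
  cc <- make_tiny_corpus()
  model <- train_gor(cc$seqs, cc$labs, pseudocount = 1, half_window = 2L)
  seq1 <- substr(cc$seqs[1L], 1L, 7L)
  pr <- predict_hec(seq1, model)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- strsplit(seq1, "")[[1L]]
  offs <- -2:2
  for (j in c(1L, 2L, 4L, 7L)) {    # includes truncated-window edges
    inr <- which(j + offs >= 1L & j + offs <= length(ch))
    n <- length(inr)
    comb <- numeric(3L)
    for (s in 1:3) {
      ssum <- 0
      for (mi in inr)
        ssum <- ssum + model$singles[s, mi, match(ch[j + offs[mi]], aas)]
      psum <- 0
      for (pi in seq_len(nrow(model$pair_index))) {
        m1 <- model$pair_index[pi, 1L]; m2 <- model$pair_index[pi, 2L]
        if (j + m1 < 1L || j + m2 > length(ch)) next
        ri <- (match(ch[j + m1], aas) - 1L) * 20L + match(ch[j + m2], aas)
        psum <- psum + model$pairs[s, pi, ri]
      }
      comb[s] <- (2 / n) * psum - ((n - 2) / n) * ssum
    }
    expect_equal(unname(pr[j, ]), exp(comb - max(comb)) /
                   sum(exp(comb - max(comb))), tolerance = 1e-12)
  }
})

test_that("probabilities are valid and single-position sequences work", {
  set.seed(34)
  cc <- make_tiny_corpus()
  model <- train_gor(cc$seqs, cc$labs)
  pr <- predict_hec(cc$seqs[2L], model)
  expect_true(all(pr >= 0), all(pr <= 1))
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-12)
  pr1 <- predict_hec("A", model)   # n = 1: window fully truncated
  expect_equal(dim(pr1), c(1L, 3L))
  expect_equal(sum(pr1), 1, tolerance = 1e-12)
  expect_error(predict_hec("", model), "empty")
})

test_that("the GOR model recovers planted state-residue associations", {
  set.seed(35)
  cfg <- ss_generator_config(seed = 91, segment_length = 5)
  corp <- make_labeled_ss_corpus(cfg, 30000L)
  model <- train_gor(corp$seqs, corp$states)
  # dims are [state H/E/C, offset index (8 = offset 0), residue in AA20 order]
  # E is strongly enriched in helix over sheet (propensity 1.51 vs 0.37)
  expect_gt(model$singles[1L, 8L, 7L], 0)    # state H, offset 0, residue E
  expect_lt(model$singles[2L, 8L, 7L], 0)
  # V is enriched in sheet (propensity 1.70)
  expect_gt(model$singles[2L, 8L, 20L], 0)
  # prediction accuracy on held-out data clearly beats the majority class
  test_corp <- make_labeled_ss_corpus(ss_generator_config(seed = 92), 5000L)
  acc <- mean(unlist(Map(function(s, l) {
    strsplit(predict_hec_states(s, model), "")[[1L]] == strsplit(l, "")[[1L]]
  }, test_corp$seqs, test_corp$states)))
  expect_gt(acc, 0.55)
})

test_that("GOR model text round-trip is exact to write precision", {
  set.seed(36)
  cc <- make_tiny_corpus(n_seq = 10L)
  model <- train_gor(cc$seqs, cc$labs, half_window = 2L)
  tmp <- tempfile(fileext = ".tsv")
  write_gor_model(model, tmp)
  back <- read_gor_model(tmp)
  expect_equal(back$singles, model$singles, tolerance = 1e-6)
  expect_equal(back$pairs, model$pairs, tolerance = 1e-6)
  expect_identical(back$half_window, model$half_window)
  expect_equal(back$background$states, model$background$states,
               tolerance = 1e-6)
  # and predictions agree
  s <- cc$seqs[1L]
  expect_equal(predict_hec(s, back), predict_hec(s, model), tolerance = 1e-5)
})

test_that("training validates its inputs", {
  expect_error(train_gor(character(), character()), "empty corpus")
  expect_error(train_gor("AC", "HEC"), "length mismatch")
  expect_error(train_gor(c("ACDE"), c("HHHH")), "every state")
})
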