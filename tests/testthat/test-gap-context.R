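test_that("to_third_bits converts ratios and rejects non-positive input", {
  expect_identical(to_third_bits(0.1, 0.1), 0)
  expect_equal(to_third_bits(0.2, 0.1), 3)
  expect_equal(to_third_bits(0.1, 0.2), -3)
  expect_equal(to_third_bits(c(2, 4, 1), c(1, 1, 2)), c(3, 6, -3))
  expect_error(to_third_bits(0, 0.1), "strictly positive")
  expect_error(to_third_bits(0.1, -1), "strictly positive")
})

test_that("homopolymer runs are detected with minimum length", {
  r <- detect_runs("AAALVVVVPG")
  expect_identical(r$start, c(1L, 5L))
  expect_identical(r$length, c(3L, 4L))
  expect_identical(r$residue, c("A", "V"))
  expect_identical(nrow(detect_runs("ALVG")), 0L)
  expect_identical(detect_runs("AALLL", min_len = 2L)$start, c(1L, 3L))
})

test_that("gap events are extracted with all estimation filters", {
  # internal gap in row 2; terminal gap in row 1 must be ignored
  sep <- paste(rep("A", 25L), collapse = "")
  pr <- aa_aln(c(paste0("--KW", sep, "RNDE", sep, "KL"),
                 paste0("MIKW", sep, "R--E", sep, "KL")), c("a", "b"))
  ev <- extract_gap_events(list(pr))
  expect_length(ev, 1L)
  expect_identical(ev[[1L]]$gapped_row, 2L)
  expect_identical(ev[[1L]]$gap_start, 31L)
  expect_identical(ev[[1L]]$gap_end, 32L)
  expect_identical(ev[[1L]]$weight, 1)

  # identity at or below 0.5 drops the whole pair
  sepR <- paste(rep("R", 25L), collapse = "")
  low <- aa_aln(c(paste0(sep, "ND", sep), paste0(sepR, "-D", sepR)),
                c("a", "b"))
  ev2 <- extract_gap_events(list(low))
  expect_length(ev2, 0L)
  expect_identical(unname(attr(ev2, "dropped")["identity"]), 1L)

  # two events closer than the separation floor drop the whole pair
  close <- aa_aln(c(paste0("KW", sep, "RNDEFGHI", sep, "KL"),
                    paste0("KW", sep, "R-DEFG-I", sep, "KL")), c("a", "b"))
  ev3 <- extract_gap_events(list(close))
  expect_length(ev3, 0L)
  expect_identical(unname(attr(ev3, "dropped")["separation"]), 1L)
  # but the same two events >= 20 columns apart are both kept
  far <- aa_aln(c(paste0("KW", sep, "RNDE", sep, "FGHI", sep, "KL"),
                  paste0("KW", sep, "R-DE", sep, "FG-I", sep, "KL")),
                c("a", "b"))
  expect_length(extract_gap_events(list(far)), 2L)
})

test_that("equivalent gap placements split weight and conserve it", {
  sep <- paste(rep("R", 25L), collapse = "")
  # opposing AA opposite a 1-column gap: AA/A- and AA/-A are equivalent
  pr <- aa_aln(c(paste0(sep, "KAAK", sep), paste0(sep, "KA-K", sep)),
               c("a", "b"))
  ev <- extract_gap_events(list(pr))
  expect_length(ev, 1L)
  ex <- expand_equivalent_placements(ev[[1L]])
  expect_length(ex, 2L)
  expect_equal(sum(vapply(ex, `[[`, 1, "weight")), 1)
  starts <- sort(vapply(ex, `[[`, 1L, "gap_start"))
  expect_identical(starts, c(27L, 28L))
  # a gap between distinct residues cannot slide
  pr2 <- aa_aln(c(paste0(sep, "KANK", sep), paste0(sep, "KA-K", sep)),
                c("a", "b"))
  ev2 <- extract_gap_events(list(pr2))
  ex2 <- expand_equivalent_placements(ev2[[1L]])
  expect_length(ex2, 1L)
  expect_identical(ex2[[1L]]$gap_start, ev2[[1L]]$gap_start)
})

test_that("estimated opening scores match a direct counting oracle", {
  set.seed(51)
  gp <- make_gap_pairs(context_bias = c(P = 2), n_pairs = 300L, seed = 52L)
  events <- extract_gap_events(gp$pairs)
  model <- estimate_gap_model(events, pseudocount = 1)

  # oracle: recount offset -1 and +2 frequencies by hand
  bg <- model$background
  cnt1 <- cnt2 <- setNames(numeric(20L), names(bg))
  for (ev in events) {
    g <- strsplit(ev$rows[[ev$gapped_row]], "")[[1L]]
    u <- g[g != "-"]
    bp <- sum(g[seq_len(ev$gap_start - 1L)] != "-")
    if (bp >= 1L) cnt1[u[bp]] <- cnt1[u[bp]] + ev$weight
    if (bp + 2L <= length(u)) cnt2[u[bp + 2L]] <- cnt2[u[bp + 2L]] + ev$weight
  }
  f1 <- (cnt1 + 1 / 20) / (sum(cnt1) + 1)
  f2 <- (cnt2 + 1 / 20) / (sum(cnt2) + 1)
  expect_equal(unname(model$open_scores["-1", ]),
               unname(to_third_bits(f1, bg)), tolerance = 1e-12)
  expect_equal(unname(model$open_scores["2", ]),
               unname(to_third_bits(f2, bg)), tolerance = 1e-12)
})

test_that("extension scores count residues opposite gap columns", {
  sep <- paste(rep("R", 25L), collapse = "")
  pr <- aa_aln(c(paste0(sep, "KWND", sep), paste0(sep, "K--D", sep)),
               c("a", "b"))
  model <- estimate_gap_model(extract_gap_events(list(pr)), pseudocount = 1)
  # W and N each observed once opposite the gap out of 2 total
  fW <- (1 + 1 / 20) / (2 + 1)
  expect_equal(unname(model$opposing_ext["W"]),
               unname(to_third_bits(fW, model$background["W"])),
               tolerance = 1e-12)
  expect_equal(unname(model$opposing_ext["N"]),
               unname(to_third_bits(fW, model$background["N"])),
               tolerance = 1e-12)
  # A was never observed opposite a gap: only pseudocount mass
  fA <- (1 / 20) / (2 + 1)
  expect_equal(unname(model$opposing_ext["A"]),
               unname(to_third_bits(fA, model$background["A"])),
               tolerance = 1e-12)
})

test_that("run terms: bonus inside runs, penalty right after a run start", {
  model <- neutral_gap_model()
  model$run_open_bonus <- 1.5
  model$run_after_penalty <- -2.5
  v <- run_score_vector("KAAAAK", model)
  #       positions:     123456
  # run of A at 2..5; after-start position is 3
  expect_equal(v, c(0, 1.5, -2.5, 1.5, 1.5, 0))
  # a 2-run gets only the after-start penalty, no bonus
  v2 <- run_score_vector("KAAK", model)
  expect_equal(v2, c(0, 0, -2.5, 0))
})

test_that("gap modifiers are clamped to the contracted fraction", {
  set.seed(53)
  model <- neutral_gap_model()
  model$open_scores[] <- rnorm(160L, 0, 5)
  model$opposing_ext[] <- rnorm(20L, 0, 5)
  model$run_open_bonus <- 4; model$run_after_penalty <- -6
  s <- random_protein(40L)
  for (b in 0:40) {
    m <- gap_open_modifier(s, b, model, opposing = random_protein(40L),
                           base_cost = 15)
    expect_lte(abs(m), 0.2 * 15 + 1e-12)
  }
  for (r in c("A", "W", "P"))
    expect_lte(abs(gap_extension_modifier(r, model, base_cost = 1)),
               0.2 * 1 + 1e-12)
  # without base_cost the raw (unclamped) value is returned
  raw <- gap_open_modifier(s, 20L, model)
  expect_gt(abs(raw), 0)
})

test_that("gap_open_modifier sums the in-range offset scores", {
  model <- neutral_gap_model()
  model$open_scores["-1", "A"] <- 2
  model$open_scores["1", "W"] <- -1
  model$open_scores["4", "K"] <- 0.5
  expect_equal(gap_open_modifier("CAWNNK", 2L, model), 2 - 1 + 0.5)
  # boundary 0: no left residues in range
  expect_equal(gap_open_modifier("WAAAAA", 0L, model), -1)
  expect_error(gap_open_modifier("WA", 3L, model), "out of range")
})

test_that("gap model text round-trip preserves every score", {
  set.seed(54)
  gp <- make_gap_pairs(n_pairs = 100L, seed = 55L)
  model <- estimate_gap_model(extract_gap_events(gp$pairs))
  tmp <- tempfile(fileext = ".tsv")
  write_gap_model(model, tmp)
  back <- read_gap_model(tmp)
  expect_equal(back$open_scores, model$open_scores, tolerance = 1e-6)
  expect_equal(back$opposing_ext, model$opposing_ext, tolerance = 1e-6)
  expect_equal(back$run_open_bonus, model$run_open_bonus, tolerance = 1e-6)
  expect_equal(back$run_after_penalty, model$run_after_penalty,
               tolerance = 1e-6)
  expect_equal(back$clamp_fraction, model$clamp_fraction)
})
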