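## Synthetic data generators with known ground truth: labeled
## secondary-structure corpora, gap-biased pairwise alignments, and whole
## protein families evolved along a tree with an exactly tracked true
## alignment and indel event log.

## ---- secondary-structure corpora ------------------------------------------

# helix/sheet propensity multipliers (Chou-Fasman style); coil propensity is
# the inverse of the helix/sheet mean so helix breakers (G, P) favor coil.
# The exponent sharpens the contrast; the default 1.75 is calibrated so that
# a GOR model trained on the resulting corpora reaches held-out Q3 ~ 0.65,
# the accuracy reported for GOR IV on real proteins -- raw Chou-Fasman ratios
# alone carry much less information than real structural context does.
hec_propensities <- function(power = 1.75) {
  pa <- c(A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70, Q = 1.11,
          E = 1.51, G = 0.57, H = 1.00, I = 1.08, L = 1.21, K = 1.14,
          M = 1.45, F = 1.13, P = 0.57, S = 0.77, T = 0.83, W = 1.08,
          Y = 0.69, V = 1.06)
  pb <- c(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10,
          E = 0.37, G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74,
          M = 1.05, F = 1.38, P = 0.55, S = 0.75, T = 1.19, W = 1.37,
          Y = 1.47, V = 1.70)
  cbind(H = pa[AA20], E = pb[AA20], C = 2 / (pa[AA20] + pb[AA20])) ^ power
}

# residue emission distributions per 3-state: P(r | state) ~ bg * propensity
hec_emission_matrix <- function(propensity = hec_propensities(),
                                background = AA_BACKGROUND) {
  em <- propensity * background[AA20]
  sweep(em, 2L, colSums(em), "/")
}

# 8-state label emission per hidden 3-state; every 8-state label reduces back
# to its own hidden state, so the reduced labels equal the hidden path
dssp8_emission <- function() {
  list(H = c(H = 0.75, G = 0.15, I = 0.10),
       E = c(E = 1.0),
       C = c(C = 0.50, T = 0.30, S = 0.15, B = 0.05))
}

#' Configuration for labeled secondary-structure corpora
#'
#' @param seed integer seed.
#' @param segment_length mean length of constant-state segments; the state
#'   sequence is a first-order chain with geometric segment lengths.
#' @param markov if `FALSE`, states are drawn independently per position
#'   (no positional correlation between neighboring labels).
#' @param state_freq stationary H/E/C frequencies.
#' @param residue_signal if `FALSE`, residues are drawn from the background
#'   regardless of state, so sequence carries no structure information.
#' @param seq_length residues per generated sequence.
#' @param propensity 20 x 3 helix/sheet/coil propensity multipliers.
#' @param background residue background frequencies.
#' @return a list of class `ss_generator_config`.
#' @export
ss_generator_config <- function(seed = 1L, segment_length = 6,
                                markov = TRUE,
                                state_freq = c(H = 0.35, E = 0.22, C = 0.43),
                                residue_signal = TRUE,
                                seq_length = 200L,
                                propensity = hec_propensities(),
                                background = AA_BACKGROUND) {
  stopifnot(segment_length >= 1, all(state_freq > 0), seq_length >= 30L)
  structure(list(seed = as.integer(seed), segment_length = segment_length,
                 markov = markov, state_freq = state_freq / sum(state_freq),
                 residue_signal = residue_signal,
                 seq_length = as.integer(seq_length),
                 propensity = propensity, background = background),
            class = "ss_generator_config")
}

# hidden 3-state path of length n (integer codes into HEC)
gen_hidden_states <- function(n, cfg) {
  if (!cfg$markov || cfg$segment_length <= 1)
    return(sample.int(3L, n, replace = TRUE, prob = cfg$state_freq))
  lens <- integer(0); states <- integer(0)
  while (sum(lens) < n) {
    k <- max(16L, ceiling((n - sum(lens)) / cfg$segment_length) * 2L)
    lens <- c(lens, 1L + stats::rgeom(k, 1 / cfg$segment_length))
    states <- c(states, sample.int(3L, k, replace = TRUE,
                                   prob = cfg$state_freq))
  }
  # discourage immediate self-transitions (merge would lengthen segments)
  for (k in seq_along(states)[-1L]) {
    if (states[k] == states[k - 1L]) {
      states[k] <- sample(setdiff(1:3, states[k]), 1L,
                          prob = cfg$state_freq[setdiff(1:3, states[k])])
    }
  }
  rep(states, lens)[seq_len(n)]
}

# sample one item per position from a per-state distribution
sample_by_state <- function(states, dists) {
  out <- character(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    d <- dists[[s]]
    out[idx] <- sample(names(d), length(idx), replace = TRUE, prob = d)
  }
  out
}

#' Generate a labeled secondary-structure corpus
#'
#' Hidden H/E/C states (Markov segments or independent draws), residues
#' emitted per state from propensity-weighted background frequencies, and
#' 8-state DSSP labels emitted per hidden state such that reducing the labels
#' with [reduce_dssp8_to3()] recovers the hidden path exactly.
#'
#' @param config an [ss_generator_config()].
#' @param n_residues total number of labeled residues to generate.
#' @return list with parallel character vectors `seqs` (residue strings),
#'   `labels` (8-state DSSP strings) and `states` (hidden 3-state strings).
#' @export
make_labeled_ss_corpus <- function(config, n_residues) {
  stopifnot(inherits(config, "ss_generator_config"), n_residues >= 30L)
  set.seed(config$seed)
  n <- as.integer(n_residues)
  st <- gen_hidden_states(n, config)

  em <- hec_emission_matrix(config$propensity, config$background)
  res_dists <- if (config$residue_signal)
    lapply(1:3, function(s) setNames(em[, s], AA20))
  else rep(list(setNames(config$background[AA20] /
                           sum(config$background[AA20]), AA20)), 3L)
  res <- sample_by_state(st, res_dists)
  lab <- sample_by_state(st, dssp8_emission())

  # chunk into sequences; fold a short tail into the last chunk
  starts <- seq.int(1L, n, by = config$seq_length)
  if (length(starts) > 1L && n - starts[length(starts)] + 1L < 30L)
    starts <- starts[-length(starts)]
  ends <- c(starts[-1L] - 1L, n)
  cut1 <- function(x) vapply(seq_along(starts), function(k)
    paste(x[starts[k]:ends[k]], collapse = ""), character(1L))
  list(seqs = cut1(res), labels = cut1(lab), states = cut1(HEC[st]))
}

## ---- gap-biased pairwise alignments ---------------------------------------

#' Default residue context bias for gap placement
#'
#' Frequency multipliers for the residue immediately left of a gap (offset
#' -1): flexible/polar residues favor gaps, hydrophobic core residues
#' disfavor them.
#'
#' @return named numeric vector of multipliers (residues not listed have
#'   multiplier 1).
#' @export
default_gap_bias <- function() {
  c(P = 2.5, G = 2.0, S = 1.5, N = 1.5, D = 1.4,
    I = 0.5, L = 0.5, V = 0.5, F = 0.6, W = 0.6, M = 0.6)
}

# boundary sampling weights giving P(left residue = r) = comp_r * mult_r
# exactly: biased residues get weight mult_r, unbiased get the absorbing
# weight Z so the weights average to 1 under the composition
bias_weights <- function(res, bias) {
  w <- rep(1, length(res))
  if (is.null(bias) || !length(bias)) return(w)
  comp <- tabulate(match(res, AA20), 20L) / length(res)
  names(comp) <- AA20
  b <- intersect(names(bias), AA20[comp > 0])
  mass <- sum(comp[b] * bias[b])
  rest <- 1 - sum(comp[b])
  if (mass >= 1 && rest > 0)
    stop("context bias too strong for this composition")
  Z <- if (rest > 0) (1 - mass) / rest else 1
  if (Z <= 0) stop("context bias too strong for this composition")
  m <- match(res, b)
  w[!is.na(m)] <- bias[b][m[!is.na(m)]]
  w[is.na(m)] <- Z
  w
}

#' Generate pairwise alignments with context-biased gap placement
#'
#' Each pair is a high-identity duplicate (point substitutions only) of a
#' random background sequence, with one internal deletion in the second row.
#' The gap boundary is sampled so that the frequency of residue `r`
#' immediately left of the gap equals its local composition times
#' `context_bias[r]` (residues not named have multiplier 1, rescaled to keep
#' total probability 1). Offsets other than -1 stay at background. The
#' realized placements are returned in `$log` for independent tallying.
#'
#' @param context_bias named frequency multipliers (see [default_gap_bias()]).
#' @param n_pairs number of alignment pairs.
#' @param seed integer seed.
#' @param len sequence length per pair.
#' @param gap_lengths candidate gap lengths (sampled uniformly).
#' @param sub_rate per-site substitution probability for the second row.
#' @param background residue background frequencies.
#' @return list with `pairs` (list of 2-row [aa_aln]), `log` (data.frame with
#'   one row per pair: `boundary` position, `left_res`, `gap_len`) and the
#'   `context_bias` used.
#' @export
make_gap_pairs <- function(context_bias = default_gap_bias(),
                           n_pairs = 1000L, seed = 1L, len = 150L,
                           gap_lengths = 1:4, sub_rate = 0.12,
                           background = AA_BACKGROUND) {
  stopifnot(len >= 60L, all(gap_lengths >= 1L))
  set.seed(seed)
  bg <- background[AA20] / sum(background[AA20])
  margin <- 22L                       # keep gaps internal and flanks intact
  pairs <- vector("list", n_pairs)
  log <- data.frame(boundary = integer(n_pairs),
                    left_res = character(n_pairs),
                    gap_len = integer(n_pairs), stringsAsFactors = FALSE)
  for (k in seq_len(n_pairs)) {
    a <- sample(AA20, len, replace = TRUE, prob = bg)
    b <- a
    mut <- stats::runif(len) < sub_rate
    if (any(mut)) b[mut] <- sample(AA20, sum(mut), replace = TRUE, prob = bg)
    glen <- if (length(gap_lengths) > 1L) sample(gap_lengths, 1L)
            else gap_lengths
    cand <- margin:(len - margin - glen)      # gap occupies cand+1 .. cand+glen
    w <- bias_weights(b[cand], context_bias)
    p <- cand[sample.int(length(cand), 1L, prob = w)]
    brow <- b
    brow[(p + 1L):(p + glen)] <- "-"
    pairs[[k]] <- aa_aln(c(paste(a, collapse = ""),
                           paste(brow, collapse = "")),
                         c(paste0("p", k, "_a"), paste0("p", k, "_b")))
    log$boundary[k] <- p
    log$left_res[k] <- b[p]
    log$gap_len[k] <- glen
  }
  list(pairs = pairs, log = log, context_bias = context_bias)
}

## ---- family evolution with exact truth ------------------------------------

#' Configuration for simulated family evolution
#'
#' @param n_leaves number of leaf sequences.
#' @param depth root-to-deepest-tip branch-length sum; per-site substitution
#'   probability along a branch of length `b` is `1 - exp(-b * rate)`.
#' @param root_length root sequence length.
#' @param indel_rate expected indel events per site per unit branch length.
#' @param indel_length_p geometric length parameter; mean length `1/p`.
#' @param context_bias named frequency multipliers for the residue left of an
#'   indel boundary (NULL = uniform placement).
#' @param use_ss evolve hidden H/E/C structure alongside the sequence.
#' @param state_sub_rate substitution-rate multiplier per structural state
#'   (structured states conserved, coil variable); used when `use_ss`.
#' @param state_indel_bias indel-placement multiplier per structural state of
#'   the boundary; used when `use_ss`.
#' @param state_emission draw root and replacement residues from the
#'   state-conditional emission distribution instead of the background.
#' @param segment_length,state_freq hidden-state chain parameters.
#' @param tree optional `ape::phylo` with edge lengths (overrides `n_leaves`
#'   and `depth`).
#' @param seed integer seed.
#' @param background residue background frequencies.
#' @return a list of class `evolution_config`.
#' @export
evolution_config <- function(n_leaves = 8L, depth = 0.4, root_length = 150L,
                             indel_rate = 0.02, indel_length_p = 0.45,
                             context_bias = NULL,
                             use_ss = TRUE,
                             state_sub_rate = c(H = 0.45, E = 0.45, C = 1.7),
                             state_indel_bias = c(H = 0.25, E = 0.25, C = 1),
                             state_emission = TRUE,
                             segment_length = 7, state_freq =
                               c(H = 0.35, E = 0.22, C = 0.43),
                             tree = NULL, seed = 1L,
                             background = AA_BACKGROUND) {
  stopifnot(root_length >= 30L, depth >= 0, indel_rate >= 0,
            indel_length_p > 0, indel_length_p <= 1)
  structure(list(n_leaves = as.integer(n_leaves), depth = depth,
                 root_length = as.integer(root_length),
                 indel_rate = indel_rate, indel_length_p = indel_length_p,
                 context_bias = context_bias, use_ss = use_ss,
                 state_sub_rate = state_sub_rate,
                 state_indel_bias = state_indel_bias,
                 state_emission = state_emission,
                 segment_length = segment_length,
                 state_freq = state_freq / sum(state_freq),
                 tree = tree, seed = as.integer(seed),
                 background = background),
            class = "evolution_config")
}

#' Evolve a protein family with an exactly known alignment
#'
#' Simulates substitutions and indels along a (coalescent or supplied) tree.
#' Every residue carries a persistent column identity and a global column
#' order is maintained across insertions, so the returned `truth` alignment
#' is exact by construction, not inferred. Hidden structural states are
#' inherited through the tree; structured (H/E) positions substitute more
#' slowly and attract fewer indels than coil when `use_ss` is on. Indel
#' boundaries are biased by the residue to their left via `context_bias`
#' using exact frequency-multiplier semantics; realized events are logged.
#'
#' @param config an [evolution_config()].
#' @return list with `seqs` (ungapped leaf [aa_seqs]), `truth` (the true
#'   [aa_aln]), `states` (per-leaf hidden-state strings), `tree` (`ape`
#'   phylo), `events` (data.frame: node, type, length, left_res, left_state)
#'   and `boundary_composition` (average residue composition at candidate
#'   indel boundaries, the base rate for tallying the context bias).
#' @export
evolve_family <- function(config) {
  stopifnot(inherits(config, "evolution_config"))
  cfg <- config
  set.seed(cfg$seed)

  tree <- cfg$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(cfg$n_leaves)
    dmax <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * (cfg$depth / dmax)
  }
  ntip <- length(tree$tip.label)

  em <- hec_emission_matrix(background = cfg$background)
  bg <- cfg$background[AA20] / sum(cfg$background[AA20])
  draw_res <- function(states) {
    if (cfg$use_ss && cfg$state_emission)
      sample_by_state(states, lapply(1:3, function(s) setNames(em[, s], AA20)))
    else sample(AA20, length(states), replace = TRUE, prob = bg)
  }

  # root
  L0 <- cfg$root_length
  st0 <- if (cfg$use_ss)
    gen_hidden_states(L0, list(markov = TRUE,
                               segment_length = cfg$segment_length,
                               state_freq = cfg$state_freq))
  else rep(3L, L0)
  root <- list(res = draw_res(st0), st = st0, key = seq_len(L0))

  # global column order and id counter
  master <- new.env(parent = emptyenv())
  master$order <- seq_len(L0)
  master$next_id <- L0 + 1L

  ev <- list()
  comp_sum <- setNames(numeric(20L), AA20); comp_n <- 0L

  evolve_edge <- function(node_val, b, node_id) {
    res <- node_val$res; st <- node_val$st; key <- node_val$key
    L <- length(res)
    # substitutions (state-dependent rate)
    rate <- if (cfg$use_ss) cfg$state_sub_rate[st] else rep(1, L)
    hit <- which(stats::runif(L) < 1 - exp(-b * rate))
    if (length(hit)) res[hit] <- draw_res(st[hit])
    # indels
    n_ev <- stats::rpois(1L, cfg$indel_rate * b * L)
    for (e in seq_len(n_ev)) {
      L <- length(res)
      glen <- min(1L + stats::rgeom(1L, cfg$indel_length_p), max(L - 10L, 1L))
      is_del <- stats::runif(1L) < 0.5
      # candidate boundaries p (indel after residue p); keep ends intact
      pmax_ <- if (is_del) L - glen - 1L else L - 1L
      if (pmax_ < 2L) next
      cand <- 2L:pmax_
      w <- bias_weights(res[cand], cfg$context_bias)
      if (cfg$use_ss && !is.null(cfg$state_indel_bias))
        w <- w * cfg$state_indel_bias[st[cand]]
      p <- cand[sample.int(length(cand), 1L, prob = w)]
      comp_here <- tabulate(match(res[cand], AA20), 20L) / length(cand)
      comp_sum <<- comp_sum + comp_here; comp_n <<- comp_n + 1L
      ev[[length(ev) + 1L]] <<- data.frame(
        node = node_id, type = if (is_del) "del" else "ins",
        length = glen, left_res = res[p], left_state = HEC[st[p]],
        stringsAsFactors = FALSE)
      if (is_del) {
        drop <- (p + 1L):(p + glen)
        res <- res[-drop]; st <- st[-drop]; key <- key[-drop]
      } else {
        new_st <- rep(st[p], glen)
        new_res <- draw_res(new_st)
        new_key <- master$next_id + seq_len(glen) - 1L
        master$next_id <- master$next_id + glen
        pos <- match(key[p], master$order)
        master$order <- append(master$order, new_key, after = pos)
        res <- append(res, new_res, after = p)
        st <- append(st, new_st, after = p)
        key <- append(key, new_key, after = p)
      }
    }
    list(res = res, st = st, key = key)
  }

  # preorder traversal from the root
  edges <- tree$edge[rev(postorder_edges(tree)), , drop = FALSE]
  lens <- tree$edge.length[rev(postorder_edges(tree))]
  nodes <- vector("list", ntip + tree$Nnode)
  nodes[[ntip + 1L]] <- root
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1L]; child <- edges[k, 2L]
    nodes[[child]] <- evolve_edge(nodes[[par]], lens[k], child)
  }

  leaves <- nodes[seq_len(ntip)]
  live <- sort(unique(unlist(lapply(leaves, `[[`, "key"))))
  cols <- master$order[master$order %in% live]
  rows <- vapply(leaves, function(lv) {
    r <- rep("-", length(cols))
    r[match(lv$key, cols)] <- lv$res
    paste(r, collapse = "")
  }, character(1L))
  ids <- tree$tip.label
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(node = integer(), type = character(), length = integer(),
               left_res = character(), left_state = character(),
               stringsAsFactors = FALSE)
  list(seqs = aa_seqs(vapply(leaves, function(lv)
         paste(lv$res, collapse = ""), character(1L)), ids),
       truth = aa_aln(rows, ids),
       states = setNames(vapply(leaves, function(lv)
         paste(HEC[lv$st], collapse = ""), character(1L)), ids),
       tree = tree, events = events,
       boundary_composition = if (comp_n) comp_sum / comp_n else comp_sum)
}

# edge indices in postorder (children before parents)
postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  match(paste(tr$edge[, 1L], tr$edge[, 2L]),
        paste(tree$edge[, 1L], tree$edge[, 2L]))
}
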