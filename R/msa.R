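## End-to-end multiple alignment: k-mer distances, UPGMA guide tree,
## progressive profile merging with secondary-structure averaging.

#' k-mer distance matrix
#'
#' `d[i, j] = 1 - shared / min(total_i, total_j)` where `shared` is the
#' number of k-mers in common (counting multiplicity). Sequences shorter than
#' `k` contribute their single full-length substring.
#'
#' @param seqs an [aa_seqs] or character vector (>= 2 sequences).
#' @param k k-mer length (default 5).
#' @return symmetric distance matrix with zero diagonal.
#' @export
kmer_distance_matrix <- function(seqs, k = 5L) {
  if (inherits(seqs, "aa_seqs")) seqs <- seqs$seq
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  enc <- lapply(seqs, function(s) {
    s <- toupper(s)
    kk <- min(k, nchar(s))
    L <- nchar(s) - kk + 1L
    cod <- aa_codes(strsplit(s, "", fixed = TRUE)[[1L]])
    cod[is.na(cod)] <- 0L  # ambiguity: fold into one bucket
    key <- numeric(L)
    for (p in seq_len(kk)) key <- key * 21 + cod[p:(p + L - 1L)]
    r <- rle(sort(key))
    list(vals = r$values, cnts = r$lengths, total = L)
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    ei <- enc[[i]]
    for (j in (i + 1L):n) {
      ej <- enc[[j]]
      m <- match(ei$vals, ej$vals)
      ok <- !is.na(m)
      shared <- sum(pmin(ei$cnts[ok], ej$cnts[m[ok]]))
      d[i, j] <- d[j, i] <- 1 - shared / min(ei$total, ej$total)
    }
  }
  d
}

#' UPGMA guide tree
#'
#' Standard average-linkage agglomeration; among tied minimum distances the
#' lowest index pair is joined; node heights are half the joining distance.
#'
#' @param d symmetric nonnegative distance matrix with zero diagonal.
#' @param method only "UPGMA".
#' @return an object of class `guide_tree` with hclust-style `merge` rows
#'   (negative entries are leaves), `height` and `labels`.
#' @export
build_guide_tree <- function(d, method = "UPGMA") {
  method <- match.arg(method, "UPGMA")
  d <- as.matrix(d)
  if (any(is.na(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves")
  active <- seq_len(n)             # cluster ids: 1..n leaves, then n+1, ...
  sizes <- rep(1L, n)
  id <- -(seq_len(n))              # hclust coding of active clusters
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  D <- d
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    Du <- D; Du[lower.tri(Du, diag = TRUE)] <- Inf
    bestd <- min(Du)
    hits <- which(Du == bestd, arr.ind = TRUE)
    # lowest index pair on ties: smallest row index, then column
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- bestd / 2
    # UPGMA update: size-weighted average to the new cluster
    newrow <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) /
      (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    id <- c(id[keep], step)
    active <- c(active[keep], n + step)
  }
  structure(list(merge = merge, height = height,
                 labels = rownames(d) %||% paste0("seq", seq_len(n)),
                 n_leaves = n),
            class = "guide_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.guide_tree <- function(x, ...) {
  cat(sprintf("UPGMA guide tree: %d leaves, root height %.4f\n",
              x$n_leaves, max(x$height)))
  invisible(x)
}

#' Newick string for a guide tree
#'
#' @param tree a `guide_tree`.
#' @return single Newick string (with branch lengths).
#' @export
tree_newick <- function(tree) {
  lab <- gsub("[,():;\\s]", "_", tree$labels)
  node <- function(k) {                 # k: merge row; returns c(str, height)
    part <- function(e) {
      if (e < 0L) c(lab[-e], 0) else node(e)
    }
    a <- part(tree$merge[k, 1L]); b <- part(tree$merge[k, 2L])
    h <- tree$height[k]
    c(sprintf("(%s:%.8g,%s:%.8g)", a[1L], h - as.numeric(a[2L]),
              b[1L], h - as.numeric(b[2L])), h)
  }
  paste0(node(nrow(tree$merge))[1L], ";")
}

#' As an ape phylo object
#'
#' @param tree a `guide_tree`.
#' @return an `ape::phylo`.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = tree_newick(tree))
}

## ---- default context models ----------------------------------------------

#' Default (synthetic-trained) context models
#'
#' The package's default GOR and gap-context models are trained at first use
#' from seeded synthetic corpora generated by [make_labeled_ss_corpus()] and
#' [make_gap_pairs()] (see the vignette for what these emulate and their
#' limits); the substitution matrix is BLOSUM62 in third-bits and the
#' structure matrix is the shipped fitted matrix. Results are cached for the
#' session. Supply your own trained models for production alignment of real
#' proteins.
#'
#' @param seed seed for the synthetic training corpora.
#' @return list with elements `gor`, `gap`, `subst`, `struct`.
#' @export
default_models <- function(seed = 20151006L) {
  key <- paste0("models_", seed)
  if (!is.null(.ctx[[key]])) return(.ctx[[key]])
  corpus <- make_labeled_ss_corpus(ss_generator_config(seed = seed),
                                   n_residues = 60000L)
  gor <- train_gor(corpus$seqs, reduce_dssp8_to3(corpus$labels))
  pairs <- make_gap_pairs(context_bias = default_gap_bias(),
                          n_pairs = 8000L, seed = seed + 1L)
  events <- extract_gap_events(pairs$pairs)
  events <- unlist(lapply(events, expand_equivalent_placements),
                   recursive = FALSE)
  gap <- estimate_gap_model(events)
  models <- list(gor = gor, gap = gap,
                 subst = default_substitution_matrix(),
                 struct = default_structure_matrix())
  .ctx[[key]] <- models
  models
}

## ---- progressive alignment ------------------------------------------------

#' Multiple sequence alignment
#'
#' Predicts helix/sheet/coil probabilities once per input sequence (single
#' sequences only), builds a UPGMA guide tree from k-mer distances, and
#' progressively merges profiles along the tree; at every merge the member
#' structure probabilities are averaged into the profile, so group-level
#' structure predictions sharpen toward the root. With `iterations > 1`,
#' distances are recomputed from the current alignment, the tree rebuilt and
#' the sequences realigned.
#'
#' @param seqs an [aa_seqs] (>= 2 sequences).
#' @param models list with `gor`, `gap`, `subst`, `struct` (default
#'   [default_models()]).
#' @param gap_par [gap_params()].
#' @param ss_weight weight of the secondary-structure score term (0 turns
#'   the structure channel off).
#' @param iterations number of alignment passes (default 1).
#' @param k k-mer length for guide-tree distances.
#' @return an [aa_aln]; rows are in input order and ungapping any row
#'   reproduces its input sequence. The guide tree of the final pass is
#'   attached as attribute `guide_tree`.
#' @export
align <- function(seqs, models = default_models(), gap_par = gap_params(),
                  ss_weight = 1, iterations = 1L, k = 5L) {
  stopifnot(inherits(seqs, "aa_seqs"))
  n <- length(seqs$id)
  if (n < 2L) stop("need at least 2 sequences to align")
  ss <- lapply(seqs$seq, predict_hec, model = models$gor)

  d <- kmer_distance_matrix(seqs, k = k)
  tree <- build_guide_tree(d)
  res <- progressive_pass(seqs, ss, tree, models, gap_par, ss_weight)
  if (iterations > 1L) {
    for (it in 2:iterations) {
      d <- aligned_identity_distance(res)
      tree <- build_guide_tree(d)
      res <- progressive_pass(seqs, ss, tree, models, gap_par, ss_weight)
    }
  }
  attr(res, "guide_tree") <- tree
  res
}

progressive_pass <- function(seqs, ss, tree, models, gap_par, ss_weight) {
  n <- length(seqs$id)
  # node value: list(aln, ss list, rows = original sequence indices)
  leaf <- function(i) list(
    aln = aa_aln(seqs$seq[i], seqs$id[i]),
    ss = ss[i], rows = i)
  nodes <- vector("list", nrow(tree$merge))
  getn <- function(e) if (e < 0L) leaf(-e) else nodes[[e]]
  for (s in seq_len(nrow(tree$merge))) {
    a <- getn(tree$merge[s, 1L]); b <- getn(tree$merge[s, 2L])
    pa <- make_profile(a$aln, a$ss)
    pb <- make_profile(b$aln, b$ss)
    fit <- align_profiles(pa, pb, models$subst, models$struct, gap_par,
                          models$gap, ss_weight)
    nodes[[s]] <- list(aln = merge_alignments(a$aln, b$aln, fit$moves),
                       ss = c(a$ss, b$ss), rows = c(a$rows, b$rows))
  }
  root <- nodes[[nrow(tree$merge)]]
  ord <- order(root$rows)
  aa_aln(root$aln$row[ord], root$aln$id[ord])
}

# fraction mismatch over columns where both rows have residues
aligned_identity_distance <- function(aln) {
  mat <- aln_matrix(aln)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- mat[i, ] != "-" & mat[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(both))
      mean(mat[i, both] != mat[j, both]) else 1
  }
  d
}

#' Add supplemental sequences to a reference set
#'
#' Reference sequences plus a seeded uniform sample (without replacement)
#' from `pool` to reach `total` sequences; sampled keys are recorded so the
#' supplements can be removed again before scoring.
#'
#' @param reference,pool [aa_seqs] objects.
#' @param total target number of sequences (>= length of `reference`).
#' @param seed integer seed.
#' @return an [aa_seqs] with attribute `supplement_keys`. If the pool is too
#'   small the whole pool is used, with a warning.
#' @export
add_supplements <- function(reference, pool, total, seed = 1L) {
  stopifnot(inherits(reference, "aa_seqs"), inherits(pool, "aa_seqs"))
  nref <- length(reference$id)
  if (total < nref) stop("total smaller than the reference set")
  need <- total - nref
  if (need > length(pool$id)) {
    warning("pool smaller than requested; using all ", length(pool$id),
            " pool sequences")
    need <- length(pool$id)
  }
  idx <- if (need > 0L) {
    set.seed(seed)
    sample.int(length(pool$id), need)
  } else integer()
  out <- aa_seqs(c(reference$seq, pool$seq[idx]),
                 c(reference$id, pool$id[idx]))
  attr(out, "supplement_keys") <- seq_keys(pool$id[idx])
  out
}

#' Drop supplemental rows from an alignment
#'
#' @param aln an [aa_aln] from aligning an [add_supplements()] set.
#' @param supplement_keys keys recorded by [add_supplements()].
#' @param drop_empty_columns remove columns that become all-gap.
#' @return an [aa_aln] with only the reference rows.
#' @export
remove_supplements <- function(aln, supplement_keys,
                               drop_empty_columns = TRUE) {
  keep <- !(seq_keys(aln) %in% supplement_keys)
  rows <- aln$row[keep]
  if (drop_empty_columns) {
    mat <- matrix(unlist(str_chars(rows)), nrow = sum(keep), byrow = TRUE)
    use <- colSums(mat != "-") > 0
    rows <- apply(mat[, use, drop = FALSE], 1L, paste, collapse = "")
  }
  aa_aln(rows, aln$id[keep])
}
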