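# ctxalign

Context-aware progressive multiple sequence alignment for proteins.

`ctxalign` aligns protein sequences with a profile–profile progressive
aligner whose scoring function uses two kinds of local sequence context on
top of a standard substitution matrix:

* **Predicted secondary structure.** A fast GOR-style single-sequence
  predictor assigns each residue helix/sheet/coil (H/E/C) probabilities,
  and profile columns are compared through a symmetric 3×3 structure
  log-odds matrix added to the substitution score. Aligning a predicted
  helix to a predicted strand is penalized; matching states are rewarded.
* **Gap context.** Gap opening and extension costs are modulated by the
  residues flanking the candidate gap (offsets −4…+4 on the gapped strand),
  the residue opposite a gap column, and runs of gap-preferring residues on
  the opposing strand. The applied modifier is clamped to ±20 % of the base
  cost so context can nudge, but never overwhelm, the affine gap model.

Both context models are *estimated from data* by functions in the package
(`train_gor()`, `estimate_gap_model()`), and the package ships seeded
simulators that generate labeled corpora, gap-annotated pairs and whole
protein families with exactly known true alignments, so every estimator and
the end-to-end aligner can be validated against ground truth.

## Quick start

```r
library(ctxalign)

# models: GOR secondary-structure predictor, gap-context model,
# substitution matrix (BLOSUM62 in third-bits) and structure matrix.
models <- default_models()

seqs <- aa_seqs(c("MKVLITGGAGFIGSHLVDRLMAEGH",
                  "MKILVTGGAGYIGSHTCVQLLQNGH",
                  "MNVLVTGGAGFIGFHTAKALLEAGH"),
                c("seq1", "seq2", "seq3"))
aln <- align(seqs, models = models)
aln$row

# score a test alignment against a trusted reference
ref <- aln   # placeholder: any aa_aln with the same sequences
score_alignment(aln, ref)
```

`align()` builds a k-mer distance matrix, clusters it with UPGMA into a
guide tree, and aligns profiles up the tree; `iterations = 2` re-estimates
the tree from the first alignment and realigns.

### Fitting the context models

```r
# secondary structure: train on (sequence, 3-state label) pairs
corpus <- make_labeled_ss_corpus(ss_generator_config(seed = 1), 60000)
gor <- train_gor(corpus$seqs, corpus$states)
predict_hec("MKVLITGGAGFIGSHLV", gor)

# gap context: estimate from gapped pairwise alignments
pairs <- make_gap_pairs(context_bias = default_gap_bias(),
                        n_pairs = 5000, seed = 2)
gaps <- estimate_gap_model(extract_gap_events(pairs$pairs))
print(gaps)
```

Scores throughout are in *third-bits* (`3 × log2` of an odds ratio), the
same unit as the rescaled BLOSUM62 matrix, so substitution, structure and
gap-context terms are directly commensurable; `to_third_bits()` converts
observed/background frequency pairs.

### Benchmark scoring

`qscore()` (sensitivity), `mscore()` (Modeler precision), `tcscore()`
(total columns) and `cline_shift()` (near-miss-tolerant shift score)
compare a test alignment to an annotated reference. Lowercase reference
residues are treated as outside core blocks and excluded by default;
sequences are matched by identifier, not row order. `ss_identity()` scores
pairwise 8-state DSSP label alignments.

### Simulators

* `make_labeled_ss_corpus()` — residues emitted from helix/sheet/coil
  propensities along a hidden Markov-segment state path, with 8-state
  labels that reduce exactly to the hidden states.
* `make_gap_pairs()` — pairwise alignments with one planted gap whose
  boundary context follows configurable residue enrichment multipliers
  (exact by construction, so estimators can be checked quantitatively).
* `evolve_family()` — a protein family evolved along a (or a supplied)
  coalescent tree with state-dependent substitution rates, indel placement
  and emissions, returning the exact true alignment, the hidden structure
  states and a full indel event log.

## Command line

A thin CLI wraps the main entry points:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ctxalign.R", package="ctxalign"))')" \
    align --in seqs.fasta --out aln.fasta
```

Subcommands: `align` (FASTA in/out), `score` (test vs reference FASTA
alignments, prints the benchmark statistics), `simulate` (writes a
simulated family and its true alignment).

## Testing

The package uses testthat (edition 3):

```r
testthat::test_dir("tests/testthat", package = "ctxalign",
                   load_package = "installed")
```

The suite checks every numerical kernel against an independent oracle:
exhaustive path enumeration for the aligner, brute-force pair enumeration
for the scorers, analytic log-ratios for the estimators. A standalone
report can be generated with:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
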