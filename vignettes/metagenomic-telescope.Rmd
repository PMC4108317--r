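---
title: "The metagenomic telescope: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metagenomic telescope: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Remote protein homologs often sit beyond the reach of a single profile
search: a family model built from well-annotated sequences assigns them
scores indistinguishable from background. Transitive search exploits
intermediates — if A detects B and B detects C, C can be reached even when A
cannot see it directly. Metagenomes, with their enormous unlabelled
diversity, are a natural reservoir of such intermediates.

`metatelescope` implements this idea as a two-projection pipeline:

1. **Original projection.** A profile hidden Markov model (HMM) is built
   from a seed family and searched directly against model-organism
   proteomes. Targets with E-value at or below the inclusion threshold
   (default `1e-6`) are the *original hits*.
2. **Projection 1.** The same model is searched against proteins derived
   from metagenome contigs — every stop-to-stop open reading frame (ORF) in
   all six frames, translated with the bacterial/archaeal code. The hits
   are the *metagenome matches*.
3. **Projection 2.** The match sequences are clustered by density (OPTICS
   on an alignment-identity distance); each sufficiently large cluster is
   aligned, turned into a new profile HMM, calibrated, and searched against
   the same proteomes. The union of their hits are the *telescopic hits*,
   and targets absent from the original hits are the *new telescopic
   hits* — the candidates the telescope adds.

## The profile HMM and its scoring

The model is a Plan7-style linear profile: per node a match state with its
own emission distribution over the 20 amino acids, an insert state, and a
silent delete state, plus BEGIN and END. Scoring is **glocal** by default —
the entire model must align to the entire sequence; flanking residues are
absorbed by the terminal insert states. A `mode = "local"` switch adds
background-emitting flank states with self-loop probability `L/(L+2)`
instead. Glocal is the right default here because whole ORFs and whole
proteins are the scored units.

The reported score is the forward log-odds
`log2(P(w | model) / P(w | background))`, with the background emitting
residues i.i.d. from Robinson–Robinson frequencies. All recursions run in
log space with a log-sum-exp primitive (underflow is treated as a
correctness bug, not a tolerance issue); the inner loops are compiled
(Rcpp). Viterbi decoding is provided alongside; at tied dynamic-programming
cells the match predecessor is preferred over insert, insert over delete,
which makes decoded paths deterministic. `X` residues score zero log-odds
(background-distributed) in every emitting state.

### Model estimation

Alignment columns with non-gap fraction ≥ 0.5 become match states
(`occupancy`, tunable). Rows are weighted with Henikoff position-based
weights, normalised to sum to the number of rows. Emissions and transitions
are pseudocounted weighted counts,
`(counts + pc) / (total + k * pc)`; transitions outside the Plan7 topology
(delete directly followed by insert and vice versa) are dropped. The
default pseudocount is `pc = 0.25`. A flat Laplace `pc = 1` — the simplest
textbook choice — measurably flattens the profile of a typical 10–15
sequence seed family: at family-level target identity (~45–55%) it costs
tens of bits of score, enough to push genuine homologs into the noise band
around the inclusion threshold. Production model builders solve this with
informative Dirichlet-mixture priors; `0.25` is the simplest defensible
analogue and leaves random sequences unscored (no decoy passed the
threshold in any benchmark replicate at either setting).

### E-values

E-values require an explicit null. For each search the model is calibrated
against the target database: `n_samples = 1000` background sequences are
drawn at lengths sampled from the database's length distribution, scored,
and a Gumbel is fitted, giving
`E = N * (1 - exp(-exp(-lambda * (s - mu_L))))`.

Two numerical choices matter:

* **Length-conditional location.** Glocal scores carry a strong
  deterministic length trend — short targets pay delete penalties, long
  ones insert penalties. When the calibration lengths span three or more
  values, a linear fit of score on length is removed first and the Gumbel
  describes the residuals, so the location parameter is
  `mu_L = mu + alpha + beta * L`. With a constant-length calibration the
  trend is zero and the closed-form Gumbel expressions hold exactly
  (e.g. `E(s = mu) = 0.632 N`).
* **Tail fitting.** The null scores are sums over many positions and are
  approximately Gaussian in the bulk; a Gumbel fitted to the whole sample
  badly overestimates the upper tail. The fit is therefore censored
  maximum likelihood on the upper decile (`tail_frac = 0.10`; scores below
  the cut enter only through the count). At the empirical 99th percentile
  the fitted exceedance is within ~15% of the true 1%, against ~70% error
  at `tail_frac = 0.25` and several-fold error for a full-sample fit. The
  tail fraction, sample size and seed are stored in the model so a
  calibration is reproducible.

## Alignment stages

Pairwise global alignment uses an affine gap model (a gap run of length
`L` costs `gap_open + L * gap_extend`; defaults −10/−1 with BLOSUM62) in a
compiled three-state DP with deterministic traceback (diagonal, then gap in
the second sequence, then gap in the first). The multiple aligner is
progressive: UPGMA guide tree on `1 − fractional identity`, groups merged
leaf-to-root by profile–profile alignment with the same gap model, column
score the mean substitution score over residue pairs (gaps excluded from
the normalisation). Two sequences reduce exactly to the pairwise aligner.
Externally computed alignments can be substituted via `read_msa()`.

Identity and similarity percentages are computed over *all* alignment
columns, similarity using the positive-substitution-score ("+") convention.
The denominator convention is stated because published identity/similarity
figures are tool-dependent; with the alternative (non-gap columns only) the
numbers can be re-derived from the same alignment.

## Clustering

Metagenome matches are clustered on `d = 1 − fractional identity` of their
pairwise global alignments. OPTICS (min_pts = 5, eps = ∞) produces the
reachability ordering; flat clusters are cut at `eps_prime = 0.6`
(DBSCAN-style extraction), and clusters below 5 members are noise. The
defaults are set so that family-level groups — above roughly 40% identity —
cohere while unrelated ORFs stay noise. The full ORF proteins (not
model-matched envelopes) are clustered and aligned, because glocal scoring
makes the whole ORF the matched unit. Tie-breaks (seed pops, start points)
always take the earliest input index, so the ordering is deterministic;
cluster memberships are order-invariant up to that tie-break. The
ξ-hierarchy extraction of the original OPTICS publication is out of scope;
the flat cut is simpler and directly testable against DBSCAN. The known
caveat of that equivalence is retained deliberately: border points
(non-core points within the cut of a core point) are assignment-ambiguous
in both algorithms, and the tests treat them accordingly.

## The synthetic benchmark

All sensitivity claims are evaluated on generated data with known labels,
emulating the real study design (a conserved seed family; divergent
homologs implanted in contigs among decoys; proteomes holding close
homologs, remote homologs and decoys). The generators are pure functions of
their seeds.

* **Substitution model.** A substituted site receives a *different* residue
  drawn from the BLOSUM62-conditional distribution
  `P(b|a) ∝ p_b 2^(S_ab/2)`. Self-substitution is excluded: with it, the
  BLOSUM62 diagonal is heavy enough that per-branch identity bottoms out
  near 30%, and no chain could place remote homologs at the intended
  20–25% identity to the seeds. Without it, expected identity per branch is
  essentially `1 − divergence` plus a small reconvergence term, which makes
  the chain geometry analytic.
* **Transitive chain.** The family ancestor evolves to an intermediate
  ancestor (divergence 0.45) and onward to a remote ancestor (0.50).
  Metagenome implants descend from the intermediate, proteome remote
  homologs from the remote ancestor, both at within-group divergence 0.08.
  The resulting identities — seed↔implant ≈ 0.5, implant↔remote ≈ 0.4,
  seed↔remote ≈ 0.25 — put the remote group beyond the direct model's
  reach but within the intermediate model's reach, which is precisely the
  regime in which a transitive method is informative. These values were
  fixed from the analytic identity composition before the end-to-end
  properties were evaluated.
* **Default sizes.** Family length 140, 12 seed sequences, 25 implants
  embedded in contigs with 30–150 nt random flanks among 120 decoy contigs
  (600–1200 nt), proteome of 3 close homologs, 5 remote homologs and 200
  background decoys (80–300 aa). These are desk-scale stand-ins for the
  real inputs (three environmental metagenomes, a dozen proteomes); the
  problem sizes keep a 20-replicate evaluation comfortably on one CPU.
* **Reverse translation** uses uniformly random synonymous codons of the
  bacterial/archaeal code, and implants land on both strands, so ORF
  recovery is exercised in all six frames.

What the generator does *not* emulate: sequencing error, chimeric contigs,
compositional bias (GC skew, low-complexity regions), multi-domain
architectures, and realistic phylogenetic correlation within groups
(descendants are i.i.d. around their ancestor). Passing benchmarks
therefore demonstrate the pipeline's mechanics and the transitive-reach
property under controlled divergence — not performance on any particular
environmental sample.

## Degenerate inputs and numerical edges

* Empty sequences are hard errors in scoring and alignment; empty
  databases and proteomes warn and return empty hit tables.
* An alignment with no column at the occupancy threshold cannot become a
  model (hard error), and a calibration with degenerate score variance is
  refused.
* If no cluster reaches the size floor the telescope is reported as
  degenerate with empty telescopic sets rather than failing.
* Codons containing `N` translate to `X` unless the residue is determined
  regardless of the ambiguity; ORFs are not split at `X`.
* ORF coordinates are 0-based half-open on the forward strand; the
  reverse-strand invariants (strand flip, coordinate mirroring, slice
  translation) are asserted in tests.

## Reproducibility

Every stochastic step (calibration, generators) takes an explicit seed;
`run_telescope()` derives stage seeds deterministically from one base seed,
and two runs with the same configuration are byte-identical up to the
manifest timestamp. The command-line interface (`inst/cli/telescope`)
materialises every default into the run manifest together with input
checksums.

## Known limitations

* Single-domain models only: no multi-domain envelope parsing, no
  composition bias correction, no acceleration filters — every target is
  scored with the full forward recursion.
* Gumbel calibration extrapolates several orders of magnitude beyond the
  sampled null; the tail fit makes this conservative rather than accurate
  at `E ≤ 1e-6`, so E-values should be read as ranking scores with a
  controlled false-positive direction, not literal expectations.
* The progressive aligner has no iterative refinement; for large or very
  divergent clusters an external aligner can be substituted via
  `read_msa()`.
* Identity/similarity percentages reproduce published values only up to
  the (usually unstated) convention of the tool that printed them.
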