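---
title: "ribodwell: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribodwell: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ribodwell studies how a ribosomal protein paralog reshapes translation
elongation. The scientific setting: knocking out the paralog changes the
composition of the nascent peptide exit tunnel (NPET), and the hypothesis is
that decoding speed at the P site depends on which residue of the nascent
chain currently sits at a given depth in the tunnel. The package provides the
computational stages needed to test this on ribosome profiling data —
P-site calibration, codon dwell-time estimation conditioned on the nascent
chain, a cross-clone consistency scan — together with companion analyses
(differential translation efficiency, paralog-to-core expression ratios,
coiled-coil positional enrichment, polysome AUC ratios) and seeded synthetic
generators that make every stage testable without external data.

## The dwell-time model and its estimator

Footprint counts at codon *i* of transcript *t* are modeled as negative
binomial with mean

    mu_{t,i} = a_t * dwell(codon_i) * effect(t, i),    Var = mu + alpha mu^2

where `a_t` is transcript abundance, `dwell(c)` a codon-specific relative
density (mean 1 over the 61 sense codons), and `effect(t,i)` an optional
planted multiplier active only when the residue `d` codons upstream of the
P-site codon equals a chosen amino acid and the P-site codon belongs to a
chosen codon set. Offset `d` counts codons 5' of the P site, so offset 0 is
the P-site codon's own residue; offsets 20–45 probe the NPET.

The estimator (`dwell_times()`) is deliberately the simplest one consistent
with "relative ribosome density per codon": per-transcript mean-normalized
density `x_{t,i} / mean_i(x_{t,i})` averaged over qualifying positions, then
renormalized to mean 1 over non-missing codons. Codons observed at fewer than
`min_codon_positions` (default 1) qualifying positions are *missing*, never
zero. Defaults: `trim_start = 20` and `trim_end = 10` codons excluded at the
CDS ends (initiation/termination ramps), transcripts below a mean of
`min_tx_coverage = 0.5` footprints/codon excluded. The estimator is validated
against a brute-force position-enumeration oracle to 1e-12 relative error.
Whether the original dwell estimator normalized per transcript or fitted a
joint model is not restated anywhere we could rely on; the per-transcript
normalization above is our explicit, disclosed substitute.

## The consistency grid and its null level

For each (amino acid, offset) cell, each KO clone's conditioned dwell vector
(replicates averaged) is compared to the pooled WT (all WT replicates
averaged) as `Delta(c) = log2(clone) - log2(WT)`, and the cell score is the
mean cosine similarity over all clone pairs (6 pairs for 4 clones). Cosines
are computed on raw (uncentered) Delta vectors over the intersection of
non-missing codons, requiring at least 2 shared codons and non-zero norms.

**The null level of this score is ~0.5, not 0.** Every clone shares the same
pooled-WT reference, so under the null the clones' Delta vectors share the WT
estimation error: with `n_k` clone replicates and `n_WT` WT replicates the
inter-clone correlation is `n_k / (n_k + n_WT)`, i.e. 1/2 for 3 vs 3. Null
cosines therefore concentrate near 0.5 (Monte-Carlo: mean 0.498, SD 0.065
per cell), and a grid maximum of ~0.6–0.75 over 520 cells is the expected
null background. This is a property of the one-shared-reference design, not
a bug; a planted effect is detected because its cell rises far above this
level (typically > 0.9 at the default simulation scale). Tests assert the
derived ~0.5 null level; a criterion demanding a null grid maximum below 0.5
is left failing by design, because it is unattainable under the stated
WT-pooling scheme at any sequencing depth.

Argmax ties resolve to the lexicographically smallest (amino acid, offset).

## Synthetic data: what it emulates and what it does not

The generators (`gen_transcriptome()`, `simulate_footprints()`,
`simulate_reads()`, `simulate_rnaseq()`, `simulate_polysome_trace()`,
`gen_domain_sets()`) emulate the statistical structure the analyses assume:

* uniform codon usage with forced ATG/stop; short UTRs (18/21 nt) so that
  footprint 5' ends near the start codon remain on-transcript;
* NB counts with dispersion `alpha = 0.1` by default (`Var = mu + alpha mu^2`);
  no noise model was stated for the source data, NB is the standard count
  model the TE stage assumes;
* log-normal(0, 1) transcript abundances — a realistic dynamic range without
  heavy tails dominating dwell estimates;
* 28–32 nt reads with length-dependent P-site offsets (12–14 nt) and a frame
  jitter: with probability `frame_noise` the 5' end shifts by a uniform draw
  from {-1, 0, +1}, giving a frame-0 fraction of `1 - 2*frame_noise/3`;
* a start-codon initiation peak (`init_boost = 5`): real ribo-seq libraries
  prepared with cycloheximide carry a strong initiation peak, and the
  start-codon metagene used for P-site calibration is not identifiable
  without one (all codons would contribute equally to distances
  `offset - 3k`);
* Gaussian-mixture polysome traces with closed-form peak areas
  `height * width * sqrt(2*pi)`;
* coiled-coil intervals whose relative start is Beta(1 + bias, 1) for target
  proteins and uniform otherwise.

Not emulated: sequencing errors, rRNA contamination, UMIs, multimapping,
isoform mixtures, batch effects. A green recovery test therefore establishes
that the estimators invert the stated generative model at realistic depth and
noise — not that they are robust to every artifact of real libraries.

Seeding: every generator derives a child seed from `(master seed, stage
label)` via a 32-bit FNV-1a hash and a Lehmer step modulo 2^31-1
(`child_seed()`), so outputs are bit-reproducible, independent of call order,
and all intermediate seeds stay below 2^31.

## P-site calibration and periodicity

Per read length, the offset is the mode of (start-codon position − 5' end)
over reads whose 5' ends fall within −20..+10 nt of annotated start codons,
requiring at least 200 windowed reads and a modal bin holding ≥ 30% of them;
lengths failing either are flagged discarded. This metagene-mode method is a
stated substitute for an unpublished in-house algorithm, chosen because it is
deterministic and testable by round-trip. Off-frame P-sites are assigned to
the containing codon by floor division rather than discarded — reads are
preserved and the periodicity diagnostics still expose frame quality. The
dominant period is the smallest autocorrelation lag (2–6) within 90% of the
maximum, so the 3-nt fundamental beats its 6-nt harmonic; the call is flagged
unstable below a noise floor of `max(0.1, 3/sqrt(profile length))`.

## Differential translation efficiency

`delta_te_test()` fits, per gene, an NB log-linear model on the combined
RNA + RPF counts with terms intercept + genotype + assay + genotype:assay and
a `log(size factor)` offset (median-of-ratios factors over the combined
matrix). The interaction coefficient is the TE log2 fold change; the Wald
statistic uses the expected information with the dispersion held at its
**Cox–Reid adjusted** profile-ML estimate (floor 1e-8). Plain ML dispersion
is biased low with 3 replicates (median estimate 0.065 for a true 0.1),
inflating type-I error to ~4.6% at the 1% level; the CR adjustment — the
standard small-sample ML variant — restores the dispersion (median 0.095)
and brings type-I error to ~1–2.5%. No shrinkage across genes is applied, by
design. An LRT variant is available behind `test = "lrt"`. Genes with an
all-zero (assay, genotype) cell are excluded before fitting; degenerate fits
are flagged and excluded from BH correction, with counts reported.

## Rank and scale tests

Wilcoxon rank-sum comparisons (`group_ratio_tests()`,
`binned_mannwhitney()`) use exact mid-rank enumeration for combined n ≤ 12
(twice the smaller tail, capped at 1) and the mid-rank normal approximation
with continuity correction above. The Ansari–Bradley scale test
(`dispersion_test()`) enumerates the exact null for combined n ≤ 20 and uses
the score-based normal approximation above; both are validated against
independent oracles (complete enumeration; `stats::ansari.test`). The
paralog-ratio reference is the pooled normal-sample set, one ratio per
sample; per-bin coiled-coil p-values carry no cross-bin correction, matching
a per-bin profile display, while a single C-terminal-half summary test is
provided alongside.

## Polysome traces

`auc_ratio()` integrates the monosome and polysome regions by the trapezoid
rule after baseline subtraction; baseline handling in the source protocol is
unstated, so all three modes are exposed (`linear` endpoints default,
`constant` region minimum, `none`). Region bounds are user-supplied; a peak
finder is provided but never applied silently. The clone comparison uses a
one-sided Welch t-test (KO greater), with fold changes expressed relative to
the WT median ratio.

## Numerical and interface choices

* Coordinates are 0-based half-open on the transcript; frame is defined
  relative to the annotated ATG; codon indices in TSV outputs are 0-based.
* Stop codons are excluded from dwell vectors (61 sense codons); the
  conditioning residue comes from the protein sequence.
* The pipeline configuration is JSON (no YAML parser in the supported
  dependency set); unknown keys are rejected before any stage runs.
* All writers emit a provenance header (package version, parameter hash,
  seed) with no timestamps, so reruns are byte-identical.
* Exit codes: 0 ok, 1 user error, 2 internal error.

## Known limitations

* The dwell estimator ignores codon-pair and ramp effects and assumes
  position-independent dwell within the trimmed CDS.
* The consistency score inherits the ~0.5 null floor discussed above;
  comparisons across designs with different WT/clone replicate ratios shift
  this floor and are not directly comparable.
* TE densities use total CDS counts; no within-CDS positional weighting.
* Coiled-coil intervals are consumed as annotations; no structure prediction
  is performed, and the proteome background proportion is an input.
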