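---
title: "Models and methods behind htselex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind htselex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`htselex` analyses high-throughput sequencing of SELEX aptamer selections:
per-round FASTQ files are reduced to counted 30-nt random-region cores,
summarised into enrichment statistics, clustered into aptamer families
with round-to-round fates, and complemented by one-site binding-affinity
fits and a ground-truth simulator. This vignette records the models, the
defaults and the reasoning behind every genuinely open design choice.

## Read processing

Reads are single-end, fixed-cycle Illumina reads covering the random core
followed by a 3'-fixed oligo and sequencing adapter. Processing applies
three rules in order:

1. **N truncation.** Bases from the first `N` onwards are discarded, the
   `N` included. Base callers emit `N` when a cycle fails, and later
   cycles on such reads are unreliable; since an `N` can never be part of
   a usable A/C/G/T core, removing it with the tail keeps the usable
   filter a pure length check.
2. **Fixed-oligo trimming.** The read is scanned left to right; at each
   position the probe is the first `min(fixed3_min_anchor, remaining)`
   bases of the fixed oligo (anchor default 10 nt). A full-length anchor
   tolerates `fixed3_max_mismatch` Hamming mismatches (default 1; reads
   are fixed-cycle, so substitutions dominate and indel-free matching is
   both adequate and exactly testable against a brute-force scan).
   Shorter terminal overlaps scale the allowance down proportionally
   (`floor(max_mismatch * overlap / anchor)`), the same convention
   adapter trimmers use: a 2-nt overlap that tolerated a mismatch would
   "match" almost any read tail and silently shave real cores. The
   leftmost accepted position wins, which prevents chimeric over-long
   cores; reads with no accepted position pass through unchanged and are
   left to the length filter. The adapter beyond the fixed oligo is never
   searched separately — cutting at the fixed-oligo start already removes
   everything 3' of the core.
3. **Usable filter.** A read is usable iff its trimmed core is exactly
   `core_length` (default 30 nt) and N-free. Strict equality is
   deliberate: a 29- or 31-nt core cannot be aligned position-by-position
   with the rest of the pool.

Quality strings are parsed and preserved but never used for filtering; no
quality threshold is part of the processing model. Sequences are kept in
the DNA alphabet (T, not U) because the sequencer reads cDNA. The
constant regions themselves are configuration (`library_layout()`):
sequencing providers and library designs differ, so no constants are
baked in; the simulator fixes its own 21-nt oligo such that core + oligo
exactly fill a 51-cycle read.

## Enrichment statistics

For round *X* with usable reads `U_X`, the ranking of unique cores is by
count descending with lexicographic tie-break — the tie rule is arbitrary
but makes every ranking, and hence every top-N set, fully deterministic.
The reported statistics are the top-N read total `T_X` (N defaults to
1000), its frequency `f_X = T_X / U_X`, and the molecular enrichment fold
`E_X = T_X / T_0` against the unselected library; `E` is exactly 1 at the
initial round and invariant to uniform rescaling of all counts.
Cross-round tracking matches a reference round's top set (conventionally
the final round) by exact 30-mer identity; no mismatch tolerance is
applied because counting is of exact uniques throughout — error
correction or near-identical read merging is explicitly out of scope.

Three frequency denominators coexist in practice and are all computed and
labelled rather than guessed: usable reads (`frequency_in_usable`), the
round's top-N total (`frequency_in_top`, the conventional denominator for
family-evolution plots), and the clustered top-50 total (the denominator
that reproduces published family percentages of the *initial* libraries,
e.g. 3,207/3,677 = 87.22%).

Composition profiles are read-weighted by default (every usable read
counts), matching how pool compositions are reported; unique weighting is
available as a synthesis-bias diagnostic independent of depth. Purine =
A+G and pyrimidine = C+T; in 2'-fluoro RNA selections the pyrimidines
carry the modification, so this split tracks preferential incorporation
of modified nucleotides. Internal arithmetic is full precision; printing
at 2–3 decimals happens only in the report writers.

## Folding and family clustering

Secondary structures are predicted by Nussinov-style base-pair
maximisation with pairs A·U(T), G·C and the G·U(T) wobble and a minimum
hairpin loop of 3 unpaired bases (`j - i > min_loop`). A thermodynamic
folder would be more realistic; base-pair maximisation was chosen because
its optimum is exactly checkable by brute-force enumeration, and the
folder is pluggable (`fold_fun` in `cluster_top_sequences()`) — clustering
consumes only pair sets, so any folder producing pair sets can be
substituted. Among co-optimal structures the traceback is deterministic:
leave position *i* unpaired whenever optimal, otherwise pair it with the
smallest admissible partner, so every sequence maps to one dot-bracket
string. Structure distance is the symmetric difference of pair sets.

Families are built greedily over the abundance-ranked top set (default
top 50): each sequence joins the first group whose representative lies
within `threshold` of the combined dissimilarity

```
D = alpha * edit/core_length + (1 - alpha) * bp_distance / (pairs_a + pairs_b)
```

(the structure term is 0 when both structures are unpaired), else it
founds a new group. Because visiting order follows abundance, a group's
representative is always its most abundant member. Defaults are
`threshold = 0.25` and `alpha = 0.85`. The strong sequence weighting is a
measured necessity, not a preference: under base-pair maximisation many
structures are co-optimal, and one or two substitutions can flip the
canonical pair set wholesale — across seeded ≤2-substitution families the
normalised pair-set distance between a variant and its seed ranged up to
1.0 (median ≈ 0.5). Any `alpha` low enough to give the structure term
half the weight therefore shatters true substitution families; at 0.85
the structure term contributes at most 0.15, below the joining threshold
less the worst-case sequence term (0.85 × 2/30 ≈ 0.057), and seeded
three-family fixtures are recovered exactly. The structure term still
separates sequence-ambiguous cases. Singleton groups whose count falls
below `orphan_min_count` (default 1% of the clustered set's reads) are
flagged as orphan sequences and aggregated into an `Others` row, as in
conventional family tables.

Whether published clusterings used full-length aptamers or bare cores is
unknowable from core-only tables; this package clusters cores, which is
also what the tables print.

**Fate labels** formalise the arrows of family-evolution tables from the
per-round frequency trajectory: *enriched* if the final frequency exceeds
the initial one and the trajectory peak lies (within 5% relative) in the
last two rounds; *depleted* if final < initial and the final value is at
most 10% of the peak; *transient* if the peak is strictly interior and the
final value is below half of it; otherwise *flat*. The 5%, 10% and 1/2
constants are tunable arguments; they were fixed once against annotated
published trajectories (a monotonically enriched family, and a
spike-and-collapse family) and are not data-derived.

## Binding affinity

The model is one-site specific binding, `F(c) = baseline + Fmax·c/(Kd+c)`
with concentrations and `Kd` in nM — the standard model for aptamer–cell
surface titrations; Hill slopes and two-site models are out of scope.
Fitting is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on the
residuals with the analytic Jacobian `∂F/∂Kd = -Fmax·c/(Kd+c)^2`,
`∂F/∂Fmax = c/(Kd+c)`, `∂F/∂baseline = 1`; `Kd` and `Fmax` are
constrained positive, tolerances are 1e-8 on parameters and objective,
and convergence is reported, never assumed. Starting values are
`Fmax0 = max(signal)` and `Kd0 =` the concentration nearest half-maximal
signal — the textbook initialisation, adequate because the model is
monotone in both parameters. The baseline term is off by default: whether
background subtraction precedes fitting differs between labs, so both
routes are exposed (`baseline = TRUE` absorbs constant background).
Degenerate inputs (constant signals, fewer than four distinct
concentrations) are errors, not silent fits. The synthetic-curve
generator uses multiplicative Gaussian noise `(1 + cv·Z)` truncated at
zero, the usual error model for mean-fluorescence readouts.

## The synthetic SELEX generator

The generator exists so that every pipeline stage has a ground truth. One
experiment is: draw an initial library, then per round apply selection,
amplification and multinomial sequencing at fixed depth.

* **Initial library.** `n_template_species` background 30-mers drawn
  i.i.d. per base from `base_weights`, sharing the non-spike probability
  mass equally; spiked "biased sequences" at fixed frequencies (default:
  one spike at 3.16% — a published biased-sequence frequency — with
  selection advantage `s = 2.5`, which reproduces a strong
  thousands-fold enrichment over seven rounds). Default base weights are
  published initial-pool compositions (solution-PCR conversion:
  A 22.5 / C 22.6 / T 28.1 / G 26.8%; droplet: A 19.9 / C 24.4 / T 24.5 /
  G 31.2% — the droplet default carries the G-rich synthesis bias).
  Background cores containing an internal near-match of the fixed oligo
  are rejected at synthesis: their reads would be trimmed inside the
  random region and could never be observed usable, so excluding them
  keeps the truth table exactly recoverable.
* **Selection.** Post-selection weight ∝ weight × (1 + s): multiplicative
  fitness, the simplest model consistent with exponential-looking
  enrichment. Counter-selection against non-target cells is absorbed into
  `s` rather than modelled as a separate population. Background species
  receive `s = 0` except for a small exponential high-affinity tail
  (probability 0.01, mean 0.5) so that de-novo winners can emerge.
* **Amplification.** Solution PCR multiplies each weight by
  `exp(β · T-fraction)` (default β = 2): a whole-sequence advantage for
  thymidine-rich templates, acting on pool composition rather than
  per-base mutation, because the drift to be emulated is of the pool.
  With β > 0 the expected T composition is non-decreasing round over
  round. Droplet digital PCR caps each template's expected copies (at
  sequencing-depth scale) at `droplet_capacity` (default 1000, i.e. 1% of
  a 1e5-read round) — a deliberate idealisation of equal template
  partitioning into uniform droplets that flattens abundances and
  preserves diversity. Whether the droplet G-bias arises at library
  synthesis or per amplification round cannot be separated from
  sequencing alone, so both switches exist: G-rich `base_weights`
  (default on via the droplet composition) and a per-round
  `droplet_g_beta` (default 0). Reverse transcription and in-vitro
  transcription are treated as lossless identity steps.
* **Sequencing.** Multinomial sampling of exactly `depth_per_round` reads
  (default 1e5 — large enough for stable top-1000 statistics, small
  enough that a full 8-library experiment simulates and analyses in well
  under five minutes), cores wrapped as core + fixed oligo into 51-nt
  reads, per-base substitution errors at `error_rate` (default 0.001;
  set 0 for exact truth-table tests). All randomness flows from the
  single configuration seed; identical configurations give byte-identical
  FASTQ.

What the generator emulates: spiked biased sequences and their
target-dependent fates, selection-driven diversity collapse, PCR-method-
dependent composition drift and diversity preservation, sequencing noise.
What it does not: thermocycler kinetics, primer dimers, chimera
formation, droplet-size distributions, RT/transcription bias, quality
degradation profiles — and it makes no attempt to match published
composition percentages quantitatively, only directionally. Passing
tests on simulated data therefore validate the pipeline's bookkeeping and
the models' qualitative phenomenology, not quantitative agreement with
any real selection.

## Problem sizes and tolerances in the test suite

Unit tests run at depths 1e3–2e4 with 300–2000 template species; the
end-to-end acceptance checks use one full-scale run (depth 1e5, 8
libraries) plus 20-replicate sign tests for drift direction, 200
Monte-Carlo curves for Kd recovery (median relative error < 10%, bias
< 5% at 5% measurement noise), and exhaustive-enumeration folding oracles
up to length 12. Stochastic assertions use fixed seeds and 3-sigma
binomial/multinomial envelopes. Composition conservation is asserted to
1e-9; population renormalisation to 1e-12.

## Known limitations

* Exact unique counting means sequencing errors smear counts across
  near-identical sequences; at the default simulated error rate this
  removes a few percent of reads from their true core. Error-aware
  clustering of reads before counting is intentionally out of scope.
* The folder maximises pair count, not free energy; its structures are a
  similarity descriptor, not a prediction of the molecule's fold.
* The greedy clustering is order-dependent by design (abundance order);
  it is deterministic and fast, but not a global optimum over partitions.
* Fate labels summarise trajectories of noisy frequencies; for families
  near the classification thresholds the label can change with depth.
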