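---
title: "Methods: inosine-aware seed retargeting and silencing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inosine-aware seed retargeting and silencing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inoseed)
```

## The biological question

ADAR enzymes deaminate adenosine to inosine (A-to-I editing) in
double-stranded RNA. When the editing site falls inside a microRNA seed
region (nucleotides 2–8 from the 5′ end), the edited miRNA can be retargeted:
inosine pairs preferentially with cytidine, so an edited seed recognizes a
different complement than the wild-type seed. Inosine is often treated as
equivalent to guanosine, but I:C pairs are thermodynamically weaker than G:C
pairs, and I:U weaker than G:U. `inoseed` implements the computational side
of testing that distinction: given a miRNA duplex with a known editing site,
it derives the editing-variant seeds and their mRNA-side target motifs,
groups transcripts by which motif their 3′-UTR carries, quantifies per-group
repression from single-channel expression arrays against a mock transfection,
and relates silencing strength to the melting temperature of the seed–target
duplex.

## Seed variants and target motifs

A miRNA duplex is modeled as two 5′→3′ strands, the *edited strand* carrying
a 1-based editing position (e.g. +6 for miR-376a-3p) and the wild-type
*opposite strand*. Positions are always counted from the 5′ end and intervals
are inclusive, matching the "+6" convention. The three duplex types differ
only at the editing site of the edited strand — A (wild type), I (edited), or
G (the guanosine mimic) — and the opposite strand carries U at the pairing
position, so the duplexes form A:U, I:U and G:U pairs there.

The seed is the 7-mer at strand positions 2–8. The four *target motifs* are
the mRNA-side 7-mers a 3′-UTR must contain to be seed-complementary: the
reverse complement of the seed with the position opposite the editing site
(motif index `8 − seed_edit_index`) enumerated over A, C, G and U. These
define the A-, C-, G- and U-target gene groups; the wild-type seed pairs the
U-target motif, the I- and G-seeds pair the C-target motif. Complementation
maps A↔U and G↔C, with I→C (inosine read as pairing cytidine); motifs never
contain inosine. The *dead seed* is the seed of the opposite strand, and
genes complementary to it are excluded everywhere, since they could be
silenced by the passenger strand regardless of editing.

Edit sites outside positions 2–8 are accepted on strands (they occur in
nature) but rejected by motif construction with an explicit error, because
group formation is defined only for seed edits.

The packaged example duplex (`mir376a2_duplex()`) uses the miRBase mature
miR-376a-3p guide sequence; the passenger is reconstructed as its perfect
antiparallel complement with 2-nt 3′ overhangs and is documented as
synthetic. Real duplexes contain bulges; the constructor therefore only warns,
rather than errors, when it cannot confirm a U opposite the edit site under
the canonical overhang register.

## Target grouping

`assign_target_groups()` follows a fixed order: (i) discard genes matching
the dead-seed motif; (ii) group remaining genes by which variant motif they
match at least once; (iii) discard genes matching more than one group;
(iv) define group X's background as the universe minus dead matches minus X
itself. Backgrounds deliberately differ slightly between groups: another
group's members remain in X's background. Matching is exact,
case-insensitive, forward-strand (UTRs are mRNA-sense); overlapping
occurrences are counted and retained for diagnostics, but membership only
requires one hit. The universe is the set of genes present in both the UTR
collection and the filtered expression table, mirroring the restriction of
array probes to annotated transcripts.

## Expression preprocessing

The probe matrix carries per-sample intensities and a boolean
"detected with certainty" flag per probe (synthetic data emits it; array
platform exports map their well-above-background flag onto it). The pipeline
order is fixed: keep probes detected in **all** samples, quantile-normalize
intensities across samples (ties receive the mean of their tied ranks'
values; implemented via `limma::normalizeQuantiles`), then average plural
probes per gene on the **linear** scale — the detection filter has already
confined signals to the linear range. Per contrast against mock,
`M = log2(sample/mock)` and `A = (log10 sample + log10 mock)/2`; the mixed
log bases (2 for the ratio, 10 for the abundance axis) are intentional and
part of the M/A definition this analysis adopts.

## Repression statistics

For each group, the *fold-change area* statistic is
`mean(background M) − mean(target M)`; positive values mean targets are more
repressed. It equals the signed area between the target and background
empirical cumulative distributions of M, which is how the cumulative plots
are read. Significance comes from the Wilcoxon rank-sum test. The test's
sidedness is a user choice; the default is one-sided ("targets lower"),
because the scientific hypothesis is directional repression, and a two-sided
mode is available. The significance threshold defaults to p < 1×10⁻². For
pooled samples of at most 12 observations the p-value is computed by exact
enumeration of all `choose(n+m, n)` labelings of the pooled ranks — which
remains exact under ties — and larger samples use the normal approximation
with continuity and tie correction via `stats::wilcox.test`. Constant pooled
data degenerates to p = 1 with a warning. No multiple-testing correction is
applied across groups or duplexes; each comparison is reported at its raw
p-value.

qRT-PCR support is the standard ΔΔCt reading of double normalization (first
to a reference gene such as LDHA, then to mock): relative expression is
`2^−ΔΔCt`.

## Thermodynamics

Seed–target duplex stability is handled on two routes:

* **Measured calibration (primary).** `calibration_table()` stores the
  UV-measured Tm values of the five melting 7-bp miR-376a-3p seed–target
  duplexes (A:U 26.6 °C, G:C 39.0 °C, I:C 23.3 °C, G:U 19.3 °C, I:U 9.3 °C)
  and the A:C duplex as *not determined* — a value, not an error. These
  reproduce the stability ranking G:C > A:U > I:C > G:U > I:U. Lookup is by
  exact (seed, target) key; an absent key raises a typed missing-entry
  condition.
* **Nearest-neighbor prediction (fallback, Watson–Crick only).** Published
  nearest-neighbor parameters exist only for Watson–Crick RNA stacks;
  inosine-pair stack parameters have not been determined. The package ships
  the canonical 1 M NaCl RNA ΔH°/ΔS° set (expanded to all 16 stack keys,
  plus initiation and terminal-AU terms) as a user-replaceable tibble, and
  computes `Tm(K) = ΔH°·1000 / (ΔS° + R·ln(C_T/4))` with
  R = 1.987 cal/(mol·K), the non-self-complementary `C_T/4` term, and a
  default total strand concentration of 5 µM (the melting buffer was 1 M
  NaCl; no salt correction is applied, the parameters being defined at that
  ionic strength). A duplex containing any stack absent from the parameter
  table — inosine pairs, G:U wobbles — returns `NA` ("unavailable") rather
  than erroring, so prediction degrades explicitly, never silently.

`seed_duplex_tm()` resolves a pair through the calibration first and records
the provenance of every value (`measured`, `not_determined`, `predicted`,
`unavailable`).

**Melting curves.** The vendor "Two Point Average" algorithm is not published
in detail; the package adopts and documents this reading: the lower baseline
is the mean absorbance over the first `baseline_fraction` of points (default
0.15), the upper over the last, and Tm is the temperature where the
(optionally running-mean-smoothed) curve first crosses the midpoint of the
two baselines, located by linear interpolation between bracketing samples.
This makes the estimate invariant to constant offsets and affine rescaling of
the absorbance axis, and recovers the midpoint of symmetric two-state curves
exactly.

**miScore.** `miScore = Tm₂₋₈ − 0.5·miTm₁₋₅`: a stable seed–target duplex
(high Tm₂₋₈) promotes silencing while a stable 5′-terminal 5-bp duplex (high
miTm₁₋₅) hinders RISC loading of the strand, with roughly half the weight.
5-bp duplexes are generally too unstable to melt in vitro, so miTm₁₋₅ is
computed by nearest-neighbor prediction when its pairs are Watson–Crick and
reported unavailable otherwise. For a +6 edit the 5-bp terminal duplex is
identical across A/I/G variants, so within one such duplex family Tm₂₋₈
alone ranks the variants.

## Synthetic data

Raw transfection arrays for this design are not something a user can count
on having, so the generator (`sim_config()`, `simulate_utrs()`,
`simulate_expression()`, `simulate_melting_curve()`) emulates the study
design as first-class, tested code: four samples (mock plus A-, I-, G-type
transfections), 3′-UTR sets with planted motifs, and two-state melting
curves.

Default conditions, chosen once as the study-scale operating point: 200
genes per target group against 5000 background genes with per-probe log2
noise sd 0.5 (the scale at which repression recovery is assessed), 50
dead-seed and 50 multi-group genes, UTR lengths uniform on 100–300 nt with
uniform base composition, log2-normal baseline intensities (mean 8, sd 2,
typical of single-channel arrays), a 5% detection-dropout rate and 1–3
probes per gene. Repression is a pure log2 mean shift: each miRNA sample is
`mock × 2^(−δ + ε)`, `ε ~ N(0, noise_sd)`, the minimal model consistent with
the M-value statistic (no variance change, no dose–response). The default
effect map encodes the qualitative biological outcome — A-type represses
U-targets (δ = 0.5), G-type represses C-targets (δ = 0.5), I-type represses
C-targets more weakly (δ = 0.3), everything else null.

Background genes are rejection-sampled to contain none of the five motifs
and planted genes are re-checked after insertion (planting can create chance
occurrences at junctions; offending draws are redrawn), so truth labels
round-trip exactly through `assign_target_groups()` and truth-based tests
are deterministic. All randomness flows from the single integer seed in the
configuration; repeated runs are byte-identical.

What the generator does **not** emulate: spatial array artifacts, dye or
probe-sequence bias, saturation, correlated probe noise within genes,
non-uniform UTR base composition, off-seed (3′-supplementary or seed-mismatch)
targeting, and transfection dose–response. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under the declared
noise model, not robustness to real microarray artifacts.

## End-to-end pipeline

`run_silencing_analysis()` executes seed derivation → preprocessing →
universe restriction → grouping → per-(variant, group) statistics → Tm
attachment and miScore → Tm-vs-fold-change correlation (requiring at least 3
measured pairs), and is deterministic given its inputs. Results are a
`silencing_report` with `tidy()`, `glance()` and `autoplot()` methods;
`correlate_tm_silencing()` reproduces the packaged-table correlation
(r = 0.82 to two decimals) without any array data. File exchange uses FASTA
for UTRs (T→U on ingest), TSV for probe matrices and reports, two-column CSV
for melting curves and YAML for duplex definitions. The package's functions
are the interface; there is no shell front-end beyond the reproduction
script.

## Problem sizes and numerical choices

The test suite exercises the generator at reduced sizes (tens of genes) for
structural checks and at the full 200/5000 operating point for recovery;
null calibration of the rank-sum test uses 500 simulated datasets of 50
targets vs 500 background genes and 2000 null replicates at n = 20 vs 200
for uniformity, sizes chosen to make binomial and Kolmogorov–Smirnov bounds
informative. Quantile-normalization equality of sorted sample vectors is
asserted to 1e-9; ECDF-area agreement of the fold-change statistic to 1e-9;
melting-curve recovery to 0.1 °C noiseless and 0.5 °C at absorbance noise
sd 0.002. Ties in ranks are handled by midranks throughout; the exact
rank-sum path enumerates labelings rather than using the tie-free Wilcoxon
distribution.

## Known limitations

* The nearest-neighbor route cannot score inosine-containing or wobble
  duplexes unless the user supplies stack parameters; the measured
  calibration covers only the miR-376a-3p sequence context.
* The "dead seed" is taken literally as positions 2–8 of the opposite
  strand; whether both strands' dead seeds should be excluded simultaneously
  is left to the caller, who can pass any motif set.
* The rank-sum test's sidedness is a genuine modeling choice; both modes
  are provided and the mode used is recorded in the report parameters.
* Group fold-changes from real arrays depend on annotation coverage and
  filtering upstream of this package; synthetic recovery bounds do not
  transfer to real data quantitatively.
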