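---
title: "Genomic signatures and the genomic index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic signatures and the genomic index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Differential methylation analyses of two-group studies (tumor/normal,
treated/untreated) produce large lists of differentially methylated CpG
sites (DMS). `methsig` ranks them by the regulatory and structural content
of the sequence immediately around each CpG. The premise is that a
methylation aberration co-located with elements whose activity methylation
is known to modulate — transcription-factor binding sites, splice sites,
G-quadruplex-forming sequences, palindromes/hairpins, methylation-sensitive
local helix geometry — is a better candidate for functional follow-up than
one in a featureless region.

Formally, for sites $x_1,\dots,x_m$ and attributes $a_1,\dots,a_n$, every
site gets raw readouts $a_{ij}$ from a window of $2\cdot\mathrm{offset}$
bases centered on the CpG cytosine. Per-attribute mapping functions $m_j$
bring everything onto the unit interval: count attributes (`G4`, `Pals`,
`TFBS`, `cTFBS`) are min–max normalized across the analyzed dataset, and
the two composite attributes are logical joins — `splicing` is 1 when the
window has any putative donor site, acceptor site or known
alternative-splicing-event overlap, and `shape` is 1 when any of the four
DNA shape parameters changes significantly (p < 0.05) between the
methylated and unmethylated decoding of the window. The genomic index is
the weighted sum $\mathrm{idx}_i = \sum_j w_j\, a'_{ij}$ with non-negative
weights (default: all 1), and sites are ranked by descending index.

Assumptions worth stating plainly:

* **The index is run-relative.** Min–max normalization uses the minima and
  maxima of the dataset being analyzed, because no universal scaling
  constants exist for, say, palindrome counts. Indices are therefore
  comparable within a run, not across runs; the mapping metadata (per
  attribute min/max) is stored in the signature object and written into
  exported files so any external rescaling is explicit, and fixed global
  bounds can be supplied via the `bounds` argument of `map_attributes()`.
* **The unit interval is closed.** The extremes 0 and 1 are attainable
  (they are attained by the dataset min and max); excluding the endpoints
  would be arbitrary.
* **The index is real-valued**, a weighted sum of unit-interval values, not
  an integer score.
* **Counts, not coverage.** Overlaps with annotation tracks are counted
  per interval, not per base; two conserved-TFBS loci in one window count
  as 2 regardless of their widths.

# Detectors and their exact definitions

Counting only works if the underlying matches are deterministic and
well-defined, so each detector has a precise maximality/overlap policy,
and each is tested for exact equality against an independently coded
brute-force oracle on hundreds of seeded random sequences.

**G-quadruplexes.** A canonical quadruplex-forming sequence is four runs of
at least `min_run` (default 3) guanines separated by three loops of length
`loop_min`–`loop_max` (defaults 1–7); loops may contain any base, N breaks
a match. Overlapping candidates are resolved greedily left-to-right,
taking the longest match at each start; minus-strand matches are the same
pattern on the reverse complement (C-run pattern on the input), resolved
per strand. This is a deliberate simplification of imperfection-tolerant
quadruplex scoring: it is deterministic, exactly testable, and captures
the presence/density signal the downstream statistics use; the detector
sits behind a plain function interface so externally computed scores can
be substituted.

**Palindromes.** A palindrome is a left arm equal to the reverse
complement of the right arm, separated by a loop of at most `max_loop`
(default 10) bases, with arms of at least `min_arm` (default 6, exact
matches only). Only maximal palindromes are reported: a match is
suppressed if the arms can grow outward by one base (same loop), or inward
by one base (loop shrinks by two), and still satisfy the definition. The
inward rule prevents one physical hairpin from being re-reported once per
nested arm/loop re-parameterization, which would inflate the `Pals` count.

**PWM scanning.** JASPAR-format position frequency matrices are converted
to log-odds PWMs with per-column probabilities
$(n_b + pc \cdot bg_b)/(N + pc)$, pseudocount $pc = 0.8$ and a uniform
background by default. A hit is any offset/strand whose score, min–max
normalized between the motif's lowest and highest achievable scores,
reaches `min_rel_score` (default 0.8). Placements covering N are skipped,
never scored — windows clipped at chromosome edges therefore lose
placements rather than gaining fabricated ones.

**Splice sites.** Donor (9 positions) and acceptor (15 positions)
per-position base-frequency models are scored by the percentile form
$100\,(t - t_{min})/(t_{max} - t_{min})$, where $t$ sums the frequency of
the observed base at each position. A window's splice-site logical is any
offset on either strand reaching `min_score` (default 80) for either
model. The bundled frequency tables are data, not code: editable TSVs
under `inst/extdata/`, replaceable by any user-supplied model of the same
shape (columns must sum to 1).

**DNA shape.** Local helix geometry (minor groove width, Roll, propeller
twist, helix twist) is decoded per position from a pentamer lookup table
over the alphabet A, C, G, T, M, W, where M is 5-methylcytosine and W the
guanine paired to a methylated C on the opposite strand. Methylation of
the central CpG is encoded symmetrically over the dyad (C→M, G→W), and the
per-position difference between the methylated and native decodings is
tested with a two-sided Wilcoxon signed-rank over the positions whose
pentamer covers a modified base. The package ships a *synthetic* table
generator (`synthetic_shape_table()`, seeded, value ranges typical of each
shape parameter) so the interface is fully exercised without any
downloads; it carries no structural information, and users with a real
pentamer table load it via `read_shape_table()`.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| window offset | 50 | nt each side | 100 nt windows; clipped windows keep their reduced length, with clipping recorded |
| min Δβ | 0.3 | β difference | strict differential threshold for cancer-scale effects |
| max p, max FDR | 0.01, 0.01 | probability | strict two-sided test + BH control |
| G4 min run / loops | 3 / 1–7 | nt | canonical quadruplex definition |
| palindrome arm / loop | ≥6 / ≤10 | nt | restriction-site-scale stems, conservative |
| PWM pseudocount / threshold | 0.8 / 0.8 | counts / relative score | common motif-scanning practice |
| splice-site score | ≥80 | percentile | conventional strong-site cutoff |
| shape alpha | 0.05 | probability | per-shape significance for the joined logical |
| weights | all 1 | — | equal-weight index unless the analyst has priors |

The differential test is Welch's t-test by default with a Mann–Whitney
switch (`test = "wilcoxon"`); there is deliberately no automatic normality
gating, because silent test switching makes results irreproducible.
Whether a BED score column holds Δβ or an M-value difference is declared
by the caller (`score_type`), never autodetected.

# Numerical and degenerate-input choices

* A count attribute that is constant across the dataset maps to 0 with a
  warning (min = max leaves min–max undefined).
* Welch's statistic with zero variance in both groups is defined as p = 1
  when the means agree (no evidence) and 0 otherwise; sites with fewer
  than two usable samples in either group are excluded from testing with a
  warning, and β matrices use pairwise-complete values per site.
* `beta_to_m()` is an error at β ∈ {0, 1}; zero-depth bisulfite sites are
  masked as missing, never a division error.
* The shape Wilcoxon with fewer than 4 informative positions, or all-zero
  differences, returns p = 1 (degenerate test).
* G+C content and the CpG observed/expected ratio exclude N from both
  numerator and denominator; all-N windows report missing.
* Ranking ties are broken by |Δβ| descending, then (chrom, start), then
  site id, so output is a pure function of the input set, independent of
  row order.

# The synthetic-data generator

`sim_config()` fixes the study conditions: a random genome (default
150 kb, G+C 0.45) with 400 evenly spaced CpG target sites whose 100 nt
windows never overlap; half the sites "enriched", half "desert"; four
fixed motifs (a canonical G4, an arm-8/loop-4 palindrome, the consensus of
a bundled synthetic PFM, and the donor-site consensus) planted with
probability 0.9 per feature at enriched sites and 0.05 at desert sites; β
values drawn from the bimodal mixture Beta(0.5, 5) / Beta(5, 0.5) that
mirrors array-like β distributions, with differential sites shifted by
Δβ = 0.6 (hypermethylated sites start from the unmethylated mode and shift
up, hypomethylated ones the reverse); 10 samples per group; expression
tables couple |log2FC| linearly to the number of planted features with the
sign opposing Δβ. Every generator is a pure function of the seed.

What this emulates: the bimodal β landscape, planted effect sizes at the
strict-threshold scale, and feature-context contrast between candidate
and background sites. What it does not emulate: probe-design artifacts,
batch effects, cell-type mixtures, spatially correlated methylation, or
realistic motif co-occurrence statistics. Passing the end-to-end tests
therefore demonstrates that the pipeline recovers planted structure
exactly and ranks by feature load as designed — not that the defaults are
optimal for any particular real dataset.

# Validation design and problem sizes

The test suite checks, among others: exact detector/oracle equality (500+
seeded instances per detector; sequences up to 200 nt, tracks up to 1,000
intervals); BH-FDR equality with the textbook step-up on a seeded grid of
p-vectors up to length 12; the signature algebra (index range, linearity,
weight-zero-equals-removal, rank monotonicity under raw-count increases)
on 1,000 randomized feature tables; end-to-end planted recovery over 20
seeded replicates of the 200/200 scenario (enriched mean index above
desert and ≥90% of enriched sites in the top half); a
methylation-stratified G-quadruplex contrast (planting probability 0.60
vs 0.15, 500 sites per stratum, 100 replicates, two-tailed t-test
p < 0.001); and recovery of a known expression-coupling slope within
±10%.

Null calibration is checked against exact binomial 99% bands around the
nominal rate. The null β distribution is Beta(2, 2) — an
intermediate-methylation site — and the headline calibration check runs at
cohort-scale group sizes (n = 50/50), where a 10^6-trial measurement puts
Welch's true size at α = 0.01 at 0.0102. At very small group sizes the
t-test itself is slightly off-nominal on bounded, non-normal data
(0.0105 at n = 10/10 on Beta(2, 2); 0.003 at n = 10/10 on the extreme
mode Beta(0.5, 5), where the skewed bounded support makes it strongly
conservative). Those deviations are properties of the test, not of the
implementation — the implementation is verified separately by row-wise
equality with `stats::t.test` — so the small-cohort calibration check is
sized (20,000 trials) to have power against implementation errors rather
than against the t-test's own finite-sample behavior.

# Known limitations

* The G4 detector counts canonical motifs only; bulged or two-quartet
  quadruplexes and i-motifs are out of scope, and no thermodynamic
  stability score is computed.
* The shipped shape table is synthetic; `shape` attribute values are only
  biologically meaningful with a real pentamer table.
* Promoter and CpG-island restriction, conserved-TFBS loci and
  alternative-splicing events are consumed as user-supplied BED tracks;
  the package bundles no genome annotation.
* Min–max mapping makes the index sensitive to outliers in a count
  attribute (one extreme window compresses everyone else); inspect the
  stored mapping metadata when a single site dominates an attribute.
* Gene-to-site mapping for expression association is user-supplied; no
  automatic promoter assignment is attempted.
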