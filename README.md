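# methsig

High-throughput methylation studies routinely report thousands of
differentially methylated CpG sites (DMS), most of them in poorly annotated
regions, and give the analyst no principled way to decide which few are
worth following up. `methsig` ranks DMS by the regulatory and structural
potential of their local sequence context, under the working hypothesis
that a methylation change landing on a substrate dense in cis-regulatory
and conformational elements (transcription-factor binding sites, splice
sites, G-quadruplexes, palindromes, methylation-sensitive DNA shape) is
more likely to be functional than one landing in a genomic "desert".

It is aimed at epigenomics analysts who already have a differential
methylation call set (from arrays or bisulfite sequencing) plus a reference
genome, and want a reproducible, configurable prioritization on top of it.

## The model

For *m* sites and *n* sequence-context attributes, each site *x_i* gets a
raw feature vector *a_ij* measured in a fixed window (default 100 nt)
centered on the CpG:

| attribute | raw readout | mapping *m_j* |
|---|---|---|
| `G4` | canonical G-quadruplex motif count | min–max to [0, 1] |
| `Pals` | maximal DNA palindrome count | min–max to [0, 1] |
| `TFBS` | PWM hits over a JASPAR-style motif set | min–max to [0, 1] |
| `cTFBS` | conserved-TFBS track overlaps | min–max to [0, 1] |
| `splicing` | any donor/acceptor hit (Shapiro–Senapathy score ≥ 80) or alternative-splicing-event overlap | logical join |
| `shape` | any pentamer-predicted DNA shape change (MGW, Roll, ProT, HelT) with Wilcoxon p < 0.05 between methylated and unmethylated states | logical join |

The mapped signature matrix A′ = (*a′_ij*) feeds the **genomic index**

    idx_i = Σ_j w_j · a′_ij ,

a weighted sum with non-negative, user-configurable weights (default all 1,
so idx ∈ [0, 6]). Sites are ranked by descending index, ties broken by
|Δβ| and then coordinates. Upstream of this, the package converts and
filters methylation data (β/M conversion, intensity and bisulfite-count
β values, Welch or Mann–Whitney differential test, Benjamini–Hochberg FDR,
default thresholds |Δβ| ≥ 0.3, p < 0.01, FDR < 0.01), and downstream it
provides group-level enrichment statistics and index-vs-expression
association. A seeded synthetic-data generator (random genomes, planted
motifs, bimodal β matrices, coupled expression) makes every stage testable
offline.

## Worked example

```r
library(methsig)

# 1. Simulate a study: 400 CpG sites (200 feature-enriched, 200 desert),
#    10 case + 10 control samples, planted differential methylation
cfg <- sim_config(seed = 42)
sim <- simulate_dataset(cfg)

# 2. Differential filtering at the strict defaults
dms <- differential_filter(sim$beta)
table(dms$status)
#> hyper  hypo
#>   209   191

# 3. 100 nt windows centered at each DMS, then raw features
w <- fetch_windows(sim$genome, dms)
pwms <- lapply(load_jaspar_pfms(system.file("extdata", "motifs_synthetic.jaspar",
                                            package = "methsig")), pfm_to_pwm)
ft <- build_feature_table(w, pwms = pwms, shape_table = synthetic_shape_table(1))

# 4. Signature matrix and equal-weight genomic index
sig <- map_attributes(ft)
ranked <- rank_sites(sig, weight_scheme(), dms = dms)
head(ranked[, c("site_id", "genomic_index", "delta_beta", "rank")])
#>   site_id genomic_index delta_beta rank
#> 1   s0061      4.000000  0.5838634    1
#> 2   s0005      3.666667  0.6770415    2
#> 3   s0086      3.666667 -0.6616142    3
#> 4   s0353      3.666667 -0.6575902    4
#> 5   s0319      3.666667  0.6267895    5
#> 6   s0391      3.666667 -0.6168792    6

# 5. Feature-enriched sites outrank deserts
cls <- sim$sites$class[match(ranked$site_id, sim$sites$site_id)]
tapply(ranked$genomic_index, cls, mean)
#>    desert  enriched
#> 0.6033333 2.6733333
mean(ranked$rank[cls == "enriched"] <= nrow(ranked) / 2)
#> [1] 0.95
```

All 400 planted differential sites pass the strict filter, and sites whose
windows were seeded with regulatory/structural motifs average a genomic
index of 2.67 against 0.60 for desert sites, with 95% of them in the top
half of the ranking — which is exactly what the index is for.

A thin CLI wrapper over the same functions ships in
`inst/scripts/methsig` (`preprocess`, `features`, `rank`, `simulate`
subcommands).

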