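# amplisom

Self-organizing-map clustering of fixed-length amplicon reads, with the
downstream analytics needed for fasting-intervention cohort studies of the
gut microbiota in rheumatoid arthritis (RA): taxonomy assignment and species
frequency tables, Simpson diversity and cohort-specific species filters,
frequency-weighted metabolic pathway scores, cytometric significance
profiles, and DAS28-ESR/SDAI disease-activity scoring with EULAR and SDAI
response classification. A synthetic-data generator with retained ground
truth makes every stage testable end to end.

The package is aimed at analysts working with multi-marker amplicon data
(16S for prokaryotes, ITS/18S for eukaryotes) from small two-group
longitudinal cohorts — here RA patients undergoing bowel cleansing and
fasting against a metabolic-syndrome control group — who need the whole
chain from raw reads to clinical response summaries reproducible from one
seed.

## The method

**Read clustering.** Reads of one sample and marker, trimmed to a fixed
length L = 200 nt and one-hot encoded over {A, C, G, T, N}, are clustered
by a two-dimensional SOM (default 20 × 20, 10,000 training rounds). Node
profiles are position-weight matrices; the distance of read *x* to node *w*
is the soft-Hamming distance

d(x, w) = Σ_p (1 − w[p, x_p]),

which reduces to the integer Hamming distance when *w* is one-hot. Each
cluster is checked for cohesion — the mean pairwise Pearson correlation R
of its members' one-hot encodings, computed through the exact identity
r = 1 − (a/(a−1))·h/L for alphabet size a and Hamming distance h — and
clusters with R < 0.95 are subclustered once in a 10 × 10 map. The member
closest to the cluster average represents the cluster.

**Taxonomy and frequencies.** Representatives are aligned to a local
species reference by optimal local alignment (+1/−1, affine gaps −2/−1);
best hit wins, and clusters whose alignment spans < 200 columns are
dropped. The frequency of species *s* in a sample is the summed size of its
clusters over the summed size of all selected clusters.

**Downstream.** Simpson's D = 1 − Σp², taxonomy rollups,
presence/absence filters for group-specific species, and a BMI correlation
screen; per-sample pathway scores PS(s, pw) = Σ_sp freq(s, sp)·score(sp, pw)
with two-level hierarchy rollups; one-sided paired t, Welch, and exact
Wilcoxon signed-rank tests, combined per cytometric population into a
profile whose *combined score* is the weakest of the three p-values;
DAS28-ESR = 0.56√TJC + 0.28√SJC + 0.70 ln(ESR) + 0.014·GH and
SDAI = TJC + SJC + PGA + EGA + CRP with the standard category, response and
remission thresholds.

## Worked example

Clinical response summary of the packaged 20-patient cohort table:

```r
library(amplisom)
summ <- cohort_summary(read_table1())
summ
#> Cohort of 20 patients
#>   median DAS28 change (last - first): -1.23
#>   median SDAI percent change: -42.5%
#>   improved (DAS28 change < 0): 19 of 20
#>   largest DAS28 decrease: -2.90
#>   DAS28 remission per timepoint: t0=2, t1=3, t2=6, t3=8
#>   SDAI remission at final timepoint: 3
#>   EULAR response: GR=7, MR=9, NR=3, SR=1
#>   SDAI response: MaR=2, MoR=3, MiR=4, none=11
#>   seropositive: RF 12, ACPA 12, either 14
#>   age mean/min/max: 51/22/77
#>   BMI mean/min/max: 25.1/17.2/39.9
```

The median DAS28 improved by 1.23 over the study, 19 of 20 patients
improved, and DAS28 remission (< 2.6) rose from 2 patients at baseline to 8
after breaking the fast. (The EULAR good/moderate tallies follow the
standard response grid; see the methods vignette for the one borderline
patient this reclassifies.)

Recovering a known composition from simulated reads:

```r
ref   <- generate_reference(n_species = 6, amplicon_length = 200,
                            within_genus_divergence = 0.2, seed = 1,
                            eukaryote_fraction = 0)
truth <- setNames(c(0.35, 0.25, 0.2, 0.1, 0.06, 0.04), names(ref$templates))
reads <- simulate_reads(truth, ref, depth = 400, substitution_rate = 0.005,
                        seed = 2, sample_id = "demo")
cl <- cluster_reads(reads, grid = c(8, 8), rounds = 5000, seed = 3)
cl
#> read_clusters: 17 clusters over 400 reads (0 subclustered)
#> cohesion: min 0.967 / median 0.987

freq <- build_frequency_table(assign_clusters(cl, ref))
round(freq_matrix(freq, ref)[1, ], 3)
#> sp001 sp002 sp003 sp004 sp005 sp006
#> 0.332 0.225 0.205 0.110 0.070 0.058
```

The estimated frequencies track the multinomial truth (0.35, 0.25, 0.20,
0.10, 0.06, 0.04) to within sampling error of 400 reads;
`simpson_diversity()` of this sample gives D = 0.776.

The full chain — simulate → cluster → assign → metrics → pathway shifts —
runs from one configuration object:

```r
res <- run_pipeline(pipeline_config(seed = 7), out_dir = "pipeline_out")
```

which writes per-stage TSVs and a manifest with seeds and file hashes;
rerunning the same configuration reproduces byte-identical tables.

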