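---
title: "Methods: SOM read clustering, pathway scores and clinical response analytics"
author: "amplisom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SOM read clustering, pathway scores and clinical response analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`amplisom` implements an analysis chain for fasting-intervention cohort
studies that combine amplicon sequencing of the gut microbiota (16S for
prokaryotes, ITS/18S for eukaryotes), metabolic pathway inference from
species abundances, cytometric population profiling, and composite clinical
disease-activity scores for rheumatoid arthritis (RA) against a metabolic
syndrome (MetS) control group. This vignette documents the models, the
tunable parameters, the synthetic-data generator used for validation, and
the design decisions taken where the method description leaves room.

## Read clustering with a Hamming-distance self-organizing map

Reads of one sample and marker are trimmed to a fixed length (200 nt by
default; shorter reads are discarded and counted, longer reads truncated)
and one-hot encoded over the alphabet {A, C, G, T, N}, one indicator block
per position. Clustering uses a two-dimensional self-organizing map (SOM):

* **Codebook.** Each node of the grid (20 x 20 by default) holds a
  position-weight matrix. Nodes are initialised from reads sampled with
  replacement, so every profile starts one-hot and per-position weights sum
  to 1; the convex update rule preserves this invariant exactly.
* **Distance.** The distance of a read to a node is the *soft Hamming*
  distance `d(read, node) = sum_p (1 - w[p, base(read, p)])`. For a one-hot
  profile this is the integer Hamming distance to the node's consensus
  sequence, which is the property the whole design rests on (and which the
  test suite asserts).
* **Training.** 10,000 rounds by default. A round presents one uniformly
  sampled read, finds the best-matching unit (BMU; ties broken by the
  smallest row-major grid coordinate) and updates all nodes within a
  Gaussian grid neighbourhood: `w <- w + alpha * h * (onehot - w)`. The
  learning rate decays linearly 0.5 to 0.01 and the neighbourhood radius
  from half the larger grid dimension to 0.5. Training-round semantics are
  genuinely ambiguous in this family of methods — "rounds" can mean single
  presentations or full epochs — so both are provided
  (`mode = "presentations"` is the default, `mode = "epochs"` presents
  every read once per round). The schedules themselves are not dictated by
  anything external; they are fixed here, exposed as arguments, and all
  results in the package are reported under the defaults.
* **Cohesion.** Every cluster (non-empty node) is checked for average
  association between its members: the mean pairwise Pearson correlation R
  of the members' one-hot encodings. For one-hot vectors over an alphabet
  of size `a` the pairwise correlation has the exact closed form
  `r = 1 - (a/(a-1)) * h/L`, so cohesion is computed from Hamming distances
  rather than by expanding vectors; the tests verify the identity against
  `cor()` directly. The alphabet is ACGT, extended by N only when N occurs
  among the members — this makes a completely divergent pair score
  `-1/3`, the natural floor for four symbols. Above 10,000 member pairs a
  seeded uniform subsample of 10,000 pairs is used. A singleton cluster has
  R = 1 by convention.
* **Subclustering.** Clusters with R below 0.95 are re-clustered once (no
  recursion) with a fresh SOM on their own members, 10 x 10 grid by
  default; the subclusters replace the parent, so the read partition is
  preserved.
* **Representatives.** Each final cluster is represented by the member
  whose one-hot vector has maximal Pearson correlation with the cluster's
  mean profile; ties go to the smallest read id. All tie-breaks in the
  chain (BMU, representative, best alignment hit) are deterministic, and
  the whole pipeline is reproducible from a single seed.

## Taxonomy assignment and species frequencies

Cluster representatives are aligned against a local reference of species
template sequences by optimal local alignment with affine gaps
(match +1, mismatch -1, gap open -2, gap extend -1 — a conventional
nucleotide-search scoring, configurable). The best-scoring species wins;
ties resolve to the lexicographically smallest species id. Clusters whose
best alignment spans fewer than 200 columns are dropped from downstream
counting and logged. There is deliberately no identity threshold beyond the
length filter; that is a documented caveat of the procedure being
reimplemented, not an oversight. A species' per-sample frequency is the
ratio of the summed sizes of its clusters to the summed sizes of all
filter-passing clusters of that sample, so rows of the frequency table sum
to 1.

Note one interaction worth knowing about: with local alignment, a
substitution error in the terminal position of a read makes the optimal
alignment 199 columns long, so the strict `>= 200` filter drops that
cluster. At the default substitution rate (0.005/base) this affects on the
order of 1% of clusters and is visible in the drop log.

## Community metrics and cohort filters

* Simpson's index of diversity `D = 1 - sum(p^2)` (probability that two
  randomly drawn sequences belong to different species), species richness,
  and taxonomy rollups (phylum/family/genus) that conserve row sums.
* A presence/absence filter for group-specific species: present
  (frequency > 0, exactly — counts are integers upstream, so no
  pseudo-threshold is needed) in at least one target-group sample at the
  target timepoint and absent from every excluded-group sample, with a
  histogram of how many target donors carry each species.
* A BMI correlation screen: Pearson R of species frequency against donor
  BMI at one timepoint, flagging |R| > 0.4. Whether such a screen should
  use frequencies or frequency changes, and at which timepoint, is an open
  choice; it is implemented per-timepoint on frequencies with both the
  timepoint and threshold configurable. A zero-variance species has an
  undefined R; it is reported as 0 and never flagged.
* Per-donor eukaryote scores: the summed frequencies of a given species
  set across a donor's T0 and T3 samples. The differential set is chosen by
  a Welch screen at p < 0.1 (configurable), and the group comparison of the
  summed scores is delegated to the statistics module.

## Pathway scores

Given a species-by-pathway score database (scores in [0, 1], each pathway
annotated with an H1 category — biosynthesis, degradation, energy, other —
and an H2 subcategory), the per-sample pathway score is the
frequency-weighted sum `PS(s, pw) = sum_sp freq(s, sp) * score(sp, pw)`.
Species missing from the database contribute zero and the covered frequency
mass per sample is recorded. PS is linear in frequencies and hierarchy
rollups conserve totals — both are asserted as exact identities in the
tests. Group-level shifts between baseline and post-intervention use a
one-sided paired t-test per category, per group (testing the groups
separately rather than pooled, since the cohorts differ in size and
baseline). The species-level profile pairs each species' change in mean
frequency with its summed score over one H1 category, sorted by the change.

## Statistics

Longitudinal comparisons use a one-sided paired t-test; group comparisons
use Welch's test (two-sided by default, since a sidedness convention for
group contrasts is not self-evident); tender/swollen joint counts call for
the Wilcoxon signed-rank test, exact (signed-rank distribution, equivalent
to full sign enumeration, verified against brute force in the tests) for up
to 25 non-zero differences without ties, and normal approximation with
continuity correction otherwise. One-sided directions must be declared per
analysis; nothing guesses a direction from the data. Pairs with missing
samples are dropped per comparison, never imputed. Raw p-values are
reported without multiple-testing correction, matching the profiling style
this reimplements (a Benjamini-Hochberg option exists but is off by
default).

The per-population significance profile computes, for every cytometric
population, the paired tests baseline vs. each of two follow-up timepoints
within the case group and the Welch test between groups at baseline, and
summarises each population by its *combined score*: the weakest (largest)
of the three p-values. Only a population consistently significant in all
three comparisons can rank highly, which is the point of the construction.
Population fractions can be converted to absolute counts per blood volume
(fraction times the leukocyte count at sampling) before testing.

## Clinical scores

DAS28-ESR uses the standard published coefficients
`0.56*sqrt(TJC28) + 0.28*sqrt(SJC28) + 0.70*ln(ESR) + 0.014*GH`; the
method description names the components but not the coefficients, so the
standard formula is a deliberate (and safe) choice. SDAI is the plain sum
of the joint counts, both global assessments in cm and CRP in mg/dL.
Category boundaries: DAS28 < 2.6 remission, up to 3.2 low, up to 5.1
moderate, above high; SDAI up to 3.3 remission, 11 low, 26 moderate.
SDAI response uses the percent reduction cuts >85 / >70 / >50 for
major/moderate/minor response, with the boundary values themselves falling
into the lower class.

EULAR response follows the standard grid on improvement and attained
level. Two decisions deserve a note:

* The "stable remission" label is restricted to patients already in
  remission at baseline whose grid result would otherwise be "no
  response". This matches the packaged cohort, where the one stable
  patient started below 2.6 and a good responder who reached remission
  keeps the GR label.
* The packaged table labels one patient (improvement 1.09, attained 1.55)
  as a good responder, which the standard grid classifies as moderate
  (improvement must exceed 1.2 for GR). The package follows the standard
  grid and documents the discrepancy rather than bending the rule to
  reproduce that single label; consequently the good/moderate tallies are
  7/9 instead of the printed 8/8, while every other summary count agrees.

RF and ACPA positivity thresholds are not stated anywhere in the packaged
data's source; they were inferred from the data itself (the value 14
recurs as an RF assay floor, hence RF > 14; ACPA >= 17) and are exposed as
arguments. Both reproduce the cohort's printed serology counts. The median
of an even number of patients is the mean of the two central values; the
cohort's median SDAI percent change computes to exactly -42.5, which
prints as -43% under round-half-away-from-zero.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with ground
truth retained for recovery tests (the read-to-species map is stored
alongside the reads but never consumed by any pipeline stage):

* **Reference** (`generate_reference`): template sequences with a
  five-rank taxonomy over the phyla Firmicutes, Bacteroidetes,
  Proteobacteria, Actinobacteria, Verrucomicrobia plus a eukaryote block.
  Within a genus, the founder species carries the genus ancestor sequence
  and each sibling substitutes exactly `round(divergence * length)`
  positions at disjoint sites, giving controlled within-genus distances;
  different genera use independent random templates (expected pairwise
  divergence 0.75).
* **Compositions** (`generate_composition`): sparse Dirichlet base
  compositions per donor, per-phylum T3/T0 multipliers (defaults: 0.6 for
  Firmicutes and Actinobacteria, 1.8 for Bacteroidetes and Verrucomicrobia,
  1.3 for Proteobacteria) emulating the post-fasting shift, designated rare
  RA-specific species at 5e-4 frequency present only in configured RA
  donors at baseline, and a smaller species pool for eukaryote markers.
* **Reads** (`simulate_reads`): multinomial sampling of templates at the
  requested depth with i.i.d. substitution errors. Substitutions only — the
  clustering operates on fixed-length reads, and indels would break the
  positional encoding; this is a documented limitation, not an error model
  claim.
* **Pathway database** (`generate_pathway_db`): uniform scores with a
  phylum bias that lifts biosynthesis scores of Bacteroidetes/Proteobacteria
  and lowers those of Firmicutes/Actinobacteria, so that combined with the
  abundance multipliers the expected qualitative pattern (post-fasting gain
  in biosynthesis capability; increasing Bacteroidetes carrying higher
  scores than decreasing Firmicutes) is recoverable from generated data.
  With bias 0 the scores are independent of phylum.
* **Clinical components and cytometry**
  (`generate_clinical_components`, `generate_cytometry_table`): component
  tables in physiologic ranges with a multiplicative RA improvement effect
  across timepoints, and population fraction tables built from stable
  donor-level profiles (lognormal deviation, sd 0.4) with smaller
  within-donor noise (sd 0.2), one designated population carrying an RA
  baseline deficit that recovers during fasting. The donor-level structure
  matters: it is what makes paired timepoint comparisons informative, as
  in real longitudinal cytometry.

What the generator does *not* emulate: PCR chimeras, primer/barcode
structure, quality-score profiles, paired-end merging, indels,
phylogenetically realistic sequence evolution, overdispersed library
sizes, or batch effects. Passing recovery tests on this generator
therefore demonstrates internal correctness of the pipeline — encoding,
clustering, alignment, counting, and the statistics — under a clean
substitution-error regime, not performance on real MiSeq data.

## Problem sizes and numerical choices

The validation suite and the acceptance script use, as the package's
reference scenario: 20 species at pairwise template divergence >= 0.10,
200 nt amplicons, 2,000 reads per sample at substitution rate 0.005, a
20 x 20 SOM with 10,000 training rounds and 10 x 10 subclustering, and
two samples for the recovery metrics; statistical calibration uses 10,000
simulated null cohorts of 20 donors; cytometric profiling uses 30 donors
and 110 (effect) / 200 (null) populations. Cohesion subsampling caps at
10,000 pairs. Composition and cytometry fractions are renormalised to sum
to 1 within 1e-9; Simpson's index validates its input to 1e-6. Seeds
propagate from a single master seed through a fixed integer derivation, so
every stage is reproducible and no two stages share a stream.

## Known limitations

* The SOM is a heuristic clusterer: node count bounds the number of
  recoverable clusters, and very low-abundance species (below roughly one
  read per node at the default depth) can merge into a neighbour's node.
* The strict 200-column alignment filter drops clusters whose
  representative carries a terminal substitution (about 1% at default
  error rates); frequencies are renormalised over the surviving clusters.
* Cohesion via Pearson correlation of one-hot encodings is one of several
  reasonable readings of "average association between sequences"; the
  member-vs-centroid alternative is not implemented.
* Scores and thresholds inferred from the packaged clinical table (RF/ACPA
  cuts) are conventions, not assay documentation.
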