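Package: amplisom
Title: Self-Organizing Map Clustering of Amplicon Reads with Pathway and
    Clinical Disease-Activity Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters fixed-length 16S/ITS/18S amplicon reads per sample with a
    Hamming-distance self-organizing map, checks cluster cohesion by Pearson
    correlation and subclusters loose clusters, assigns representative sequences
    to a local species reference by optimal local alignment with an
    alignment-length filter, and builds per-sample species frequency tables.
    Downstream analytics cover Simpson diversity, taxonomy rollups,
    cohort-specific species filters, frequency-weighted metabolic pathway
    scores with two-level hierarchy rollups, paired and unpaired group
    statistics with per-population significance profiles, and DAS28-ESR/SDAI
    disease-activity scoring with EULAR and SDAI response classification.
    A synthetic-data generator produces reference sequences, error-bearing
    reads, pathway databases and clinical/cytometric tables with known ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
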