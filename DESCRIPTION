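Package: ampliconcord
Title: Concordance Analysis of OTU and ASV 16S Amplicon Cluster Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing 16S rRNA amplicon feature sets produced by
    different clustering strategies (identity-based OTUs at several cutoffs
    and denoised ASVs) on the same samples. Implements tailored
    relative-abundance and sample-singleton filtering, exact centroid-sequence
    overlap partitions with read-weighted accounting, nearest-neighbour
    nucleotide-difference profiles, greedy identity-clustering resilience
    sweeps, taxonomy-resolution metrics with last-common-ancestor
    attribution, cross-set Spearman correlations, rarefaction-based alpha
    diversity (observed features, Shannon entropy, bias-corrected Chao1),
    beta diversity (Jaccard, Bray-Curtis, weighted and unweighted UniFrac),
    principal coordinate analysis, ANOSIM with pairwise post hoc testing,
    and a ground-truthed synthetic generator of linked cluster sets for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phangorn,
    picante,
    withr
Config/testthat/edition: 3
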