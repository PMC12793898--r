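Package: epimsap
Title: Methylation-Sensitive Amplified Polymorphism (MSAP) Analysis of
    Ecological Epigenetic Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring and analysing methylation-sensitive amplified
    polymorphism (MSAP) fingerprints in ecological studies. Converts
    capillary-electrophoresis peak tables from parallel HpaII/MspI digests
    into binary fragment matrices, classifies CCGG methylation states
    (non-methylated, hemimethylated, internal-cytosine-methylated,
    hypermethylated), partitions methylation-susceptible loci, and
    quantifies epigenetic structure with Shannon diversity, PERMANOVA,
    PERMDISP, principal coordinates analysis, distance-based redundancy
    analysis, RDA variance partitioning, and discriminant analysis of
    principal components. Includes a phenotype-epigenotype plasticity
    coupling statistic based on rank correlation of group centroid
    distances, ecological field metrics (sedimentation rate, nutrient
    status, transect density, caged survival series), and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
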