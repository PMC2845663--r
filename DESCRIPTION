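Package: standscape
Title: Local-Scale Population Genetics of Predominantly Selfing Plant Stands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dense SNP genotype panels sampled from
    spatially structured stands of predominantly self-fertilising annual
    plants. Provides multilocus-genotype identification and stand censuses,
    diversity and inbreeding estimation (expected heterozygosity,
    1-Q interindividual, Weir-Cockerham F-statistics) with size-corrected
    subsampling and locus bootstrap, the F_IS-to-effective-outcrossing
    transform, spatial structure statistics (Mantel test, Moran's I
    correlograms, Gregorius distograms, Clark-Evans aggregation index,
    within-stand transect clustering), detection of outcrossing and
    recombination footprints (identity/divergence mosaic blocks,
    heterozygous stretches, first-generation outcross calls, natural
    recombinant-inbred-line reconstruction), nonparametric clustering with
    gap-statistic cluster-number selection, and a forward-in-time simulator
    of selfing metapopulations with full pedigree truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
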