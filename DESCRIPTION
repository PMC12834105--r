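Package: refugia
Title: Spatial Population Genomics of Post-Glacial Range Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterises the spatial footprint of range expansion out of
    glacial refugia in diploid genomes. Provides per-individual
    heterozygosity, PLINK-style runs of homozygosity with age dating,
    derived-allele genetic-load statistics (Pn/(Pn+Ps), Pn*fn/(Ps*fs),
    loss-of-function dosage), Weir-Cockerham FST with Mantel
    isolation-by-distance tests, variogram estimation and ordinary kriging
    of per-individual statistics, refuge-centre extraction from binary
    presence rasters, and distance-gradient correlation tests with false
    discovery rate control. A forward-in-time serial-founder
    range-expansion simulator generates genotypes, functional annotations,
    sampling coordinates and presence rasters with the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
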