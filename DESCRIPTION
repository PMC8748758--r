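Package: pleioslice
Title: Dissection of GWAS Summary Statistics by a Conditioning Trait
Version: 0.1.0
Authors@R:
    person("Pleioslice", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to dissect one trait's genome-wide association summary
    statistics by their effects in a second, conditioning trait into
    non-associated, sign-concordant and sign-discordant variant partitions,
    and to propagate that dissection through downstream statistical
    genetics: clumping-and-thresholding polygenic scores with Nagelkerke
    pseudo-R2 and liability-scale conversion, stratified LD-score
    regression heritability and enrichment with block-jackknife errors,
    annotation-stratified cross-trait genetic covariance, and a
    bidirectional two-sample Mendelian randomization sensitivity suite
    (IVW, weighted median, Egger, mode estimators, Cochran's Q, MR-PRESSO).
    Includes a synthetic-data generator producing LD-blocked genotype
    panels, two-trait pleiotropic architectures with controllable
    concordant/discordant sharing, GWAS summary statistics and an
    ascertained liability-threshold case-control cohort with known ground
    truth, so every stage can be validated against simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
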