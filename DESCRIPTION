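Package: aneuploidr
Title: Aneuploidy Quantification from Copy-Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quantifying aneuploidy from probe-level copy-number
    log2-ratio data. Segments noisy probe signals with penalized recursive
    binary splitting, computes per-sample aneuploidy scores relative to a
    parental clone and the fraction of genome altered, classifies samples into
    aneuploid-high/low quartile groups, tests per-arm alteration differences
    between genotype groups, correlates chromosome-level copy number with
    average expression (gene dosage), classifies TP53 mutation status from
    MAF-style tables, and stratifies survival by aneuploidy quartile with
    Kaplan-Meier estimation and log-rank tests. Includes a full synthetic-data
    generator (karyotypes with whole-genome doubling and chromothripsis, probe
    signals, expression, mutation tables, survival cohorts, growth curves) so
    every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
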