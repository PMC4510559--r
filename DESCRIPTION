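Package: cnvtrio
Title: Family-Based Benchmarking of Copy-Number Variant Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking copy-number variation (CNV) call sets
    from SNP-array detection software using parent-offspring trios.
    Heterogeneous caller outputs (segment-level or marker-level,
    class-coded or genotype-coded) are standardized into a common segment
    model; offspring CNV predictions are validated in silico against
    parental predictions by class-aware coverage overlap; chance
    validation is quantified by permuting parent-offspring assignments;
    asymmetric predictor/verifier concordance, multi-tool consensus
    regions and external-reference verification are computed.  Includes
    the SNP-array signal transforms (theta, B-allele fraction, log R
    ratio) and a trio/caller simulator with Mendelian transmission,
    population structure and tool-class error profiles, so the whole
    pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
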