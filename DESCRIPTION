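Package: cryptsnp
Title: Encrypted VCF Cohort Compression and Top-K Chi-Squared SNP Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control association screening over compressed and
    encrypted variant files. A simplified 8-column VCF dialect is packed into a
    10-byte-per-SNP binary format, grouped into blocks and sealed with
    AES-128-GCM authenticated encryption. A streaming search engine scans
    control and case cohorts in horizontal (chromosome, position) ranges,
    counts SNP presence in mask-randomized Fibonacci-hashed counter tables,
    ranks variants by the Pearson chi-squared statistic and reports the top-K
    most significant SNPs with p-values from a precomputed-grid trapezoidal
    survival function whose table accesses are input-independent. A synthetic
    cohort generator with planted case/control frequency differences provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    tidyr
SystemRequirements: OpenSSL >= 1.1 (libcrypto)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
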