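Package: cholvar
Title: Rare-Variant Prioritization and Burden Analysis for Cholestasis Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Candidate-gene rare-variant analysis for cholestatic liver
    disease: consequence classification of annotated variants, inclusion
    filtering (minor allele frequency gate plus phenotype, literature,
    cohort-private and in-silico consensus criteria), an ACMG-AMP
    evidence-combining engine with a five-tier verdict, collapsed-carrier
    (CMC) exact burden testing per gene, bidirectional electronic health
    record phenotype-genotype linkage around intrahepatic cholestasis of
    pregnancy, and a Hardy-Weinberg cohort simulator with ground-truth
    bookkeeping for calibration and parameter-recovery studies. Ships
    plain-text fixtures for the five candidate genes (ABCB4, ABCB11,
    ATP8B1, NR1H4, TJP2).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
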