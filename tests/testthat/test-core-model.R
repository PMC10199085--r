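test_that("gene registry houses the five candidates with their products", {
  reg <- gene_registry()
  expect_setequal(reg$symbol, c("ABCB4", "ABCB11", "ATP8B1", "TJP2", "NR1H4"))
  expect_equal(gene_info("ABCB11")$product, "BSEP")
  expect_equal(gene_info("ABCB11")$associated_disease, "PFIC-2")
  expect_equal(gene_info("ATP8B1")$product, "FIC1")
  expect_equal(gene_info("ATP8B1")$associated_disease, "PFIC-1")
  expect_equal(gene_info("ABCB4")$omim_id, 171060L)
  expect_equal(gene_info("ABCB4")$length_kb, 81)
  expect_error(gene_info("BRCA1"), "unknown candidate gene")
})

test_that("read_vcf counts alternate alleles and derives AF over called samples", {
  f <- write_test_vcf(c(vcf_header_line(c("S1", "S2")),
                        vcf_record("1", 100, "ABCB4:X1Y", "A", "G",
                                   c("0/1", "1/1"))))
  gm <- read_vcf(f)
  expect_equal(unname(gm$allele_counts[, 1]), c(1L, 2L))
  expect_equal(unname(variant_af(gm)), 3 / 4)
  expect_equal(gm$meta$gene, "ABCB4")

  # missing genotypes leave both numerator and denominator
  f2 <- write_test_vcf(c(vcf_header_line(c("S1", "S2", "S3")),
                         vcf_record("1", 100, ".", "A", "G",
                                    c("./.", "0/1", "1|1"))))
  gm2 <- read_vcf(f2)
  expect_true(is.na(gm2$allele_counts[1, 1]))
  expect_equal(unname(variant_af(gm2)), 3 / 4)
})

test_that("multiallelic records split into per-alt rows matching a hand-split VCF", {
  gts <- c("1/2", "0/1", "2/2", "0/0")
  f <- write_test_vcf(c(vcf_header_line(paste0("S", 1:4)),
                        vcf_record("1", 100, "rs9", "A", "G,T", gts)))
  gm <- read_vcf(f)
  expect_equal(length(gm$variant_keys), 2)
  expect_equal(gm$variant_keys, c("rs9_alt1", "rs9_alt2"))

  # hand-split: one biallelic record per alternate, non-matching alleles -> 0
  hand1 <- c("0/1", "0/1", "0/0", "0/0")   # allele G
  hand2 <- c("0/1", "0/0", "1/1", "0/0")   # allele T
  fh <- write_test_vcf(c(vcf_header_line(paste0("S", 1:4)),
                         vcf_record("1", 100, "a1", "A", "G", hand1),
                         vcf_record("1", 101, "a2", "A", "T", hand2)))
  gmh <- read_vcf(fh)
  expect_equal(unname(gm$allele_counts), unname(gmh$allele_counts))
})

test_that("an empty VCF body yields a valid zero-variant matrix", {
  f <- write_test_vcf(vcf_header_line(c("S1", "S2")))
  gm <- read_vcf(f)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(dim(gm), c(0L, 0L))
})

test_that("VCF round-trip preserves biallelic genotype content exactly", {
  set.seed(42)
  ac <- matrix(sample(c(0L, 1L, 2L, NA), 60, replace = TRUE), nrow = 10)
  gm <- genotype_matrix(ac, paste0("S", 1:10), paste0("ABCB4:V", 1:6),
                        meta = data.frame(chrom = "7", pos = 1:6 * 10,
                                          ref = "A", alt = "C",
                                          gene = "ABCB4"))
  f <- tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  back <- read_vcf(f)
  expect_equal(unname(back$allele_counts), unname(gm$allele_counts))
  expect_equal(back$variant_keys, gm$variant_keys)
  expect_equal(back$sample_ids, gm$sample_ids)
  # a second write is byte-identical
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("a VCF without GT is rejected, as is a missing file", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
               vcf_header_line("S1"),
               paste(c("1", "100", ".", "A", "G", ".", "PASS", ".", "DP", "7"),
                     collapse = "\t")), f)
  expect_error(read_vcf(f), "GT")
  expect_error(read_vcf(tempfile()), "no such VCF")
})

test_that("carrier and allele tallies follow het + 2*hom arithmetic", {
  # composition printed for the commonest ABCB11 variant: 760 het, 99 hom
  g <- c(rep(1L, 760), rep(2L, 99), rep(0L, 100))
  expect_equal(carrier_and_allele_counts(g),
               c(het_count = 760, hom_count = 99,
                 allele_count = 958, carrier_count = 859))
  expect_equal(carrier_and_allele_counts(integer(0)),
               c(het_count = 0, hom_count = 0,
                 allele_count = 0, carrier_count = 0))
  set.seed(1)
  for (i in 1:5) {
    v <- sample(c(0L, 1L, 2L, NA), 50, replace = TRUE)
    got <- carrier_and_allele_counts(v)
    expect_equal(unname(got["allele_count"]), sum(v, na.rm = TRUE))
    expect_equal(unname(got["carrier_count"]), sum(v >= 1, na.rm = TRUE))
  }
  expect_error(carrier_and_allele_counts(c(0, 3)), "0, 1, 2")
})

test_that("derived AF equals allele_count over twice the called samples", {
  set.seed(7)
  ac <- matrix(sample(c(0L, 1L, 2L, NA), 200, replace = TRUE,
                      prob = c(.6, .2, .1, .1)), nrow = 20)
  gm <- genotype_matrix(ac, paste0("S", 1:20), paste0("V", 1:10))
  af <- variant_af(gm)
  for (j in 1:10) {
    cc <- carrier_and_allele_counts(ac[, j])
    expect_equal(unname(af[j]),
                 cc[["allele_count"]] / (2 * sum(!is.na(ac[, j]))))
  }
})

test_that("annotation reader types records and flags violations", {
  t3 <- chol_fixture("phenotype_variants")
  n510s <- t3[t3$variant_id == "ABCB4:N510S", ]
  expect_equal(n510s$af_gnomad, 0.00019110)
  expect_equal(n510s$af_cohort, 0.00057394)
  expect_true(n510s$literature_known)
  # a cohort-private variant has a missing (not zero) reference AF
  a833t <- t3[t3$variant_id == "ABCB4:A833T", ]
  expect_true(is.na(a833t$af_gnomad))
  expect_false(is.na(a833t$af_cohort))

  f <- tempfile(fileext = ".tsv")
  write_tsv(make_annotation(af_cohort = 1.2), f)
  expect_error(read_annotation_table(f), "af_cohort out of")
  write_tsv(make_annotation(phenotype_groups = "dragonpox"), f)
  expect_error(read_annotation_table(f), "allowed: ICP")
})

test_that("variant identifiers fall back to the cDNA label for splice variants", {
  expect_equal(variant_id("ABCB4", "N510S"), "ABCB4:N510S")
  expect_equal(variant_id("ABCB11", "", "c.2611-2A>T"), "ABCB11:c.2611-2A>T")
  expect_equal(variant_id("ATP8B1", "?-61", "c.182-4_183del"),
               "ATP8B1:c.182-4_183del")
})

test_that("packaged fixtures reproduce the printed tables digit for digit", {
  t2 <- chol_fixture("icp_cases")
  expect_equal(length(unique(t2$volunteer_id)), 15)
  expect_equal(max(t2$highest_tsba), 115)

  raw3 <- readLines(system.file("extdata", "table3_phenotype_variants.tsv",
                                package = "cholvar"))
  # printed AF strings preserved to all printed digits
  expect_true(any(grepl("0.00019110\t0.00057394", raw3, fixed = TRUE)))
  expect_true(any(grepl("0.00026040\t0.00009558", raw3, fixed = TRUE)))
  expect_true(any(grepl("0.0005776\t0.0006719", raw3, fixed = TRUE)))
  expect_equal(nrow(chol_fixture("phenotype_variants")), 50)
  expect_equal(nrow(chol_fixture("lof_variants")), 14)

  # hom/het footnote counts carried through
  t3 <- chol_fixture("phenotype_variants")
  n591s <- t3[t3$variant_id == "ABCB11:N591S", ]
  expect_equal(n591s$het_n, 760)
  expect_equal(n591s$hom_n, 99)
})

test_that("phenotype reader parses lists and rejects negative bile acids", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsex\ticd10\ttsba\ticp_verified",
               "P1\tF\tO26.6;K80.2\t12.5;44\tTRUE",
               "P2\tM\t\t\tFALSE"), f)
  ph <- read_phenotype_table(f)
  expect_equal(ph$icd10_codes[[1]], c("O26.6", "K80.2"))
  expect_equal(ph$highest_tsba, c(44, NA))
  writeLines(c("sample_id\tsex\ticd10\ttsba\ticp_verified",
               "P1\tF\tO26.6\t-3\tTRUE"), f)
  expect_error(read_phenotype_table(f), "negative TSBA")
})
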