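test_that("identical configuration and seed reproduce the cohort bit for bit", {
  cfg <- sim_config(n_samples = 300, seed = 99, genes = c("ABCB4", "TJP2"),
                    n_variants = c(5, 7), prevalence = 0.1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$allele_counts, b$genotypes$allele_counts)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$annotations, b$annotations)
  da <- tempfile(); db <- tempfile()
  pa <- write_cohort(a, da); pb <- write_cohort(b, db)
  expect_identical(unname(tools::md5sum(pa)), unname(tools::md5sum(pb)))
  # a different seed changes the genotypes
  c2 <- simulate_cohort(sim_config(n_samples = 300, seed = 100,
                                   genes = c("ABCB4", "TJP2"),
                                   n_variants = c(5, 7), prevalence = 0.1))
  expect_false(identical(a$genotypes$allele_counts,
                         c2$genotypes$allele_counts))
})

test_that("empirical allele frequencies track the configured spectrum", {
  cfg <- sim_config(n_samples = 4000, seed = 21, genes = "ABCB11",
                    n_variants = 40, prevalence = 0.1)
  sim <- simulate_cohort(cfg)
  emp <- variant_af(sim$genotypes)
  tru <- sim$truth$af
  n2 <- 2 * cfg$n_samples
  sd3 <- 3 * sqrt(tru * (1 - tru) / n2)
  expect_true(all(abs(emp - tru) <= pmax(sd3, 1e-9)))
})

test_that("genotypes follow Hardy-Weinberg proportions at a common allele", {
  cfg <- sim_config(n_samples = 10000, seed = 5, genes = "ABCB4",
                    n_variants = 1, af_range = c(0.3, 0.3), prevalence = 0.1)
  sim <- simulate_cohort(cfg)
  hom_frac <- mean(sim$genotypes$allele_counts[, 1] == 2L)
  se <- sqrt(0.09 * 0.91 / 10000)
  expect_lt(abs(hom_frac - 0.09), 3 * se)
})

test_that("case counts match the configured prevalence within binomial bounds", {
  cfg <- sim_config(seed = 7)    # cohort defaults: n = 5236, 1.54% prevalence
  sim <- simulate_cohort(cfg)
  expected <- 5236 * 0.0154
  bound <- 3 * sqrt(5236 * 0.0154 * (1 - 0.0154))
  expect_lt(abs(sum(sim$truth$case) - expected), bound)
  # cases are female and code-positive; female fraction near target
  expect_true(all(sim$phenotypes$sex[sim$truth$case] == "F"))
  expect_true(all(sim$phenotypes$icd10[sim$truth$case] == "O26.6"))
  expect_lt(abs(mean(sim$phenotypes$sex == "F") - 0.60), 0.02)
  # most measured cases exceed the 10 umol/L diagnostic threshold
  ph <- read_phenotype_table(write_tsv(sim$phenotypes,
                                       tempfile(fileext = ".tsv")))
  case_tsba <- ph$highest_tsba[sim$truth$case]
  expect_gt(mean(case_tsba >= 10, na.rm = TRUE), 0.8)
  ctrl_tsba <- ph$highest_tsba[!sim$truth$case]
  expect_lt(mean(ctrl_tsba >= 10, na.rm = TRUE), 0.2)
})

test_that("carrier fractions in cases equal controls under a null odds ratio", {
  carrier_case <- 0; n_case <- 0; carrier_ctrl <- 0; n_ctrl <- 0
  for (s in 1:60) {
    sim <- simulate_cohort(sim_config(n_samples = 400, seed = 5000 + s,
                                      genes = "ABCB11", n_variants = 10,
                                      prevalence = 0.5))
    carr <- sim$truth$carrier[, "ABCB11"]
    cs <- sim$truth$case
    carrier_case <- carrier_case + sum(carr & cs); n_case <- n_case + sum(cs)
    carrier_ctrl <- carrier_ctrl + sum(carr & !cs); n_ctrl <- n_ctrl + sum(!cs)
  }
  p1 <- carrier_case / n_case; p2 <- carrier_ctrl / n_ctrl
  pool <- (carrier_case + carrier_ctrl) / (n_case + n_ctrl)
  se <- sqrt(pool * (1 - pool) * (1 / n_case + 1 / n_ctrl))
  expect_lt(abs(p1 - p2), 4 * se)
})

test_that("planted co-carrier groups are recovered exactly, never merged", {
  cfg <- sim_config(n_samples = 200, seed = 13, genes = "ATP8B1",
                    n_variants = 12, prevalence = 0.1)
  sim <- simulate_cohort(cfg)
  gm <- sim$genotypes
  k1 <- gm$variant_keys[1:3]; k2 <- gm$variant_keys[4:5]
  gm <- plant_co_carriers(gm, k1, gm$sample_ids[c(3, 50, 70)])
  gm <- plant_co_carriers(gm, k2, gm$sample_ids[c(10, 11)])
  groups <- co_carrier_groups(gm)
  expect_true(any(vapply(groups, identical, logical(1), k1)))
  expect_true(any(vapply(groups, identical, logical(1), k2)))
  # validation
  expect_error(plant_co_carriers(gm, k1[1], "S00001"), "k >= 2")
  expect_error(plant_co_carriers(gm, k1, character(0)), "m >= 1")
  expect_error(plant_co_carriers(gm, k1, "NOPE"), "sample id")
})

test_that("simulated annotation tables are self-consistent and readable", {
  cfg <- sim_config(n_samples = 500, seed = 77, genes = c("ABCB4", "NR1H4"),
                    n_variants = c(8, 6), prevalence = 0.2)
  sim <- simulate_cohort(cfg)
  p <- write_cohort(sim, tempfile())
  ann <- read_annotation_table(p[["annotations"]])
  expect_equal(ann$variant_id, sim$genotypes$variant_keys)
  expect_equal(ann$af_cohort, unname(variant_af(sim$genotypes)))
  # cohort-private rows have no reference AF but a cohort AF
  priv <- is.na(ann$af_gnomad)
  expect_true(any(priv))
  expect_true(all(!is.na(ann$af_cohort[priv])))
  # evidence codes parse and combine for every row
  expect_silent(acmg_verdicts(ann))
})
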