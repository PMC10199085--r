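test_that("exact test reproduces small worked tables", {
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), 0.1)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1.0)
  expect_equal(fisher_exact_2x2(8, 92, 1, 99),
               oracle_fisher_2x2(8, 92, 1, 99))
  expect_error(fisher_exact_2x2(-1, 0, 0, 0), "non-negative")
})

test_that("exact test matches enumeration oracle for all tables with margins <= 8", {
  for (r1 in 0:8) for (r2 in 0:8) for (a in 0:r1) for (cc in 0:r2) {
    p <- fisher_exact_2x2(a, r1 - a, cc, r2 - cc)
    expect_equal(p, oracle_fisher_2x2(a, r1 - a, cc, r2 - cc),
                 tolerance = 1e-10)
    if (r1 > 0 && r2 > 0 && (a + cc) > 0 && (r1 - a + r2 - cc) > 0) {
      ft <- stats::fisher.test(matrix(c(a, cc, r1 - a, r2 - cc), 2))
      expect_equal(p, ft$p.value, tolerance = 1e-7)
    }
  }
})

test_that("two-sided exact p is invariant under transposition and swaps", {
  set.seed(9)
  for (i in 1:40) {
    t <- sample(0:30, 4, replace = TRUE)
    p <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    expect_equal(p, fisher_exact_2x2(t[1], t[3], t[2], t[4]))  # transpose
    expect_equal(p, fisher_exact_2x2(t[3], t[4], t[1], t[2]))  # row swap
    expect_equal(p, fisher_exact_2x2(t[2], t[1], t[4], t[3]))  # column swap
  }
})

test_that("carrier collapse is an OR over qualifying variants", {
  ac <- cbind(v1 = c(0L, 1L, 2L, 0L))
  gm <- genotype_matrix(ac, paste0("S", 1:4), "ABCB4:v1",
                        meta = data.frame(chrom = "7", pos = 1, ref = "A",
                                          alt = "G", gene = "ABCB4"))
  carriers <- collapse_carriers(gm, "ABCB4",
                                burden_config(af_threshold = 0.5))
  expect_equal(as.vector(carriers), c(FALSE, TRUE, TRUE, FALSE))

  # a second variant carried only by an existing carrier changes nothing
  ac2 <- cbind(ac, v2 = c(0L, 1L, 0L, 0L))
  gm2 <- genotype_matrix(ac2, paste0("S", 1:4), c("ABCB4:v1", "ABCB4:v2"),
                         meta = data.frame(chrom = "7", pos = 1:2, ref = "A",
                                           alt = "G", gene = "ABCB4"))
  carriers2 <- collapse_carriers(gm2, "ABCB4",
                                 burden_config(af_threshold = 0.5))
  expect_equal(as.vector(carriers2), as.vector(carriers))

  # frequency gate: a variant above the threshold is not collapsed
  cfg <- burden_config(af_threshold = 0.01)
  af <- c(0.02, 0.005)
  carriers3 <- collapse_carriers(gm2, "ABCB4",
                                 burden_config(af_threshold = 0.01,
                                               af_source = "annotation"),
                                 annotation_af = af)
  expect_equal(attr(carriers3, "n_variants"), 1L)
  expect_equal(as.vector(carriers3), c(FALSE, TRUE, FALSE, FALSE))

  # no qualifying variant is a signal, not a p-value
  empty <- collapse_carriers(gm, "ABCB4",
                             burden_config(af_threshold = 0.01,
                                           af_source = "annotation"),
                             annotation_af = 0.4)
  expect_true(is_empty_collapse(empty))
})

test_that("cmc_exact builds the carrier table and matches direct recomputation", {
  cfg <- calibration_config(seed = 101)
  sim <- simulate_cohort(cfg)
  res <- cmc_exact(sim$genotypes, "ABCB11", sim$truth$case)
  expect_s3_class(res, "burden_result")
  # margins equal group sizes
  expect_equal(sum(res$table[, "case"]), sum(sim$truth$case))
  expect_equal(sum(res$table[, "control"]), sum(!sim$truth$case))
  # direct recomputation from raw genotypes and the enumeration oracle
  af <- variant_af(sim$genotypes)
  qual <- af <= 0.01
  carrier <- rowSums(sim$genotypes$allele_counts[, qual, drop = FALSE] >= 1) > 0
  a <- sum(carrier & sim$truth$case); b <- sum(carrier & !sim$truth$case)
  c2 <- sum(!carrier & sim$truth$case); d <- sum(!carrier & !sim$truth$case)
  expect_equal(unname(res$table[1, ]), c(a, b))
  expect_equal(res$p_value, oracle_fisher_2x2(a, b, c2, d), tolerance = 1e-12)

  expect_error(cmc_exact(sim$genotypes, "ABCB11",
                         rep(TRUE, length(sim$genotypes$sample_ids))),
               "control")
})

test_that("burden result is unchanged by a nested-carrier variant and empty on no carriers", {
  set.seed(31)
  ac <- cbind(v1 = rbinom(200, 1, 0.05))
  ac <- cbind(ac, v2 = ifelse(ac[, 1] == 1 & runif(200) < 0.5, 1L, 0L))
  gm <- genotype_matrix(ac, paste0("S", 1:200), c("ABCB4:v1", "ABCB4:v2"),
                        meta = data.frame(chrom = "7", pos = 1:2, ref = "A",
                                          alt = "G", gene = "ABCB4"))
  cases <- rep(c(TRUE, FALSE), each = 100)
  both <- cmc_exact(gm, "ABCB4", cases, burden_config(af_threshold = 0.5))
  gm1 <- genotype_matrix(ac[, 1, drop = FALSE], paste0("S", 1:200),
                         "ABCB4:v1",
                         meta = data.frame(chrom = "7", pos = 1, ref = "A",
                                           alt = "G", gene = "ABCB4"))
  only1 <- cmc_exact(gm1, "ABCB4", cases, burden_config(af_threshold = 0.5))
  expect_equal(both$table, only1$table)
  expect_equal(both$p_value, only1$p_value)

  none <- genotype_matrix(matrix(0L, 200, 1), paste0("S", 1:200), "ABCB4:v0",
                          meta = data.frame(chrom = "7", pos = 1, ref = "A",
                                            alt = "G", gene = "ABCB4"))
  expect_true(is_empty_collapse(
    cmc_exact(none, "ABCB4", cases, burden_config(af_threshold = 0.5))))
})

test_that("cohort variant comparison is an exact test on count proportions", {
  expect_equal(cohort_variant_comparison(2, 10, 2, 10)$p_value, 1.0)
  expect_equal(cohort_variant_comparison(9, 10, 1, 10)$p_value,
               oracle_fisher_2x2(9, 1, 1, 9))
  expect_equal(cohort_variant_comparison(0, 5, 5, 5)$p_value,
               oracle_fisher_2x2(0, 5, 5, 0))
  expect_error(cohort_variant_comparison(6, 5, 1, 10), "k <= n")
})

test_that("co-carrier grouping recovers identical carrier sets only", {
  n <- 30
  ac <- matrix(0L, n, 5,
               dimnames = list(NULL, paste0("ATP8B1:v", 1:5)))
  ac[c(3, 9, 20), 1:3] <- 1L        # the planted trio of co-carried variants
  ac[5, 4] <- 1L; ac[6, 5] <- 1L    # disjoint singletons
  gm <- genotype_matrix(ac, paste0("S", 1:n), colnames(ac),
                        meta = data.frame(chrom = "18", pos = 1:5, ref = "A",
                                          alt = "G", gene = "ATP8B1"))
  groups <- co_carrier_groups(gm)
  expect_length(groups, 1)
  expect_equal(groups[[1]], paste0("ATP8B1:v", 1:3))

  # all-disjoint carriers -> no group; duplicated column -> grouped
  ac2 <- diag(3L); colnames(ac2) <- paste0("V", 1:3)
  gm2 <- genotype_matrix(ac2, paste0("S", 1:3), colnames(ac2))
  expect_length(co_carrier_groups(gm2), 0)
  ac3 <- cbind(ac2, V4 = ac2[, 2])
  gm3 <- genotype_matrix(ac3, paste0("S", 1:3), colnames(ac3))
  expect_equal(co_carrier_groups(gm3), list(c("V2", "V4")))
})
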