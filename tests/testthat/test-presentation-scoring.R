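test_that("HLA genotypes require six slots, two per locus, well-formed names", {
  g <- toy_genotype()
  expect_s3_class(g, "hla_genotype")
  expect_error(hla_genotype(c("A*02:01", "A*01:01", "B*07:02", "B*08:01", "C*07:01")),
               class = "arity_error")
  expect_error(hla_genotype(c("A*02:01", "A*01:01", "A*03:01", "B*08:01",
                              "C*07:01", "C*04:01")), class = "arity_error")
  expect_error(hla_genotype(c("A*02:01", "A*01:01", "B*07:02", "B*08:01",
                              "C*07:01", "D*04:01")), class = "parse_error")
  expect_error(validate_hla_allele("A02:01"), class = "parse_error")
})

test_that("the harmonic mean reproduces its closed form and respects bounds", {
  expect_equal(phbr(rep(0.5, 6)), 0.5)
  expect_equal(phbr(c(0.1, 0.5, 1, 2, 4, 8)), 6 / 13.875, tolerance = 1e-12)
  expect_error(phbr(rep(1, 5)), class = "arity_error")
  expect_error(phbr(c(-1, 1, 1, 1, 1, 1)), class = "domain_error")

  set.seed(21)
  for (i in 1:200) {
    br <- stats::rlnorm(6, 0, 2)
    v <- phbr(br)
    expect_gte(v, min(br))
    expect_lte(v, max(br))
    expect_lte(v, 6 * min(br) + 1e-12)
    # monotone: decreasing any single rank never increases PHBR
    j <- sample(6, 1)
    br2 <- br
    br2[j] <- br2[j] * stats::runif(1, 0.1, 0.99)
    expect_lte(phbr(br2), v + 1e-12)
  }
})

test_that("best rank is the minimum over unique peptides", {
  o <- toy_oracle(rep("A*02:01", 3), c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
                  c(5.0, 0.3, 12.0))
  expect_equal(best_rank(o, "A*02:01", c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD")), 0.3)
  # duplicated sequences are collapsed before lookup
  expect_equal(best_rank(o, "A*02:01",
                         c("AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC")), 0.3)
  expect_equal(best_rank(constant_oracle(2), "A*02:01", random_peptides(38)), 2.0)
  expect_error(best_rank(o, "A*02:01", character(0)), class = "empty_input")
})

test_that("mutation PHBR composes per-slot best ranks; homozygotes count twice", {
  peps <- random_peptides(5)
  hom <- hla_genotype(rep(c("A*02:01", "B*07:02", "C*07:01"), each = 2))
  s <- mutation_phbr(constant_oracle(3.7), hom, peps)
  expect_equal(s$value, 3.7)
  expect_length(s$per_allele_best_ranks, 6L)
  expect_error(mutation_phbr(constant_oracle(1),
                             c("A*02:01", "A*01:01", "B*07:02", "B*08:01", "C*07:01"),
                             peps),
               class = "arity_error")
})

test_that("mutation PHBR equals a brute-force slot-by-peptide evaluation", {
  set.seed(33)
  for (i in 1:200) {
    oracle <- synthetic_rank_oracle(seed = i, strong_binder_fraction = 0.15)
    g <- random_genotype()
    peps <- unique(random_peptides(sample(3:12, 1)))
    got <- mutation_phbr(oracle, g, peps)$value
    # independent path: flat double loop then the explicit reciprocal sum
    br <- numeric(6)
    for (slot in 1:6) {
      best <- Inf
      for (p in peps) best <- min(best, oracle_rank(oracle, unclass(g)[slot], p))
      br[slot] <- max(best, 1e-6)
    }
    expect_equal(got, 6 / sum(1 / br), tolerance = 1e-12)
  }
})

test_that("the synthetic oracle is deterministic with the configured strong fraction", {
  o1 <- synthetic_rank_oracle(5, 0.1)
  o2 <- synthetic_rank_oracle(5, 0.1)
  peps <- random_peptides(50)
  expect_identical(oracle_rank(o1, "A*02:01", peps), oracle_rank(o2, "A*02:01", peps))
  expect_identical(oracle_rank(o1, "A*02:01", peps), oracle_rank(o1, "A*02:01", peps))
  # different seed, different ranks
  expect_false(identical(oracle_rank(synthetic_rank_oracle(6, 0.1), "A*02:01", peps),
                         oracle_rank(o1, "A*02:01", peps)))

  expect_true(all(oracle_rank(synthetic_rank_oracle(1, 0), "B*07:02",
                              random_peptides(300)) >= 0.5))

  set.seed(8)
  many <- random_peptides(10000)
  frac <- mean(oracle_rank(synthetic_rank_oracle(2, 0.1), "A*02:01", many) < 0.5)
  half_width <- stats::qnorm(0.995) * sqrt(0.1 * 0.9 / 10000)
  expect_gt(frac, 0.1 - half_width)
  expect_lt(frac, 0.1 + half_width)
})

test_that("per-allele effects shift the strong-binder fraction for that allele", {
  set.seed(9)
  peps <- random_peptides(4000)
  o <- synthetic_rank_oracle(3, 0.1, allele_effects = c("B*07:02" = 0.2))
  f_shift <- mean(oracle_rank(o, "B*07:02", peps) < 0.5)
  f_base <- mean(oracle_rank(o, "A*02:01", peps) < 0.5)
  expect_gt(f_shift, f_base + 0.1)
})

test_that("the patient minimum selects the best-presented mutation, first on ties", {
  expect_equal(patient_min_phbr(c(0.4, 2.3))$value, 0.4)
  expect_equal(patient_min_phbr(7.7)$value, 7.7)
  tie <- patient_min_phbr(c(0.7, 0.7), variants = c("v1", "v2"))
  expect_identical(tie$index, 1L)
  expect_identical(tie$variant, "v1")
  expect_error(patient_min_phbr(numeric(0)), class = "patient_not_evaluable")
})

test_that("rank tables load, reject ambiguity, and flag missing predictions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# precomputed predictor output",
               "allele\tpeptide\trank_percentile",
               "A*02:01\tAAAAAAAAA\t5.0",
               "A*02:01\tCCCCCCCCC\t0.3",
               "B*07:02\tAAAAAAAAA\t12.0"), path)
  o <- load_rank_table(path)
  expect_equal(oracle_rank(o, "A*02:01", "CCCCCCCCC"), 0.3)
  expect_error(oracle_rank(o, "B*07:02", "CCCCCCCCC"), class = "missing_prediction")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("allele\tpeptide\trank_percentile",
               "A*02:01\tAAAAAAAAA\t5.0",
               "A*02:01\tAAAAAAAAA\t6.0"), dup)
  expect_error(load_rank_table(dup), class = "parse_error")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("allele\tpeptide\trank_percentile",
               "A*02:01\tAAAAAAAAA\tstrong"), bad)
  expect_error(load_rank_table(bad), class = "parse_error")
})

test_that("binder classes follow the conventional rank thresholds", {
  expect_identical(binder_class(c(0.49, 0.5, 1.99, 2, 50)),
                   c("strong", "weak", "weak", "non-binder", "non-binder"))
})
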