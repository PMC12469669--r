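test_that("allele-count and heterozygosity statistics match hand values", {
  expect_equal(n_alleles_observed(c(0.75, 0.25)), 2)
  expect_equal(n_alleles_observed(1), 1)
  expect_equal(n_alleles_observed(rep(0.1, 10)), 10)

  expect_equal(n_alleles_effective(c(0.5, 0.5)), 2)
  expect_equal(n_alleles_effective(c(0.75, 0.25)), 1.6)
  expect_equal(n_alleles_effective(1), 1)

  expect_equal(expected_het(c(0.5, 0.5)), 0.5)
  expect_equal(expected_het(c(0.5, 0.5), n_genes = 20, unbiased = TRUE),
               20 / 19 * 0.5)
  expect_equal(expected_het(1), 0)
  expect_error(expected_het(c(0.5, 0.5), unbiased = TRUE), "n_genes")

  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(1), 0)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
})

test_that("PIC and He match brute-force double-loop oracles and inequalities", {
  withr::with_seed(42, {
    for (i in 1:200) {
      p <- random_spectrum(sample(2:12, 1))
      expect_equal(pic(p), pic_oracle(p), tolerance = 1e-12)
      expect_equal(expected_het(p), he_oracle(p), tolerance = 1e-12)
      expect_lte(pic(p), expected_het(p))
      expect_lte(expected_het(p), 1 - 1 / length(p) + 1e-12)
      expect_lt(n_alleles_effective(p), length(p))  # never equifrequent
    }
  })
  # Ne = No exactly iff equifrequent
  expect_equal(n_alleles_effective(rep(1 / 6, 6)), 6, tolerance = 1e-12)
})

test_that("observed heterozygosity counts typed individuals only", {
  g <- make_geno(list(c(100, 120), c(100, 102), c(104, 120), c(100, 100)))
  expect_equal(observed_het(g)$Ho, 0.75)
  all_hom <- make_geno(list(c(100, 100), c(102, 102)))
  expect_equal(observed_het(all_hom)$Ho, 0)
  with_missing <- make_geno(list(c(100, 120), c(NA, NA), c(100, 100)))
  expect_equal(observed_het(with_missing)$Ho, 0.5)
  expect_equal(observed_het(with_missing)$n_typed, 2L)
})

test_that("Ho and He are invariant under allele and individual relabeling", {
  g <- make_geno(list(c(100, 120), c(120, 140), c(100, 100), c(140, 140)))
  base <- diversity_stats(g)
  shifted <- g
  shifted$allele_a <- g$allele_a + 60L   # relabel alleles
  shifted$allele_b <- g$allele_b + 60L
  shifted <- shifted[sample(nrow(shifted)), ]  # reorder individuals
  shifted$individual <- paste0("x", shifted$individual)
  re <- diversity_stats(shifted)
  expect_equal(re[, c("Ho", "He", "PIC", "No", "Ne")],
               base[, c("Ho", "He", "PIC", "No", "Ne")])
})

test_that("per-locus F follows 1 - Ho/He with monomorphic loci undefined", {
  het_rich <- make_geno(list(c(100, 120), c(100, 120), c(100, 120),
                             c(100, 100)))
  d <- diversity_stats(het_rich, unbiased = FALSE)
  expect_equal(d$F, 1 - d$Ho / d$He)
  expect_lt(d$F, 0)  # heterozygote excess scores negative

  mono <- make_geno(list(c(100, 100), c(100, 100)))
  dm <- diversity_stats(mono)
  expect_equal(dm$No, 1)
  expect_equal(dm$Ne, 1)
  expect_equal(dm$He, 0)
  expect_equal(dm$PIC, 0)
  expect_true(is.na(dm$F))
})

test_that("breed summaries use the n-1 SE convention over loci", {
  g <- make_geno_multi(
    list(c(100, 120), c(100, 120), c(100, 100), c(120, 120), c(100, 120)),
    list(c(100, 120), c(100, 120), c(100, 120), c(100, 100), c(100, 100))
  )
  per_locus <- diversity_stats(g)
  expect_equal(sort(per_locus$Ho), c(0.6, 0.6))
  summ <- diversity_summary(g)
  expect_equal(summ$loci_used, 2L)
  expect_equal(summ$Ho_mean, 0.6)

  # two loci with Ho 0.4 and 0.6 -> SE = sd(c(.4,.6))/sqrt(2) = 0.1
  g2 <- make_geno_multi(
    list(c(100, 120), c(100, 120), c(100, 100), c(100, 100), c(100, 100)),
    list(c(100, 120), c(100, 120), c(100, 120), c(100, 100), c(100, 100))
  )
  s2 <- diversity_summary(g2)
  expect_equal(s2$Ho_mean, 0.5)
  expect_equal(s2$Ho_se, 0.1)

  # single locus: mean defined, SE undefined
  s1 <- diversity_summary(make_geno(list(c(100, 120), c(100, 100))))
  expect_true(is.na(s1$Ho_se))
})

test_that("the seven-breed summary has one row and full columns per breed", {
  g <- simulate_genotypes(seed = 303, n_loci = 5)
  summ <- diversity_summary(g)
  expect_equal(nrow(summ), 7)
  expect_setequal(summ$population,
                  c("BB", "WB", "RB", "JAB", "NZW", "AR", "CH"))
  expect_true(all(c("No_mean", "No_se", "Ne_mean", "Ho_mean", "He_mean",
                    "PIC_mean", "F_mean", "F_ratio") %in% names(summ)))
  expect_true(all(summ$Ne_mean <= summ$No_mean + 1e-12))
  expect_true(all(summ$PIC_mean <= summ$He_mean + 1e-12))
})
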