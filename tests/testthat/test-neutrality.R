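test_that("unsigned Stirling numbers satisfy the defining recurrence", {
  expect_equal(stirling1_unsigned(4, 2), 11)
  expect_equal(stirling1_unsigned(0, 0), 1)
  expect_equal(stirling1_unsigned(3, 5), 0)
  for (n in 2:12) {
    for (k in 1:n) {
      expect_equal(stirling1_unsigned(n, k),
                   stirling1_unsigned(n - 1, k - 1) +
                     (n - 1) * stirling1_unsigned(n - 1, k),
                   info = paste(n, k))
    }
  }
  # row sums are n! (permutations counted by cycle number)
  expect_equal(sum(vapply(0:6, function(k) stirling1_unsigned(6, k),
                          numeric(1))), factorial(6))
})

test_that("partition counting and enumeration agree", {
  expect_equal(msatpop:::count_partitions(4, 2), 2)
  expect_equal(msatpop:::count_partitions(10, 3), 8)
  for (n in c(6, 9, 13)) {
    for (k in 2:(n - 1)) {
      parts <- msatpop:::enumerate_partitions(n, k)
      expect_equal(length(parts), msatpop:::count_partitions(n, k))
      expect_true(all(vapply(parts, sum, numeric(1)) == n))
      expect_true(all(vapply(parts, length, integer(1)) == k))
      expect_true(all(vapply(parts, function(p) all(diff(p) <= 0),
                             logical(1))))
    }
  }
})

test_that("the exact (4,2) null reproduces the enumerated distribution", {
  nl <- ewens_null(4, 2, method = "exact")
  expect_equal(sort(nl$partitions$prob), sort(c(3 / 11, 8 / 11)),
               tolerance = 1e-12)
  expect_equal(nl$mean, 6.5 / 11, tolerance = 1e-12)
  # normaliser of the partition weights is the Stirling number itself
  lw <- vapply(nl$partitions$partition, msatpop:::esf_log_weight, numeric(1))
  expect_equal(sum(exp(lw)), stirling1_unsigned(4, 2), tolerance = 1e-9)
})

test_that("exact null probabilities sum to one and moments match paths", {
  for (nk in list(c(8, 3), c(12, 5), c(20, 4), c(15, 14))) {
    en <- ewens_null(nk[1], nk[2], method = "exact")
    expect_equal(sum(en$partitions$prob), 1, tolerance = 1e-12)
    mo <- ewens_null(nk[1], nk[2], method = "auto")
    expect_equal(mo$mean, en$mean, tolerance = 1e-10)
    expect_lt(abs(mo$sd - en$sd), 1e-8)
  }
})

test_that("degenerate allele counts give spreadless nulls", {
  k1 <- ewens_null(10, 1)
  expect_equal(k1$mean, 1)
  expect_equal(k1$sd, 0)
  kn <- ewens_null(10, 10)
  expect_equal(kn$mean, 0.1)
  expect_equal(kn$sd, 0)
  expect_error(ewens_null(4, 5), "k <= n")
})

test_that("expected homozygosity decreases in allele count at fixed n", {
  ef <- vapply(2:10, function(k) ewens_null(30, k)$mean, numeric(1))
  expect_true(all(diff(ef) < 0))
})

test_that("Monte Carlo agrees with exact moments and respects its contract", {
  mc <- ewens_null(12, 4, method = "monte_carlo", reps = 5000, seed = 99)
  ex <- ewens_null(12, 4, method = "exact")
  expect_lt(abs(mc$mean - ex$mean), 4 * ex$sd / sqrt(5000))
  # reproducible under the same seed
  mc2 <- ewens_null(12, 4, method = "monte_carlo", reps = 5000, seed = 99)
  expect_identical(mc$mean, mc2$mean)
  expect_error(ewens_null(12, 4, method = "monte_carlo", reps = 5000), "seed")
  expect_error(ewens_null(12, 4, method = "monte_carlo", reps = 10, seed = 1),
               "1000")
  # exact budget overflow falls back with a warning
  expect_warning(
    big <- ewens_null(60, 6, method = "exact", reps = 2000, seed = 3,
                      exact_budget = 100),
    "Monte Carlo")
  expect_equal(big$method, "monte_carlo")
})

test_that("observed homozygosity is the squared-frequency sum", {
  expect_equal(observed_homozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(observed_homozygosity(1), 1)
  expect_equal(observed_homozygosity(c(0.75, 0.25)), 0.625)
})

test_that("neutrality deviates centre, orient and respect undefined cells", {
  # two individuals, alleles (2,2): n = 4, k = 2, F_obs = 0.5
  g <- make_geno(list(c(100, 102), c(100, 102)))
  nt <- neutrality_test(g)
  ex <- ewens_null(4, 2, method = "exact")
  expect_equal(nt$F_obs, 0.5)
  expect_equal(nt$D, (ex$mean - 0.5) / ex$sd, tolerance = 1e-12)
  expect_gt(nt$D, 0)  # even, allele-rich spectrum scores positive
  flipped <- neutrality_test(g, sign = -1)
  expect_equal(flipped$D, -nt$D)

  # F_obs equal to the null mean centres at D = 0 by construction
  expect_equal((ex$mean - ex$mean) / ex$sd, 0)

  mono <- make_geno(list(c(100, 100), c(100, 100)))
  expect_true(is.na(neutrality_test(mono)$D))
})

test_that("D is invariant under allele relabeling", {
  g <- make_geno(list(c(100, 104), c(100, 100), c(104, 108)))
  base <- neutrality_test(g)
  shifted <- g
  shifted$allele_a <- g$allele_a + 50L
  shifted$allele_b <- g$allele_b + 50L
  expect_equal(neutrality_test(shifted)$D, base$D)
})

test_that("the neutrality matrix mirrors undefined cells and breed means", {
  g <- dplyr::bind_rows(
    make_geno_multi(list(c(100, 102), c(100, 102), c(102, 102)),
                    list(c(100, 100), c(100, 100), c(100, 100)),
                    population = "A"),
    dplyr::mutate(
      make_geno_multi(list(c(100, 100), c(100, 102), c(102, 102)),
                      list(c(100, 102), c(100, 100), c(100, 102)),
                      population = "B"),
      individual = paste0("b_", individual))
  )
  nt <- neutrality_test(g)
  tab <- neutrality_table(nt)
  expect_true(is.na(tab$matrix$A[tab$matrix$locus == "L2"]))
  a_summary <- tab$summary[tab$summary$population == "A", ]
  expect_equal(a_summary$n_defined, 1L)
  expect_equal(a_summary$mean, nt$D[nt$population == "A" & nt$locus == "L1"])
  b_mean <- mean(nt$D[nt$population == "B"])
  expect_equal(tab$summary$mean[tab$summary$population == "B"], b_mean)
})
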