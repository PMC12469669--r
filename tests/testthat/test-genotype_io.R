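test_that("CSV genotype tables parse, with missing cells kept as missing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,population,LocA,LocB",
               "i1,P1,100/100,140/150",
               "i2,P1,100/120,",
               "i3,P2,120/100,150/150"), f)
  g <- suppressMessages(read_genotypes(f, "csv"))
  expect_equal(nrow(g), 6)
  loca <- g[g$locus == "LocA", ]
  expect_equal(sort(unique(c(loca$allele_a, loca$allele_b))), c(100L, 120L))
  # unphased: "120/100" stored ascending
  expect_equal(g$allele_a[g$individual == "i3" & g$locus == "LocA"], 100L)
  # empty cell -> both alleles missing, row preserved
  miss <- g[g$individual == "i2" & g$locus == "LocB", ]
  expect_true(is.na(miss$allele_a) && is.na(miss$allele_b))
})

test_that("malformed cells and duplicate ids raise named parse errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,population,LocA", "i1,P1,100/abc"), f)
  expect_error(suppressMessages(read_genotypes(f, "csv")), "line 2")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,population,LocA", "i1,P1,100/100",
               "i1,P1,100/120"), f2)
  expect_error(suppressMessages(read_genotypes(f2, "csv")), "duplicate")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,population,LocA", "i1,P1,100"), f3)
  expect_error(suppressMessages(read_genotypes(f3, "csv")), "malformed")
})

test_that("GenePop files parse with Pop separators and 0 = missing", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("two pops, two loci", "LocA", "LocB",
               "Pop", "a1 ,  100102 000000",
               "Pop", "b1 ,  102102 140140"), f)
  g <- suppressMessages(read_genotypes(f, "genepop"))
  expect_equal(length(unique(g$population)), 2)
  expect_equal(g$allele_a[g$individual == "a1" & g$locus == "LocA"], 100L)
  expect_true(is.na(g$allele_a[g$individual == "a1" & g$locus == "LocB"]))
  # 2-digit coding also accepted
  f2 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "LocA", "Pop", "x1 ,  0912"), f2)
  g2 <- suppressMessages(read_genotypes(f2, "genepop"))
  expect_equal(c(g2$allele_a, g2$allele_b), c(9L, 12L))
  # malformed coding names the line
  f3 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "LocA", "Pop", "x1 ,  10012"), f3)
  expect_error(suppressMessages(read_genotypes(f3, "genepop")), "coding")
})

test_that("write/read round trips are bit-exact in both formats", {
  g <- simulate_genotypes(populations = c(A = 8, B = 6), n_loci = 4,
                          missing_rate = 0.1, seed = 7)
  by_call <- function(x) {
    dplyr::arrange(x[, c("individual", "locus", "allele_a", "allele_b")],
                   individual, locus)
  }
  for (fmt in c("csv", "genepop")) {
    f <- withr::local_tempfile()
    write_genotypes(g, f, format = fmt)
    back <- suppressMessages(read_genotypes(f, format = fmt))
    expect_equal(by_call(back), by_call(g), info = fmt)
  }
})

test_that("allele frequencies count two genes per typed individual", {
  g <- make_geno(list(c(100, 100), c(100, 120)))
  af <- allele_freqs(g)
  expect_equal(af$freq[af$allele == 100], 0.75)
  expect_equal(af$freq[af$allele == 120], 0.25)
  expect_equal(unique(af$n_genes), 4L)

  mono <- allele_freqs(make_geno(list(c(100, 100), c(100, 100))))
  expect_equal(mono$freq, 1)

  hets <- allele_freqs(make_geno(list(c(100, 120), c(120, 140), c(100, 140))))
  expect_equal(hets$freq, rep(1 / 3, 3))
  expect_equal(unique(hets$n_genes), 6L)
})

test_that("spectra conserve frequency mass and ignore missing calls", {
  g <- simulate_genotypes(populations = c(A = 20, B = 15), n_loci = 5,
                          missing_rate = 0.15, seed = 21)
  af <- allele_freqs(g)
  sums <- af |>
    dplyr::group_by(population, locus) |>
    dplyr::summarise(s = sum(freq), n = n_genes[1], .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  typed <- g[!is.na(g$allele_a), ] |>
    dplyr::count(population, locus)
  expect_equal(sort(sums$n), sort(2L * typed$n))

  # adding a missing call changes no spectrum
  extra <- tibble::tibble(individual = "zz", population = "A", locus = "L01",
                          allele_a = NA_integer_, allele_b = NA_integer_)
  af2 <- allele_freqs(dplyr::bind_rows(g, extra))
  expect_equal(af2, af)
})

test_that("a population x locus cell with no data errors distinctly", {
  g <- make_geno(list(c(NA, NA), c(NA, NA)))
  expect_error(allele_freqs(g), "no typed")
  g2 <- dplyr::bind_rows(make_geno(list(c(100, 102))),
                         make_geno(list(c(NA, NA)), population = "P2",
                                   ids = "j1"))
  af <- allele_freqs(g2)
  expect_error(msatpop:::spectrum_for(af, "P2", "L1"),
               class = "msatpop_no_data")
})

test_that("half-missing and multi-population individuals are rejected", {
  bad <- tibble::tibble(individual = "i1", population = "P1", locus = "L1",
                        allele_a = 100L, allele_b = NA_integer_)
  expect_error(msatpop:::as_genotypes(bad), "half-missing")
  two_pop <- dplyr::bind_rows(
    make_geno(list(c(100, 100)), population = "P1", ids = "i1"),
    make_geno(list(c(100, 100)), population = "P2", locus = "L2", ids = "i1"))
  expect_error(msatpop:::as_genotypes(two_pop), "more than one population")
})
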