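# Compact genotype-table builder: calls is a list of c(a, b) per individual
# (NA for missing), one locus; or use make_geno_multi for several loci.
make_geno <- function(calls, population = "P1", locus = "L1",
                      ids = sprintf("i%02d", seq_along(calls))) {
  tibble::tibble(
    individual = ids,
    population = population,
    locus = locus,
    allele_a = vapply(calls, function(x) as.integer(x[1]), integer(1)),
    allele_b = vapply(calls, function(x) as.integer(x[2]), integer(1))
  )
}

# Stack several single-locus builders for the same individuals.
make_geno_multi <- function(..., population = "P1") {
  blocks <- list(...)
  dplyr::bind_rows(purrr::imap(blocks, function(calls, i) {
    make_geno(calls, population = population, locus = sprintf("L%d", i))
  }))
}

# A random valid frequency vector of k alleles (never exactly equifrequent).
random_spectrum <- function(k) {
  p <- stats::rgamma(k, shape = 1) + 1e-6
  p / sum(p)
}

# Brute-force double-loop oracles for He and Botstein's PIC.
he_oracle <- function(p) {
  s <- 0
  for (i in seq_along(p)) s <- s + p[i]^2
  1 - s
}

pic_oracle <- function(p) {
  s <- 0
  for (i in seq_along(p)) s <- s + p[i]^2
  cross <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i < j) cross <- cross + 2 * p[i]^2 * p[j]^2
    }
  }
  1 - s - cross
}

# An exactly log-linear ladder: log10(size) = slope * migration + intercept.
exact_ladder <- function(sizes = c(50, 100, 200, 400),
                         slope = -0.05, intercept = 3) {
  tibble::tibble(size_bp = sizes,
                 migration = (log10(sizes) - intercept) / slope)
}
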