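#' Simulate a multi-breed microsatellite genotype dataset
#'
#' Generates diploid codominant genotypes under the Balding-Nichols model:
#' per locus, ancestral allele frequencies are drawn from a flat Dirichlet
#' over the locus's allele count, and each population's frequencies from a
#' Dirichlet with parameters `p_anc * (1 - fst) / fst`, which makes `fst`
#' the expected differentiation between populations. Within populations,
#' genotypes are drawn with inbreeding coefficient `fis`:
#' `P(hom i) = p_i^2 + fis p_i (1 - p_i)` and
#' `P(het ij) = 2 p_i p_j (1 - fis)`.
#'
#' Defaults emulate a seven-breed rabbit survey design: populations BB, WB,
#' RB, JAB, NZW, AR, CH of sizes 127, 40, 40, 112, 87, 60, 60; 14 loci with
#' 2-10 alleles each; between-breed differentiation 0.22 with within-breed
#' inbreeding 0; 2% missing calls. Allele classes are mapped to plausible
#' fragment sizes at 2-bp spacing (dinucleotide-style markers) starting at
#' 100 bp. Output is fully determined by `seed`.
#'
#' @param populations Named integer vector of population sizes (each >= 2).
#' @param n_loci Number of independent loci.
#' @param alleles_range Inclusive range the per-locus allele count is drawn
#'   from uniformly.
#' @param fst Target differentiation in `[0, 1)`; `0` makes every
#'   population share the ancestral frequencies exactly.
#' @param fis Within-population inbreeding coefficient in `(-1, 1)`.
#' @param missing_rate Probability a call is missing.
#' @param seed Integer seed (required; the dataset is a pure function of
#'   the configuration).
#' @return A genotype tibble (see [genotype-table]).
#' @examples
#' g <- simulate_genotypes(populations = c(A = 30, B = 30), n_loci = 3,
#'                         seed = 1)
#' dplyr::count(g, population)
#' @export
simulate_genotypes <- function(populations = c(BB = 127, WB = 40, RB = 40,
                                               JAB = 112, NZW = 87, AR = 60,
                                               CH = 60),
                               n_loci = 14, alleles_range = c(2, 10),
                               fst = 0.22, fis = 0, missing_rate = 0.02,
                               seed) {
  if (missing(seed)) abort("simulate_genotypes() requires a seed")
  if (is.null(names(populations)) || any(!nzchar(names(populations)))) {
    abort("populations must be a named vector of sizes")
  }
  if (any(populations < 2)) abort("population sizes must be >= 2")
  if (fst < 0 || fst >= 1) abort("fst must lie in [0, 1)")
  if (fis <= -1 || fis >= 1) abort("fis must lie in (-1, 1)")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)")
  }

  withr::with_seed(as.integer(seed), {
    loci <- sprintf("L%02d", seq_len(n_loci))
    inds <- tibble::tibble(
      population = rep(names(populations), populations),
      individual = sprintf("%s_%03d", rep(names(populations), populations),
                           unlist(lapply(populations, seq_len)))
    )
    rows <- purrr::map(seq_len(n_loci), function(l) {
      k <- sample(seq.int(alleles_range[1], alleles_range[2]), 1L)
      sizes <- 100L + 2L * (seq_len(k) - 1L)
      p_anc <- rdirichlet_one(rep(1, k))
      pop_rows <- purrr::map(names(populations), function(pop) {
        p <- if (fst == 0) p_anc else rdirichlet_one(p_anc * (1 - fst) / fst)
        ab <- draw_genotypes(p, populations[[pop]], fis)
        tibble::tibble(population = pop,
                       allele_a = sizes[pmin(ab$a, ab$b)],
                       allele_b = sizes[pmax(ab$a, ab$b)])
      })
      out <- dplyr::bind_rows(pop_rows)
      out$individual <- inds$individual
      out$locus <- loci[[l]]
      out
    })
    geno <- dplyr::bind_rows(rows)
    drop <- runif(nrow(geno)) < missing_rate
    geno$allele_a[drop] <- NA_integer_
    geno$allele_b[drop] <- NA_integer_
    as_genotypes(geno)
  })
}

rdirichlet_one <- function(alpha) {
  # guard tiny concentrations: gamma draws can underflow to all-zero
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  while (sum(g) == 0) g <- stats::rgamma(length(alpha),
                                         shape = pmax(alpha, 1e-8))
  g / sum(g)
}

# n diploid draws with inbreeding. For fis >= 0 the second gene copies the
# first with probability fis (exactly the target genotype law). For fis < 0
# (heterozygote excess) independent pairs are thinned by rejection with
# acceptance ratio target/HWE scaled so heterozygotes are always kept;
# infeasible cells (target P(hom) < 0 for rare alleles) are clamped to 0.
draw_genotypes <- function(p, n, fis) {
  k <- length(p)
  a <- sample.int(k, n, replace = TRUE, prob = p)
  b <- sample.int(k, n, replace = TRUE, prob = p)
  if (fis > 0) {
    copy <- runif(n) < fis
    b[copy] <- a[copy]
  } else if (fis < 0) {
    for (i in seq_len(n)) {
      repeat {
        if (a[i] != b[i]) break
        acc <- (1 + fis * (1 - p[a[i]]) / p[a[i]]) / (1 - fis)
        if (runif(1) < max(0, acc)) break
        a[i] <- sample.int(k, 1L, prob = p)
        b[i] <- sample.int(k, 1L, prob = p)
      }
    }
  }
  list(a = a, b = b)
}

#' Simulate a gel band table from genotypes
#'
#' Inverts the log-linear sizing model to produce per-band migration
#' distances for every non-missing call (one row per individual x locus;
#' homozygotes show a single band), adds seeded Gaussian noise to the
#' fragment sizes, and emits a matching 50-bp ladder specification so the
#' whole gel-sizing stage can be exercised end to end.
#'
#' @param geno A genotype tibble.
#' @param slope,intercept Parameters of the sizing model
#'   `log10(size) = slope * migration + intercept` used to place bands.
#' @param noise_sd Gaussian size noise in bp (applied before converting to
#'   migration).
#' @param ladder_max Largest ladder rung in bp (rungs run 50, 100, ...).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return A list with `bands` (tibble `individual`, `population`, `locus`,
#'   `migration_1`, `migration_2`) and `ladder` (tibble `size_bp`,
#'   `migration`).
#' @export
simulate_band_table <- function(geno, slope = -0.02, intercept = 2.899,
                                noise_sd = 0, ladder_max = 500, seed = NULL) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (noise_sd > 0 && is.null(seed)) {
    abort("simulate_band_table() needs a seed when noise_sd > 0")
  }
  geno <- as_genotypes(geno)
  typed <- geno[!is.na(geno$allele_a), ]
  to_migration <- function(size) (log10(size) - intercept) / slope

  sizes_a <- as.numeric(typed$allele_a)
  sizes_b <- ifelse(typed$allele_b == typed$allele_a, NA_real_,
                    as.numeric(typed$allele_b))
  if (noise_sd > 0) {
    noisy <- withr::with_seed(as.integer(seed), {
      list(a = sizes_a + rnorm(length(sizes_a), sd = noise_sd),
           b = sizes_b + rnorm(length(sizes_b), sd = noise_sd))
    })
    sizes_a <- noisy$a
    sizes_b <- noisy$b
  }
  bands <- tibble::tibble(
    individual = typed$individual, population = typed$population,
    locus = typed$locus,
    migration_1 = to_migration(sizes_a),
    migration_2 = to_migration(sizes_b)
  )
  rungs <- seq(50, ladder_max, by = 50)
  ladder <- tibble::tibble(size_bp = rungs, migration = to_migration(rungs))
  list(bands = bands, ladder = ladder)
}
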