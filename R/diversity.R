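#' Single-spectrum diversity statistics
#'
#' Helpers operating on one allele frequency vector `p` (summing to 1):
#' * `n_alleles_observed()` — the observed allele count No.
#' * `n_alleles_effective()` — Ne = 1 / sum(p^2), the number of equifrequent
#'   alleles giving the same homozygosity; 1 <= Ne <= No with equality iff
#'   the alleles are equifrequent.
#' * `expected_het()` — gene diversity He = 1 - sum(p^2); with
#'   `unbiased = TRUE` the small-sample correction n/(n-1) is applied
#'   (`n_genes` = number of sampled genes), capped at 1.
#' * `pic()` — Botstein's polymorphic information content,
#'   `1 - sum(p^2) - sum_{i != j} p_i^2 p_j^2`; always <= He, with markers
#'   conventionally called highly informative above 0.50 and moderately
#'   informative between 0.25 and 0.50.
#'
#' @param p Numeric vector of allele frequencies (must sum to 1).
#' @param n_genes Number of genes sampled (2 x typed individuals); required
#'   for the unbiased estimator.
#' @param unbiased Apply the small-sample correction?
#' @return A single number.
#' @examples
#' p <- c(0.5, 0.5)
#' n_alleles_effective(p)
#' expected_het(p)
#' pic(p)
#' @name spectrum-stats
NULL

check_freqs <- function(p) {
  if (length(p) == 0L || any(p <= 0) || any(p > 1)) {
    abort("frequencies must lie in (0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-9) abort("frequencies must sum to 1")
  invisible(p)
}

#' @rdname spectrum-stats
#' @export
n_alleles_observed <- function(p) {
  check_freqs(p)
  length(p)
}

#' @rdname spectrum-stats
#' @export
n_alleles_effective <- function(p) {
  check_freqs(p)
  1 / sum(p^2)
}

#' @rdname spectrum-stats
#' @export
expected_het <- function(p, n_genes = NULL, unbiased = FALSE) {
  check_freqs(p)
  he <- 1 - sum(p^2)
  if (unbiased) {
    if (is.null(n_genes) || n_genes < 2) {
      abort("unbiased He needs n_genes >= 2")
    }
    he <- min(1, n_genes / (n_genes - 1) * he)
  }
  he
}

#' @rdname spectrum-stats
#' @export
pic <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2)
  # sum over ordered pairs i != j of p_i^2 p_j^2 equals (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Observed heterozygosity
#'
#' Fraction of typed individuals carrying two distinct alleles, per
#' population x locus. Missing calls are excluded from the denominator.
#'
#' @param geno A genotype tibble.
#' @return Tibble with `population`, `locus`, `n_typed`, `Ho`.
#' @export
observed_het <- function(geno) {
  geno <- as_genotypes(geno)
  typed <- geno[!is.na(geno$allele_a), ]
  if (nrow(typed) == 0L) abort("no typed genotypes")
  typed |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      n_typed = dplyr::n(),
      Ho = mean(.data$allele_a != .data$allele_b),
      .groups = "drop"
    )
}

#' Per-population, per-locus diversity table
#'
#' Computes, for every population x locus with data: the observed (No) and
#' effective (Ne) allele counts, observed (Ho) and expected (He)
#' heterozygosity, polymorphic information content (PIC), and the per-locus
#' inbreeding coefficient F = 1 - Ho/He (undefined at monomorphic loci,
#' where He = 0; negative F indicates heterozygote excess).
#'
#' @param geno A genotype tibble.
#' @param unbiased Use the small-sample-corrected He (default `TRUE`; the
#'   uncorrected gene diversity is available for comparison).
#' @return Tibble with one row per population x locus and columns `n_typed`,
#'   `No`, `Ne`, `Ho`, `He`, `PIC`, `F`.
#' @export
diversity_stats <- function(geno, unbiased = TRUE) {
  geno <- as_genotypes(geno)
  freqs <- allele_freqs(geno)
  spec_stats <- freqs |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      No = length(.data$freq),
      Ne = n_alleles_effective(.data$freq),
      He = expected_het(.data$freq, n_genes = .data$n_genes[[1]],
                        unbiased = unbiased),
      PIC = pic(.data$freq),
      .groups = "drop"
    )
  out <- dplyr::inner_join(observed_het(geno), spec_stats,
                           by = c("population", "locus"))
  out$F <- ifelse(out$He > 0, 1 - out$Ho / out$He, NA_real_)
  out[, c("population", "locus", "n_typed", "No", "Ne", "Ho", "He", "PIC", "F")]
}

se_over <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Per-breed diversity summary
#'
#' Means and standard errors over loci of every [diversity_stats()] column,
#' one row per population. The SE convention is the n-1 sample standard
#' deviation over loci divided by sqrt(loci used); it is reported as `NA`
#' when only one locus contributes. `F_mean` averages the per-locus
#' F = 1 - Ho/He over polymorphic loci only (the ratio-of-means alternative
#' `F_ratio = 1 - mean(Ho)/mean(He)` is also reported).
#'
#' @inheritParams diversity_stats
#' @return Tibble with one row per population: `loci_used`, then
#'   `<stat>_mean` and `<stat>_se` for No, Ne, Ho, He, PIC, plus `F_mean`,
#'   `F_se` and `F_ratio`.
#' @export
diversity_summary <- function(geno, unbiased = TRUE) {
  per_locus <- diversity_stats(geno, unbiased = unbiased)
  per_locus |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      loci_used = dplyr::n(),
      dplyr::across(c("No", "Ne", "Ho", "He", "PIC"),
                    list(mean = mean, se = se_over)),
      F_mean = mean(.data$F, na.rm = TRUE),
      F_se = se_over(.data$F),
      F_ratio = 1 - mean(.data$Ho) / mean(.data$He),
      .groups = "drop"
    )
}

#' Plot per-breed diversity summaries
#'
#' Dot-and-error-bar panel of the per-breed means (+/- 1 SE) of the
#' diversity statistics.
#'
#' @param geno A genotype tibble.
#' @param unbiased Passed to [diversity_summary()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(geno, unbiased = TRUE) {
  summ <- diversity_summary(geno, unbiased = unbiased)
  long <- summ |>
    tidyr::pivot_longer(dplyr::matches("^(No|Ne|Ho|He|PIC)_(mean|se)$"),
                        names_to = c("stat", "moment"), names_sep = "_") |>
    tidyr::pivot_wider(id_cols = c("population", "stat"),
                       names_from = "moment")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$population, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se, ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean over loci (+/- SE)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
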