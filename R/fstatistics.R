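#' Island-model gene flow from FST
#'
#' Wright's island-model transform `Nm = (1 - FST) / (4 FST)`, the effective
#' number of migrants per generation. The transform blows up as FST
#' approaches 0, so estimates at or below `fst_floor` are reported as `NA`
#' (the conventional dash for unstable gene-flow estimates).
#'
#' @param fst Numeric vector of FST values in `[0, 1]`.
#' @param fst_floor Suppress Nm when `fst <= fst_floor` (default 0.005).
#' @return Numeric vector of Nm values, `NA` where suppressed or undefined.
#' @examples
#' gene_flow(c(0.048, 0.237, 0.5))
#' @export
gene_flow <- function(fst, fst_floor = 0.005) {
  nm <- ifelse(is.na(fst) | fst <= fst_floor | fst > 1,
               NA_real_, (1 - fst) / (4 * fst))
  if (any(!is.na(fst) & fst > 0 & fst <= fst_floor)) {
    suppressed <- fst[!is.na(fst) & fst > 0 & fst <= fst_floor]
    inform(paste0("Nm suppressed for FST <= ", fst_floor, " (raw Nm: ",
                  paste(sprintf("%.3f", (1 - suppressed) / (4 * suppressed)),
                        collapse = ", "), ")"))
  }
  nm
}

# Invert the gene-flow transform (used in property tests and interactively).
#' @rdname gene_flow
#' @param nm Numeric vector of Nm values.
#' @export
fst_from_gene_flow <- function(nm) {
  ifelse(is.na(nm) | nm < 0, NA_real_, 1 / (4 * nm + 1))
}

#' Hierarchical F-statistics per locus
#'
#' Nei's gene-diversity decomposition of heterozygosity across populations:
#' `HI` is the (weighted) mean observed heterozygosity, `HS` the mean
#' within-population gene diversity `1 - sum(p_k^2)`, and `HT` the gene
#' diversity of the pooled (weighted mean) allele frequencies. Wright's
#' fixation indices follow as `FIS = 1 - HI/HS`, `FST = 1 - HS/HT`,
#' `FIT = 1 - HI/HT`, so Wright's identity
#' `(1 - FIS)(1 - FST) = (1 - FIT)` holds exactly by construction.
#' Populations are weighted by their typed sample size at the locus by
#' default (`weighting = "equal"` gives each population equal weight).
#'
#' Degenerate cases: a locus monomorphic overall (`HT = 0`) has undefined
#' FST/FIT; `HS = 0` with `HT > 0` (populations fixed for different alleles)
#' gives `FST = 1` with FIS undefined.
#'
#' An alternative Weir-Cockerham variance-components estimator (`theta`) is
#' available for sensitivity via `estimator = "wc"`; it does not satisfy the
#' Wright identity exactly and can go negative.
#'
#' @param geno A genotype tibble with at least two populations.
#' @param weighting `"by_sample_size"` (default) or `"equal"`.
#' @param fst_floor Passed to [gene_flow()].
#' @param estimator `"nei"` (default) or `"wc"` (Weir-Cockerham).
#' @return Tibble with one row per locus: `HI`, `HS`, `HT`, `FIS`, `FIT`,
#'   `FST`, `Nm`, `n_pops`.
#' @export
locus_fstats <- function(geno, weighting = c("by_sample_size", "equal"),
                         fst_floor = 0.005,
                         estimator = c("nei", "wc")) {
  weighting <- match.arg(weighting)
  estimator <- match.arg(estimator)
  geno <- as_genotypes(geno)
  if (length(unique(geno$population)) < 2L) {
    abort("F-statistics need at least two populations")
  }
  if (estimator == "wc") {
    recs <- purrr::map(unique(geno$locus), ~ wc_locus(geno, .x))
  } else {
    recs <- purrr::map(unique(geno$locus), ~ nei_locus(geno, .x, weighting))
  }
  out <- dplyr::bind_rows(recs)
  out$Nm <- gene_flow(out$FST, fst_floor = fst_floor)
  out
}

nei_locus <- function(geno, locus, weighting) {
  sub <- geno[geno$locus == locus & !is.na(geno$allele_a), ]
  pops <- unique(sub$population)
  if (nrow(sub) == 0L || length(pops) < 2L) {
    return(tibble::tibble(locus = locus, HI = NA_real_, HS = NA_real_,
                          HT = NA_real_, FIS = NA_real_, FIT = NA_real_,
                          FST = NA_real_, n_pops = length(pops)))
  }
  per_pop <- sub |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n = dplyr::n(),
                     Ho = mean(.data$allele_a != .data$allele_b),
                     .groups = "drop")
  w <- if (weighting == "by_sample_size") {
    per_pop$n / sum(per_pop$n)
  } else {
    rep(1 / nrow(per_pop), nrow(per_pop))
  }
  names(w) <- per_pop$population

  freqs <- allele_freqs(sub)
  hs_pop <- freqs |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(He = 1 - sum(.data$freq^2), .groups = "drop")
  hs_pop <- hs_pop[match(per_pop$population, hs_pop$population), ]

  pooled <- freqs |>
    dplyr::mutate(wf = .data$freq * w[.data$population]) |>
    dplyr::group_by(.data$allele) |>
    dplyr::summarise(p = sum(.data$wf), .groups = "drop")

  HI <- sum(w * per_pop$Ho)
  HS <- sum(w * hs_pop$He)
  HT <- 1 - sum(pooled$p^2)

  FIS <- if (HS > 0) 1 - HI / HS else NA_real_
  FST <- if (HT > 0) 1 - HS / HT else NA_real_
  FIT <- if (HT > 0) 1 - HI / HT else NA_real_
  tibble::tibble(locus = locus, HI = HI, HS = HS, HT = HT,
                 FIS = FIS, FIT = FIT, FST = FST, n_pops = length(pops))
}

# Weir & Cockerham (1984) variance-components theta, averaged over alleles.
# Offered for sensitivity only; HI/HS/HT are reported as in the Nei path.
wc_locus <- function(geno, locus) {
  sub <- geno[geno$locus == locus & !is.na(geno$allele_a), ]
  pops <- unique(sub$population)
  nei <- nei_locus(geno, locus, "by_sample_size")
  if (nrow(sub) == 0L || length(pops) < 2L) return(nei)

  r <- length(pops)
  n_i <- as.numeric(table(factor(sub$population, levels = pops)))
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)

  alleles <- sort(unique(c(sub$allele_a, sub$allele_b)))
  a_sum <- b_sum <- c_sum <- 0
  for (al in alleles) {
    p_i <- vapply(pops, function(pp) {
      s <- sub[sub$population == pp, ]
      (sum(s$allele_a == al) + sum(s$allele_b == al)) / (2 * nrow(s))
    }, numeric(1))
    h_i <- vapply(pops, function(pp) {
      s <- sub[sub$population == pp, ]
      mean((s$allele_a == al) != (s$allele_b == al))
    }, numeric(1))
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)

    a <- n_bar / n_c * (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                                h_bar / 4) / (n_bar - 1))
    b <- n_bar / (n_bar - 1) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                                  (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    a_sum <- a_sum + a; b_sum <- b_sum + b; c_sum <- c_sum + cc
  }
  denom <- a_sum + b_sum + c_sum
  nei$FST <- if (denom > 0) a_sum / denom else NA_real_
  nei$FIT <- if (denom > 0) 1 - c_sum / denom else NA_real_
  nei$FIS <- if (b_sum + c_sum > 0) 1 - c_sum / (b_sum + c_sum) else NA_real_
  nei
}

#' F-statistics summary table
#'
#' One row per locus from [locus_fstats()] plus column means and standard
#' errors (the n-1 SD over loci divided by sqrt(loci); Nm averaged over loci
#' where it is defined). Each locus is labelled `"high"` differentiation
#' when FST exceeds 0.15, `"moderate"` above 0.05, `"low"` otherwise.
#'
#' @inheritParams locus_fstats
#' @return A list with components `per_locus` (tibble, one row per locus,
#'   with a `differentiation` label) and `summary` (tibble of `mean` and
#'   `se` rows for FIS, FIT, FST, Nm).
#' @export
fstats_table <- function(geno, weighting = c("by_sample_size", "equal"),
                         fst_floor = 0.005, estimator = c("nei", "wc")) {
  per_locus <- locus_fstats(geno, weighting = weighting,
                            fst_floor = fst_floor, estimator = estimator)
  per_locus$differentiation <- dplyr::case_when(
    is.na(per_locus$FST) ~ NA_character_,
    per_locus$FST > 0.15 ~ "high",
    per_locus$FST > 0.05 ~ "moderate",
    TRUE ~ "low"
  )
  cols <- per_locus[c("FIS", "FIT", "FST", "Nm")]
  summary <- tibble::tibble(
    statistic = names(cols),
    mean = unname(vapply(cols, mean, numeric(1), na.rm = TRUE)),
    se = unname(vapply(cols, se_over, numeric(1))),
    n_loci = unname(vapply(cols, function(x) sum(!is.na(x)), integer(1)))
  )
  list(per_locus = per_locus, summary = summary)
}

#' Plot per-locus differentiation
#'
#' Lollipop chart of per-locus FST with the conventional 0.15 high-
#' differentiation threshold marked.
#'
#' @param fstats Either a genotype tibble or the result of [locus_fstats()].
#' @param ... Passed to [locus_fstats()] when `fstats` is a genotype table.
#' @return A ggplot object.
#' @export
plot_fstats <- function(fstats, ...) {
  if (!"FST" %in% names(fstats)) fstats <- locus_fstats(fstats, ...)
  ggplot2::ggplot(fstats, ggplot2::aes(x = .data$locus, y = .data$FST)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$locus, yend = 0),
                          colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.15, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = expression(F[ST]),
                  subtitle = "dashed line: high-differentiation threshold (0.15)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
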