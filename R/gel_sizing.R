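#' Fit a ladder sizing curve
#'
#' Fits the conventional gel calibration model, `log10(size bp)` linear in
#' migration distance, to the rungs of a DNA ladder by ordinary least
#' squares. Larger fragments migrate less, so a valid ladder has strictly
#' increasing sizes with strictly decreasing migrations. A warning is issued
#' when the fit's R-squared drops below `r2_warn` (default 0.99), the usual
#' QC bar for accepting a gel's sizing.
#'
#' @param ladder Data frame with columns `size_bp` and `migration`
#'   (migration in any consistent unit).
#' @param r2_warn QC threshold: warn (never error) when R-squared is lower.
#' @return An object of class `sizing_curve` with elements `slope`,
#'   `intercept`, `r2`, `fit` (the underlying `lm`), and `ladder`.
#' @examples
#' ladder <- tibble::tibble(size_bp = c(50, 100, 200),
#'                          migration = c(30, 20, 10))
#' fit_sizing_curve(ladder)
#' @export
fit_sizing_curve <- function(ladder, r2_warn = 0.99) {
  if (!all(c("size_bp", "migration") %in% names(ladder))) {
    abort("ladder needs columns 'size_bp' and 'migration'")
  }
  ladder <- tibble::as_tibble(ladder)[, c("size_bp", "migration")]
  ladder <- ladder[order(ladder$size_bp), ]
  if (nrow(ladder) < 3L) abort("ladder must have at least 3 rungs")
  if (any(diff(ladder$size_bp) <= 0)) {
    abort("ladder rung sizes must be strictly increasing")
  }
  if (any(diff(ladder$migration) >= 0)) {
    abort("ladder migrations must be strictly decreasing in size")
  }

  fit <- lm(log10(size_bp) ~ migration, data = ladder)
  y <- log10(ladder$size_bp)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  if (r2 < r2_warn) {
    warn(sprintf("sizing curve r2 = %.4f below QC threshold %.2f", r2, r2_warn))
  }
  structure(
    list(slope = unname(coef(fit)[["migration"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r2 = r2, fit = fit, ladder = ladder),
    class = "sizing_curve"
  )
}

#' @export
print.sizing_curve <- function(x, ...) {
  cat(sprintf(
    "<sizing_curve> log10(bp) = %.6g * migration + %.6g  (r2 = %.4f, %d rungs)\n",
    x$slope, x$intercept, x$r2, nrow(x$ladder)))
  invisible(x)
}

#' @rdname fit_sizing_curve
#' @param x A `sizing_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sizing_curve <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "migration"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname fit_sizing_curve
#' @exportS3Method generics::glance
glance.sizing_curve <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, n_rungs = nrow(x$ladder),
                 slope = x$slope, intercept = x$intercept)
}

#' Estimate fragment sizes from migrations
#'
#' Inverts the fitted sizing curve: `size = 10^(slope * migration +
#' intercept)`. Migrations outside the ladder's span are still sized
#' (extrapolation) but flagged in the `extrapolated` attribute.
#'
#' @param curve A `sizing_curve` from [fit_sizing_curve()].
#' @param migration Numeric vector of migration distances.
#' @return Numeric vector of sizes in bp with a logical attribute
#'   `extrapolated` marking entries outside the ladder span.
#' @export
estimate_band_size <- function(curve, migration) {
  stopifnot(inherits(curve, "sizing_curve"))
  size <- 10^(curve$slope * migration + curve$intercept)
  rng <- range(curve$ladder$migration)
  outside <- migration < rng[1] | migration > rng[2]
  if (any(outside)) {
    warn(sprintf("%d band(s) outside the ladder span; sizes extrapolated",
                 sum(outside)))
  }
  attr(size, "extrapolated") <- outside
  size
}

#' Bin raw fragment sizes into allele classes
#'
#' Sorts the raw sizes and chains them into single-linkage clusters, linking
#' neighbours whose gap is strictly below `tolerance` (so alleles spaced at
#' exactly the tolerance stay distinct). Any chain whose total span still
#' reaches the tolerance is then split greedily at its largest internal gap,
#' recursively, until every cluster spans strictly less — placing the
#' class boundaries at the sparsest points of the size distribution. Each
#' cluster is labelled by its rounded mean size. The procedure is
#' deterministic (ties split at the leftmost largest gap) and idempotent
#' (re-binning the integer labels returns them unchanged).
#'
#' @param raw_sizes Numeric vector of estimated sizes in bp.
#' @param tolerance Maximum within-class span in bp (default 2, typical PAGE
#'   resolution).
#' @return A tibble with columns `raw_size` (input order) and `allele`
#'   (integer class label).
#' @examples
#' bin_alleles(c(99.6, 100.3, 120.1))
#' @export
bin_alleles <- function(raw_sizes, tolerance = 2) {
  if (tolerance <= 0) abort("tolerance must be positive")
  if (length(raw_sizes) == 0L) {
    return(tibble::tibble(raw_size = numeric(), allele = integer()))
  }
  ord <- order(raw_sizes)
  sorted <- raw_sizes[ord]

  split_cluster <- function(v) {
    # v sorted; returns a list of sorted chunks each spanning < tolerance
    if (v[[length(v)]] - v[[1]] < tolerance) return(list(v))
    gaps <- diff(v)
    cut <- which.max(gaps)  # leftmost largest gap
    c(split_cluster(v[seq_len(cut)]),
      split_cluster(v[seq.int(cut + 1L, length(v))]))
  }

  # single-linkage chains: break where the gap reaches the tolerance
  chain_id <- cumsum(c(1, diff(sorted) >= tolerance))
  clusters <- unlist(
    lapply(split(sorted, chain_id), split_cluster),
    recursive = FALSE
  )
  label <- unname(purrr::map_int(clusters, ~ as.integer(round(mean(.x)))))
  out <- tibble::tibble(
    raw_size = unlist(clusters, use.names = FALSE),
    allele = rep(label, lengths(clusters))
  )
  # unlist(clusters) preserves the sorted order, so undo the sort directly
  out[order(ord), , drop = FALSE]
}

#' Call genotypes from band observations
#'
#' Sizes each band with the fitted curve, bins sizes into allele classes per
#' locus (pooling all individuals so allele classes are shared across the
#' gel), and applies the codominant diploid scoring rule: one band is a
#' homozygote, two distinct bands a heterozygote. Two bands that fall into
#' the same allele class collapse to a homozygote with a warning, mirroring
#' manual resolution of faint double bands.
#'
#' @param bands Data frame with columns `individual`, `population`, `locus`,
#'   `migration_1` and optionally `migration_2` (`NA` = single band).
#' @param curve A `sizing_curve`.
#' @param tolerance Binning tolerance in bp passed to [bin_alleles()].
#' @return A genotype tibble (see [genotype-table]).
#' @export
call_genotypes <- function(bands, curve, tolerance = 2) {
  need <- c("individual", "population", "locus", "migration_1")
  if (!all(need %in% names(bands))) {
    abort("bands needs columns individual, population, locus, migration_1")
  }
  bands <- tibble::as_tibble(bands)
  if (!"migration_2" %in% names(bands)) bands$migration_2 <- NA_real_
  if (any(is.na(bands$migration_1))) {
    abort("migration_1 must be present for every observation")
  }

  long <- tidyr::pivot_longer(bands, cols = c("migration_1", "migration_2"),
                              values_to = "migration", values_drop_na = TRUE)
  # round far below gel resolution so equal fragments size identically
  long$size <- round(as.numeric(estimate_band_size(curve, long$migration)), 6)
  long <- long |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(allele = bin_alleles(.data$size, tolerance)$allele) |>
    dplyr::ungroup()

  calls <- long |>
    dplyr::group_by(.data$individual, .data$population, .data$locus) |>
    dplyr::summarise(alleles = list(.data$allele), .groups = "drop")

  n_bands <- lengths(calls$alleles)
  if (any(n_bands > 2L)) {
    bad <- calls[n_bands > 2L, ]
    abort(paste0(">2 bands for a diploid call: ",
                 paste(bad$individual, bad$locus, sep = "@", collapse = ", ")))
  }
  a <- purrr::map_int(calls$alleles, ~ .x[[1]])
  b <- purrr::map_int(calls$alleles, ~ .x[[length(.x)]])
  collapsed <- n_bands == 2L & a == b
  if (any(collapsed)) {
    warn(sprintf(
      "%d two-band observation(s) binned to one allele class; called homozygous",
      sum(collapsed)))
  }
  as_genotypes(tibble::tibble(
    individual = calls$individual, population = calls$population,
    locus = calls$locus, allele_a = a, allele_b = b
  ))
}

#' @rdname fit_sizing_curve
#' @param object A `sizing_curve`.
#' @exportS3Method ggplot2::autoplot
autoplot.sizing_curve <- function(object, ...) {
  lad <- object$ladder
  ggplot2::ggplot(lad, ggplot2::aes(x = .data$migration,
                                    y = log10(.data$size_bp))) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "migration distance",
                  y = expression(log[10] ~ "size (bp)"),
                  title = sprintf("ladder sizing curve (r2 = %.4f)",
                                  object$r2))
}
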