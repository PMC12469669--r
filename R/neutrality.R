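#' Unsigned Stirling numbers of the first kind
#'
#' `|s(n, k)|` counts permutations of `n` elements with exactly `k` cycles;
#' it is the normalising constant of the Ewens sampling formula conditioned
#' on the number of alleles. Computed by the triangular recurrence
#' `|s(n, k)| = |s(n-1, k-1)| + (n-1) |s(n-1, k)|` in double precision
#' (exact for the modest `n` the exact null ever uses).
#'
#' @param n,k Non-negative integers, `k <= n`.
#' @return The unsigned Stirling number as a double.
#' @examples
#' stirling1_unsigned(4, 2)  # 11
#' @export
stirling1_unsigned <- function(n, k) {
  stopifnot(n >= 0, k >= 0)
  if (k > n) return(0)
  if (n == 0) return(1)
  row <- c(1, rep(0, n))  # row for n = 0: |s(0,0)| = 1
  for (m in seq_len(n)) {
    new <- rep(0, n + 1)
    new[-1] <- row[-(n + 1)]                 # |s(m-1, k-1)|
    new <- new + (m - 1) * row               # (m-1) |s(m-1, k)|
    row <- new
  }
  row[[k + 1]]
}

# Number of partitions of n into exactly k parts (DP on p(n,k) =
# p(n-1,k-1) + p(n-k,k)); used to decide exact enumeration vs Monte Carlo.
count_partitions <- function(n, k) {
  if (k > n || k < 1) return(0)
  p <- matrix(0, nrow = n + 1, ncol = k + 1)
  p[1, 1] <- 1  # p(0, 0) = 1
  for (nn in seq_len(n)) {
    for (kk in seq_len(min(nn, k))) {
      p[nn + 1, kk + 1] <- p[nn, kk] +
        if (nn - kk >= 0) p[nn - kk + 1, kk + 1] else 0
    }
  }
  p[n + 1, k + 1]
}

# Enumerate all partitions of n into exactly k parts (non-increasing),
# into a preallocated list (the recursive tree costs O(k) per partition).
enumerate_partitions <- function(n, k) {
  total <- count_partitions(n, k)
  out <- vector("list", total)
  cur <- integer(k)
  idx <- 0L
  recur <- function(remaining, parts_left, max_part) {
    if (parts_left == 1L) {
      if (remaining <= max_part) {
        cur[k] <<- remaining
        idx <<- idx + 1L
        out[[idx]] <<- cur + 0L  # force a copy of the scratch vector
      }
      return(invisible(NULL))
    }
    hi <- min(max_part, remaining - (parts_left - 1L))
    lo <- ceiling(remaining / parts_left)
    if (hi < lo) return(invisible(NULL))
    for (part in hi:lo) {
      cur[k - parts_left + 1L] <<- part
      recur(remaining - part, parts_left - 1L, part)
    }
  }
  recur(n, k, n)
  out
}

# Log-space table of unsigned Stirling numbers of the first kind:
# L[m+1, j+1] = log |s(m, j)| for m = 0..n, j = 0..k.
log_stirling1_table <- function(n, k) {
  L <- matrix(-Inf, n + 1, k + 1)
  L[1, 1] <- 0
  for (m in seq_len(n)) {
    jj <- seq_len(min(m, k))
    prev_km1 <- L[m, jj]            # log |s(m-1, j-1)|
    prev_k <- L[m, jj + 1]          # log |s(m-1, j)|
    hi <- pmax(prev_km1, prev_k + log(m - 1))
    lo <- pmin(prev_km1, prev_k + log(m - 1))
    val <- ifelse(is.infinite(hi), hi, hi + log1p(exp(lo - hi)))
    L[m + 1, jj + 1] <- val
  }
  L
}

# Exact mean and sd of F = sum((lambda_i/n)^2) under the ESF conditioned on
# (n, k), without enumerating partitions. The conditional law is the cycle
# type of a uniform permutation of n elements with k cycles, so the cycle
# count moments follow from counting permutations containing given cycles:
#   E[a_j]        = C(n,j) (j-1)! |s(n-j, k-1)| / |s(n,k)|
#   E[a_j a_l]    = C(n,j) (j-1)! C(n-j,l) (l-1)! |s(n-j-l, k-2)| / |s(n,k)|
#   E[a_j(a_j-1)] = C(n,j) (j-1)! C(n-j,j) (j-1)! |s(n-2j, k-2)| / |s(n,k)|
# and F = sum_j j^2 a_j / n^2. Everything is evaluated in log space.
esf_exact_moments <- function(n, k) {
  L <- log_stirling1_table(n, k)
  ls_nk <- L[n + 1, k + 1]
  j <- seq_len(n - k + 1)  # a j-cycle leaves >= k-1 singletons
  l_ea <- lchoose(n, j) + lgamma(j) + L[n - j + 1, k] - ls_nk
  mean_S <- sum(j^2 * exp(l_ea))          # S = sum_j j^2 a_j

  # second moment: ordered pairs of distinct cycles of sizes (j, l)
  pair_sum <- 0
  if (k >= 2) {
    for (jv in j) {
      lmax <- n - jv - (k - 2)
      if (lmax < 1) next
      lv <- seq_len(lmax)
      lw <- lchoose(n, jv) + lgamma(jv) + lchoose(n - jv, lv) + lgamma(lv) +
        L[n - jv - lv + 1, k - 1] - ls_nk
      pair_sum <- pair_sum + sum(jv^2 * lv^2 * exp(lw))
    }
  }
  mean_S2 <- sum(j^4 * exp(l_ea)) + pair_sum
  list(mean = mean_S / n^2,
       sd = sqrt(max(0, mean_S2 - mean_S^2)) / n^2)
}

# log multinomial weight of a partition under the ESF conditioned on k:
# P(lambda | n, k) = [n! / prod_j j^{a_j} a_j!] / |s(n, k)|, with a_j the
# number of parts of size j. Weights are normalised directly (their sum is
# |s(n, k)|), avoiding overflow for larger n.
esf_log_weight <- function(lambda) {
  r <- rle(lambda)  # lambda is non-increasing, so rle gives multiplicities
  lfactorial(sum(lambda)) - sum(r$lengths * log(r$values)) -
    sum(lfactorial(r$lengths))
}

#' Ewens sampling formula null for sample homozygosity
#'
#' Distribution of the sample homozygosity `F = sum((lambda_i / n)^2)` over
#' allele configurations (partitions of `n` genes into `k` allele classes)
#' under the Ewens sampling formula conditioned on `(n, k)` — the null of
#' the Ewens-Watterson homozygosity test of neutrality.
#'
#' The default `"auto"` method computes the exact null mean and SD in
#' closed form from the cycle-count moments of a uniform permutation with
#' `k` cycles (the conditional ESF is exactly that cycle-type law), which
#' costs O(n^2) and never enumerates the support.
#'
#' The `"exact"` method enumerates all partitions of `n` with `k` parts and
#' weights them by `n! / prod_j(j^a_j a_j!)`, normalised by the unsigned
#' Stirling number `|s(n, k)|`. When the partition count exceeds
#' `exact_budget` the method falls back to seeded Monte Carlo with a
#' warning: partitions are drawn by the Feller coupling (independent
#' Bernoulli spacings), which samples the unconditional ESF exactly at the
#' theta solved from `E[K | theta, n] = k`, and draws with a part count
#' other than `k` are rejected.
#'
#' @param n Number of genes sampled (2 x typed individuals).
#' @param k Observed number of alleles, `1 <= k <= n`.
#' @param method `"auto"` (default), `"exact"` or `"monte_carlo"`.
#' @param reps Accepted Monte-Carlo draws (default 10000, minimum 1000).
#' @param seed Integer seed, required for the Monte-Carlo path.
#' @param exact_budget Maximum partition count enumerated exactly.
#' @return An object of class `ewens_null`: a list with `mean`, `sd`
#'   (population SD of F under the null), `n`, `k`, `method`, `reps`,
#'   `seed`, and for the exact method a tibble `partitions` of the support
#'   (`partition`, `prob`, `F`).
#' @examples
#' ewens_null(4, 2)          # E[F] = 6.5/11
#' @export
ewens_null <- function(n, k, method = c("auto", "exact", "monte_carlo"),
                       reps = 10000, seed = NULL, exact_budget = 1e6) {
  method <- match.arg(method)
  n <- as.integer(n); k <- as.integer(k)
  if (k < 1 || k > n) abort("need 1 <= k <= n")

  if (k == 1L || k == n) {
    # degenerate: a single configuration, so the null has no spread
    f <- if (k == 1L) 1 else 1 / n
    lambda <- if (k == 1L) n else rep(1L, n)
    return(structure(list(
      mean = f, sd = 0, n = n, k = k, method = "exact", reps = NA_integer_,
      seed = seed,
      partitions = tibble::tibble(partition = list(lambda), prob = 1, F = f)
    ), class = "ewens_null"))
  }

  if (method == "auto") {
    # closed-form conditional moments: exact for any (n, k), no enumeration
    mom <- esf_exact_moments(n, k)
    return(structure(list(
      mean = mom$mean, sd = mom$sd, n = n, k = k, method = "exact",
      reps = NA_integer_, seed = seed, partitions = NULL
    ), class = "ewens_null"))
  }
  if (method == "exact" && count_partitions(n, k) > exact_budget) {
    warn(sprintf(
      "partition count for (n=%d, k=%d) exceeds exact budget; using Monte Carlo",
      n, k))
    method <- "monte_carlo"
  }

  if (method == "exact") {
    parts <- enumerate_partitions(n, k)
    lw <- vapply(parts, esf_log_weight, numeric(1))
    prob <- exp(lw - max(lw))
    prob <- prob / sum(prob)
    f <- vapply(parts, function(l) sum((l / n)^2), numeric(1))
    m <- sum(prob * f)
    v <- sum(prob * f^2) - m^2
    structure(list(
      mean = m, sd = sqrt(max(0, v)), n = n, k = k, method = "exact",
      reps = NA_integer_, seed = seed,
      partitions = tibble::tibble(partition = parts, prob = prob, F = f)
    ), class = "ewens_null")
  } else {
    if (reps < 1000) abort("Monte-Carlo reps must be >= 1000")
    if (is.null(seed)) abort("the Monte-Carlo null needs a seed")
    draws <- withr::with_seed(as.integer(seed),
                              esf_sample_F(n, k, reps))
    structure(list(
      mean = mean(draws), sd = sqrt(mean((draws - mean(draws))^2)),
      n = n, k = k, method = "monte_carlo", reps = as.integer(reps),
      seed = as.integer(seed), partitions = NULL
    ), class = "ewens_null")
  }
}

#' @export
print.ewens_null <- function(x, ...) {
  cat(sprintf("<ewens_null> n=%d k=%d (%s)  E[F]=%.5f  sd[F]=%.5f\n",
              x$n, x$k, x$method, x$mean, x$sd))
  invisible(x)
}

# Solve E[K | theta, n] = sum_i theta/(theta + i - 1) = k for theta.
ewens_theta <- function(n, k) {
  if (k <= 1) return(1e-8)
  if (k >= n) return(1e8)
  ek <- function(theta) sum(theta / (theta + seq_len(n) - 1)) - k
  uniroot(ek, c(1e-8, 1e8), tol = 1e-10)$root
}

# Sample `reps` values of F = sum((lambda/n)^2) from the ESF conditioned on
# K = k. The Feller coupling generates an exact unconditional ESF partition
# from independent Bernoulli(theta/(theta+i-1)) indicators: part sizes are
# the spacings between successive 1s in (xi_1..xi_n, 1), and the number of
# 1s among xi_1..xi_n is the allele count. Draws with K != k are rejected.
esf_sample_F <- function(n, k, reps, max_batches = 4000) {
  theta <- ewens_theta(n, k)
  p <- theta / (theta + seq_len(n) - 1)
  out <- numeric(0)
  batch <- max(1000L, as.integer(reps))
  for (b in seq_len(max_batches)) {
    xi <- matrix(runif(batch * n), nrow = batch) < rep(p, each = batch)
    keep <- rowSums(xi) == k
    if (any(keep)) {
      f_new <- apply(xi[keep, , drop = FALSE], 1L, function(row) {
        ones <- c(which(row), n + 1L)
        sum((diff(ones) / n)^2) + if (ones[1] > 1)
          ((ones[1] - 1) / n)^2 else 0
      })
      out <- c(out, f_new)
    }
    if (length(out) >= reps) break
  }
  if (length(out) < reps) {
    abort(sprintf("Monte-Carlo sampler accepted only %d of %d draws",
                  length(out), reps))
  }
  out[seq_len(reps)]
}

#' Observed sample homozygosity
#'
#' `F = sum(p_hat^2)`, the test statistic of the Ewens-Watterson
#' homozygosity test.
#'
#' @param p Allele frequency vector summing to 1.
#' @return A single number in `(0, 1]`.
#' @export
observed_homozygosity <- function(p) {
  check_freqs(p)
  sum(p^2)
}

#' Ewens-Watterson neutrality deviates
#'
#' For every population x locus, compares the observed sample homozygosity
#' `F_obs = sum(p_hat^2)` with its Ewens-sampling-formula null conditioned
#' on the sample size in genes and the observed allele count, and reports
#' the normalised deviate `D = sign * (E[F_null] - F_obs) / sd[F_null]`.
#' Under the default `sign = 1`, allele-rich samples with even frequencies
#' (low homozygosity) score positive. Monomorphic cells (`k = 1`) have an
#' undefined deviate and are reported as `NA`.
#'
#' @param geno A genotype tibble.
#' @param method,reps,seed,exact_budget Passed to [ewens_null()].
#' @param sign `1` (default) or `-1` to flip the deviate's orientation.
#' @return Tibble with one row per population x locus: `F_obs`, `k`, `n`,
#'   `F_null_mean`, `F_null_sd`, `D`, `method`, `reps`, `seed`.
#' @export
neutrality_test <- function(geno, method = c("auto", "exact", "monte_carlo"),
                            reps = 10000, seed = NULL, sign = 1,
                            exact_budget = 1e6) {
  method <- match.arg(method)
  stopifnot(sign %in% c(-1, 1))
  freqs <- allele_freqs(as_genotypes(geno))
  cells <- dplyr::distinct(freqs, .data$population, .data$locus)

  purrr::pmap(cells, function(population, locus) {
    sub <- spectrum_for(freqs, population, locus)
    k <- nrow(sub)
    n <- sub$n_genes[[1]]
    f_obs <- observed_homozygosity(sub$freq)
    if (k == 1L) {
      return(tibble::tibble(
        population = population, locus = locus, F_obs = f_obs,
        k = k, n = n, F_null_mean = 1, F_null_sd = 0, D = NA_real_,
        method = "exact", reps = NA_integer_, seed = NA_integer_))
    }
    # derive a distinct, stable seed per cell so Monte-Carlo cells are
    # independent yet reproducible for a fixed top-level seed
    cell_seed <- if (is.null(seed)) NULL else
      (as.integer(seed) + 7L * k + n) %% .Machine$integer.max
    null <- ewens_null(n, k, method = method, reps = reps, seed = cell_seed,
                       exact_budget = exact_budget)
    # sd below fp noise means a single-configuration null: D undefined
    d <- if (null$sd > 1e-8) sign * (null$mean - f_obs) / null$sd else NA_real_
    tibble::tibble(
      population = population, locus = locus, F_obs = f_obs, k = k, n = n,
      F_null_mean = null$mean, F_null_sd = null$sd, D = d,
      method = null$method, reps = null$reps,
      seed = null$seed %||% NA_integer_)
  }) |>
    dplyr::bind_rows()
}

#' Neutrality matrix with breed means
#'
#' Reshapes [neutrality_test()] output into the loci x populations deviate
#' matrix, and summarises each population by the arithmetic mean and SE of
#' its defined deviates.
#'
#' @param neut Output of [neutrality_test()], or a genotype tibble (in which
#'   case `...` is passed through to [neutrality_test()]).
#' @param ... Passed to [neutrality_test()] when `neut` is a genotype table.
#' @return A list with `matrix` (tibble, loci in rows, one column per
#'   population, `NA` for undefined) and `summary` (per-population `mean`,
#'   `se`, `n_defined`).
#' @export
neutrality_table <- function(neut, ...) {
  if (!"D" %in% names(neut)) neut <- neutrality_test(neut, ...)
  mat <- tidyr::pivot_wider(neut[, c("locus", "population", "D")],
                            names_from = "population", values_from = "D")
  summary <- neut |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(mean = mean(.data$D, na.rm = TRUE),
                     se = se_over(.data$D),
                     n_defined = sum(!is.na(.data$D)), .groups = "drop")
  list(matrix = mat, summary = summary)
}

#' Plot neutrality deviates
#'
#' Tile heatmap of the per-population, per-locus deviates, with undefined
#' cells left blank.
#'
#' @inheritParams neutrality_table
#' @return A ggplot object.
#' @export
plot_neutrality <- function(neut, ...) {
  if (!"D" %in% names(neut)) neut <- neutrality_test(neut, ...)
  ggplot2::ggplot(neut, ggplot2::aes(x = .data$population, y = .data$locus,
                                     fill = .data$D)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "D")
}
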