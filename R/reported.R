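#' Reported reference statistics from a seven-breed rabbit survey
#'
#' Validation datasets shipped with the package: per-locus F-statistics
#' (FIS, FIT, FST and the island-model gene flow Nm, with Nm suppressed at
#' one near-zero-FST locus) and per-breed Ewens-Watterson neutrality
#' deviates, as reported for seven rabbit breeds (four Egyptian natives —
#' BB, WB, RB, JAB — and three exotics — NZW, AR, CH) genotyped at 14
#' microsatellite loci. The raw genotypes behind these tables are not
#' public, so they serve as internal-consistency references: the Nm column
#' is reproduced by [gene_flow()] applied to the FST column, the rows obey
#' Wright's identity within print rounding, and column means follow the
#' package's summary conventions.
#'
#' @param table `"fstats"` or `"neutrality"`.
#' @return A tibble. For `"fstats"`: `locus`, `FIS`, `FIT`, `FST`, `Nm`
#'   (`NA` = suppressed). For `"neutrality"`: `locus` plus one deviate
#'   column per breed (`NA` = undefined, typically monomorphic cells).
#' @examples
#' reported_rabbit_stats("fstats")
#' @export
reported_rabbit_stats <- function(table = c("fstats", "neutrality")) {
  table <- match.arg(table)
  file <- switch(table,
                 fstats = "rabbit_fstats_reported.tsv",
                 neutrality = "rabbit_neutrality_reported.tsv")
  path <- system.file("extdata", file, package = "msatpop", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
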