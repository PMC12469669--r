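#' Run the full microsatellite analysis pipeline
#'
#' Orchestrates genotypes -> diversity -> F-statistics -> neutrality ->
#' per-locus trees and writes one TSV per stage (plus Newick files for the
#' requested loci) into `out_dir`. Every TSV carries a commented
#' `# key=value` provenance header recording the configuration, seed and
#' package version, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param geno A genotype tibble, or a path to a genotype file.
#' @param out_dir Output directory (created if needed).
#' @param format Input format when `geno` is a path.
#' @param unbiased_he Use small-sample-corrected He in the diversity stage.
#' @param weighting,fst_floor,estimator Passed to [fstats_table()].
#' @param reps,seed,sign Passed to [neutrality_test()].
#' @param tree_loci Character vector of loci to build dendrograms for
#'   (default: none).
#' @param tree_level,tree_metric Level (`"breed"`/`"individual"`) for
#'   [locus_tree()]; at breed level the metric is Nei's standard distance,
#'   at individual level Dice band sharing.
#' @return Invisibly, a list with the `diversity`, `fstats`, `neutrality`
#'   tables and any `trees`, plus the output `paths`.
#' @export
run_msat_pipeline <- function(geno, out_dir, format = c("csv", "genepop"),
                              unbiased_he = TRUE,
                              weighting = "by_sample_size", fst_floor = 0.005,
                              estimator = "nei", reps = 10000, seed = NULL,
                              sign = 1, tree_loci = character(),
                              tree_level = "breed", tree_metric = NULL) {
  if (is.character(geno) && length(geno) == 1L) {
    geno <- read_genotypes(geno, format = match.arg(format))
  }
  geno <- as_genotypes(geno)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  header <- c(
    paste0("# msatpop=", as.character(utils::packageVersion("msatpop"))),
    paste0("# unbiased_he=", unbiased_he),
    paste0("# weighting=", weighting),
    paste0("# estimator=", estimator),
    paste0("# fst_floor=", fst_floor),
    paste0("# reps=", reps),
    paste0("# seed=", seed %||% "NA"),
    paste0("# sign=", sign)
  )
  write_stage <- function(tbl, file) {
    path <- file.path(out_dir, file)
    body <- utils::capture.output(
      utils::write.table(format(as.data.frame(tbl), digits = 10,
                                trim = TRUE, nsmall = 0, scientific = FALSE),
                         sep = "\t", quote = FALSE, row.names = FALSE))
    writeLines(c(header, body), path, useBytes = TRUE)
    path
  }

  stage <- "diversity"
  paths <- list()
  result <- tryCatch({
    div <- diversity_summary(geno, unbiased = unbiased_he)
    paths$diversity <- write_stage(div, "diversity.tsv")

    stage <- "fstatistics"
    fst <- fstats_table(geno, weighting = weighting, fst_floor = fst_floor,
                        estimator = estimator)
    paths$fstats <- write_stage(fst$per_locus, "fstats.tsv")
    paths$fstats_summary <- write_stage(fst$summary, "fstats_summary.tsv")

    stage <- "neutrality"
    neut <- neutrality_test(geno, reps = reps, seed = seed, sign = sign)
    ntab <- neutrality_table(neut)
    wide <- ntab$matrix
    for (cn in setdiff(names(wide), "locus")) {
      wide[[cn]] <- ifelse(is.na(wide[[cn]]), "-",
                           sprintf("%.3f", wide[[cn]]))
    }
    paths$neutrality <- write_stage(wide, "neutrality.tsv")
    paths$neutrality_summary <- write_stage(ntab$summary,
                                            "neutrality_summary.tsv")

    stage <- "phylogenetics"
    trees <- list()
    for (locus in tree_loci) {
      tree <- locus_tree(geno, locus, level = tree_level)
      nwk <- file.path(out_dir, paste0(locus, ".nwk"))
      writeLines(write_newick(tree), nwk, useBytes = TRUE)
      trees[[locus]] <- tree
      paths[[paste0("tree_", locus)]] <- nwk
    }
    list(diversity = div, fstats = fst, neutrality = ntab, trees = trees,
         paths = paths)
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)), parent = e)
  })
  invisible(result)
}
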