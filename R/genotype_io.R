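#' Genotype tables
#'
#' A genotype table is an ordinary tibble with one row per individual x locus
#' call and columns `individual`, `population`, `locus`, `allele_a`,
#' `allele_b`. Alleles are integer fragment sizes in base pairs; a missing
#' call has both alleles `NA` (never just one). Because microsatellite
#' genotypes are unphased, every call is stored canonically with
#' `allele_a <= allele_b`.
#'
#' @name genotype-table
NULL

# Canonicalise and validate a long genotype tibble. All readers and the
# simulator funnel through here so every downstream function can rely on the
# invariants (paired missingness, positive sizes, sorted alleles, unique ids).
as_genotypes <- function(x) {
  required <- c("individual", "population", "locus", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  x$individual <- as.character(x$individual)
  x$population <- as.character(x$population)
  x$locus <- as.character(x$locus)
  x$allele_a <- as.integer(x$allele_a)
  x$allele_b <- as.integer(x$allele_b)

  half <- xor(is.na(x$allele_a), is.na(x$allele_b))
  if (any(half)) {
    abort(paste0("half-missing genotype (one allele NA) for individual(s): ",
                 paste(unique(x$individual[half]), collapse = ", ")))
  }
  ok <- !is.na(x$allele_a)
  if (any(x$allele_a[ok] <= 0L) || any(x$allele_b[ok] <= 0L)) {
    abort("allele sizes must be positive integers (bp)")
  }
  swap <- ok & x$allele_a > x$allele_b
  if (any(swap)) {
    tmp <- x$allele_a[swap]
    x$allele_a[swap] <- x$allele_b[swap]
    x$allele_b[swap] <- tmp
  }

  pop_of <- tapply(x$population, x$individual, function(p) length(unique(p)))
  if (any(pop_of > 1)) {
    abort(paste0("individual(s) assigned to more than one population: ",
                 paste(names(pop_of)[pop_of > 1], collapse = ", ")))
  }
  dup <- duplicated(x[, c("individual", "locus")])
  if (any(dup)) {
    abort(paste0("duplicate call for individual x locus: ",
                 paste(unique(x$individual[dup]), collapse = ", ")))
  }
  x[, required]
}

parse_allele_cell <- function(cell, line_no, path) {
  cell <- trimws(cell)
  if (cell == "" || cell == "NA" || cell == "0/0") {
    return(c(NA_integer_, NA_integer_))
  }
  parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
  sizes <- suppressWarnings(as.integer(parts))
  if (length(parts) != 2L || anyNA(sizes) || any(sizes <= 0L)) {
    abort(paste0("malformed genotype cell '", cell, "' at line ", line_no,
                 " of ", path, " (expected 'A/B' with positive integer bp)"))
  }
  sizes
}

#' Read a genotype table
#'
#' Reads diploid codominant genotypes from either a wide CSV table
#' (`individual,population,<locus1>,...` with cells `A/B` in bp; empty cell =
#' missing) or a GenePop 4.x file (3- or 6-digit allele coding, `Pop`
#' separators, `0` allele = missing).
#'
#' @param path Path to the input file.
#' @param format `"csv"` or `"genepop"`.
#' @return A genotype tibble (see [genotype-table]).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("individual,population,LocA",
#'              "i1,P1,100/100", "i2,P1,100/120"), f)
#' read_genotypes(f)
#' @export
read_genotypes <- function(path, format = c("csv", "genepop")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  geno <- switch(format,
                 csv = read_genotypes_csv(path),
                 genepop = read_genotypes_genepop(path))
  counts <- table(unique(geno[, c("individual", "population")])$population)
  inform(paste0("read ", length(unique(geno$individual)), " individuals in ",
                length(counts), " population(s): ",
                paste(names(counts), counts, sep = "=", collapse = ", ")))
  geno
}

read_genotypes_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort(paste0("no data rows in ", path))
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (length(header) < 3L || header[1] != "individual" ||
      header[2] != "population") {
    abort(paste0("CSV header must be 'individual,population,<loci...>' in ",
                 path))
  }
  loci <- header[-(1:2)]
  if (anyDuplicated(loci)) abort("duplicate locus names in CSV header")

  rows <- purrr::map(seq.int(2L, length(lines)), function(i) {
    cells <- trimws(strsplit(lines[[i]], ",", fixed = TRUE)[[1]])
    length(cells) <- length(header)  # pad trailing empties with NA
    cells[is.na(cells)] <- ""
    alleles <- purrr::map(cells[-(1:2)], parse_allele_cell,
                          line_no = i, path = path)
    tibble::tibble(
      individual = cells[[1]],
      population = cells[[2]],
      locus = loci,
      allele_a = purrr::map_int(alleles, 1),
      allele_b = purrr::map_int(alleles, 2)
    )
  })
  geno <- dplyr::bind_rows(rows)
  ids <- unique(geno$individual)
  if (length(ids) != length(lines) - 1L) {
    abort(paste0("duplicate individual id in ", path))
  }
  as_genotypes(geno)
}

read_genotypes_genepop <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L) abort(paste0("not a GenePop file: ", path))
  body <- lines[-1]  # first line is a free-text title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort(paste0("no 'Pop' separator in ", path))

  locus_lines <- trimws(body[seq_len(first_pop - 1L)])
  # loci may be one per line or comma-separated on one line
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci[nzchar(trimws(loci))])
  if (length(loci) == 0L) abort(paste0("no locus names in ", path))

  pop_idx <- cumsum(is_pop)
  rows <- list()
  for (i in which(!is_pop & pop_idx > 0 & nzchar(trimws(body)))) {
    line <- body[[i]]
    halves <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(halves) != 2L) {
      abort(paste0("malformed GenePop sample line ", i + 1L, " of ", path))
    }
    id <- trimws(halves[[1]])
    codes <- strsplit(trimws(halves[[2]]), "[[:space:]]+")[[1]]
    codes <- codes[nzchar(codes)]
    if (length(codes) != length(loci)) {
      abort(paste0("line ", i + 1L, " of ", path, " has ", length(codes),
                   " genotypes for ", length(loci), " loci"))
    }
    width <- unique(nchar(codes))
    if (length(width) != 1L || !width %in% c(4L, 6L) ||
        any(!grepl("^[0-9]+$", codes))) {
      abort(paste0("line ", i + 1L, " of ", path,
                   " is not 2- or 3-digit GenePop allele coding"))
    }
    half <- width / 2L
    a <- as.integer(substr(codes, 1L, half))
    b <- as.integer(substr(codes, half + 1L, width))
    a[a == 0L] <- NA_integer_
    b[b == 0L] <- NA_integer_
    if (any(xor(is.na(a), is.na(b)))) {
      abort(paste0("half-missing genotype at line ", i + 1L, " of ", path))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      individual = id,
      population = paste0("Pop", pop_idx[[i]]),
      locus = loci, allele_a = a, allele_b = b
    )
  }
  geno <- dplyr::bind_rows(rows)
  n_lines <- sum(!is_pop & pop_idx > 0 & nzchar(trimws(body)))
  if (length(unique(geno$individual)) != n_lines) {
    abort(paste0("duplicate individual id in ", path))
  }
  as_genotypes(geno)
}

#' Write a genotype table
#'
#' Writes the wide CSV dialect or GenePop (6-digit allele coding, zero-padded
#' bp; missing written as `000000`).
#'
#' @param geno A genotype tibble.
#' @param path Output path.
#' @param format `"csv"` or `"genepop"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("csv", "genepop")) {
  format <- match.arg(format)
  geno <- as_genotypes(geno)
  loci <- unique(geno$locus)
  inds <- unique(geno[, c("individual", "population")])

  if (format == "csv") {
    cell <- ifelse(is.na(geno$allele_a), "",
                   paste0(geno$allele_a, "/", geno$allele_b))
    wide <- tidyr::pivot_wider(
      dplyr::mutate(geno, cell = cell),
      id_cols = c("individual", "population"),
      names_from = "locus", values_from = "cell"
    )
    wide <- wide[, c("individual", "population", loci)]
    lines <- c(
      paste(names(wide), collapse = ","),
      apply(as.matrix(wide), 1L, paste, collapse = ",")
    )
    writeLines(lines, path, useBytes = TRUE)
  } else {
    code <- function(a) sprintf("%03d", ifelse(is.na(a), 0L, a))
    geno$code <- paste0(code(geno$allele_a), code(geno$allele_b))
    wide <- tidyr::pivot_wider(geno, id_cols = c("individual", "population"),
                               names_from = "locus", values_from = "code")
    wide <- wide[, c("individual", "population", loci)]
    out <- c("msatpop genotype export", loci)
    for (pop in unique(inds$population)) {
      out <- c(out, "Pop")
      sub <- wide[wide$population == pop, , drop = FALSE]
      out <- c(out, paste0(sub$individual, " ,  ",
                           apply(as.matrix(sub[, loci, drop = FALSE]), 1L,
                                 paste, collapse = " ")))
    }
    writeLines(out, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Allele frequency spectra
#'
#' Computes the per population x locus allele frequency spectrum, counting
#' each non-missing diploid call as two genes. Population x locus cells with
#' no typed individual are dropped (they have no spectrum).
#'
#' @param geno A genotype tibble.
#' @return A tibble with columns `population`, `locus`, `allele`, `freq`,
#'   `n_genes` where `n_genes` is twice the number of typed individuals.
#' @examples
#' g <- tibble::tibble(individual = c("i1", "i2"), population = "P1",
#'                     locus = "L1", allele_a = c(100L, 100L),
#'                     allele_b = c(100L, 120L))
#' allele_freqs(g)
#' @export
allele_freqs <- function(geno) {
  geno <- as_genotypes(geno)
  typed <- geno[!is.na(geno$allele_a), ]
  if (nrow(typed) == 0L) abort("no typed genotypes: cannot compute frequencies")
  long <- tidyr::pivot_longer(typed, cols = c("allele_a", "allele_b"),
                              values_to = "allele")
  long |>
    dplyr::count(.data$population, .data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(n_genes = sum(.data$count),
                  freq = .data$count / .data$n_genes) |>
    dplyr::ungroup() |>
    dplyr::select("population", "locus", "allele", "freq", "n_genes")
}

# Frequency vector for one population x locus cell; errors distinctly when
# the cell has no typed data (mirrors the "-" cells of sparse surveys).
spectrum_for <- function(freqs, population, locus) {
  sub <- freqs[freqs$population == population & freqs$locus == locus, ]
  if (nrow(sub) == 0L) {
    abort(paste0("no data for population '", population, "' at locus '",
                 locus, "'"), class = "msatpop_no_data")
  }
  sub
}
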