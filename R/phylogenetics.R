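#' Nei's standard genetic distance between two spectra
#'
#' `D = -ln( sum(p q) / sqrt(sum(p^2) sum(q^2)) )` for two allele-frequency
#' maps at the same locus. When the populations share no alleles the
#' identity is 0 and the distance is capped at `max_distance` rather than
#' returned as infinity.
#'
#' @param p,q Named numeric vectors mapping allele (bp, as names) to
#'   frequency.
#' @param max_distance Cap applied when no alleles are shared (default 10).
#' @return A non-negative number.
#' @examples
#' nei_distance_pair(c("100" = 0.5, "120" = 0.5), c("100" = 1))
#' @export
nei_distance_pair <- function(p, q, max_distance = 10) {
  check_freqs(p); check_freqs(q)
  if (is.null(names(p)) || is.null(names(q))) {
    abort("spectra must be named by allele")
  }
  alleles <- union(names(p), names(q))
  pv <- setNames(rep(0, length(alleles)), alleles)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  jxy <- sum(pv * qv)
  denom <- sqrt(sum(pv^2) * sum(qv^2))
  if (jxy <= 0) return(max_distance)
  min(max_distance, max(0, -log(jxy / denom)))
}

#' Dice band-sharing distance
#'
#' `1 - 2|A intersect B| / (|A| + |B|)` over two band (allele-class) sets —
#' the complement of the Dice similarity used for individual-level band
#' pattern comparison.
#'
#' @param a,b Vectors of allele classes (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @export
band_sharing_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("band sets must be non-empty")
  }
  1 - 2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Per-locus distance matrix
#'
#' Builds the symmetric distance matrix used for the per-locus dendrograms:
#' at `level = "breed"` the labels are populations and distances are Nei's
#' standard distance between their allele-frequency spectra; at
#' `level = "individual"` the labels are individuals typed at the locus and
#' distances are Dice band-sharing distances between their allele sets.
#'
#' @param geno A genotype tibble.
#' @param locus Locus name.
#' @param level `"breed"` (default) or `"individual"`.
#' @param max_distance Cap for Nei distances with no shared alleles.
#' @return A symmetric matrix with zero diagonal and labelled dimnames.
#' @export
locus_distance_matrix <- function(geno, locus, level = c("breed", "individual"),
                                  max_distance = 10) {
  level <- match.arg(level)
  geno <- as_genotypes(geno)
  sub <- geno[geno$locus == locus & !is.na(geno$allele_a), ]
  if (nrow(sub) == 0L) abort(paste0("no typed data at locus '", locus, "'"))

  if (level == "breed") {
    freqs <- allele_freqs(sub)
    labels <- sort(unique(freqs$population))
    spectra <- purrr::map(labels, function(pop) {
      s <- freqs[freqs$population == pop, ]
      setNames(s$freq, s$allele)
    })
  } else {
    labels <- sort(unique(sub$individual))
    spectra <- purrr::map(labels, function(id) {
      s <- sub[sub$individual == id, ]
      unique(c(s$allele_a, s$allele_b))
    })
  }
  if (length(labels) < 2L) abort("need at least 2 labels for a distance matrix")

  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- if (level == "breed") {
        nei_distance_pair(spectra[[i]], spectra[[j]],
                          max_distance = max_distance)
      } else {
        band_sharing_distance(spectra[[i]], spectra[[j]])
      }
    }
  }
  d
}

#' UPGMA dendrogram
#'
#' Average-linkage (cluster-size weighted, i.e. standard UPGMA)
#' agglomeration of a symmetric distance matrix into an ultrametric rooted
#' tree. Ties are broken deterministically by lexicographic label order
#' (labels are sorted before clustering). Node heights are half the merge
#' distances, so two leaves at distance `d` sit on branches of length
#' `d / 2`.
#'
#' @param d A symmetric matrix with labelled dimnames (e.g. from
#'   [locus_distance_matrix()]) or a [stats::dist] object.
#' @return An [ape::phylo] tree of class `c("upgma", "phylo")`, ultrametric,
#'   with the `hclust` object attached as attribute `"hclust"`.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' write_newick(upgma(d))
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("d must be a square matrix")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-12) abort("distance matrix must be symmetric")
  if (any(diag(d) != 0)) abort("distance matrix must have zero diagonal")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)  # divides heights by two -> ultrametric branches
  attr(tree, "hclust") <- hc
  class(tree) <- c("upgma", "phylo")
  tree
}

#' Newick serialisation
#'
#' `write_newick()` renders a tree as a Newick string with branch lengths;
#' `read_newick()` parses one. Writing a parsed string back is stable
#' (canonical round trip).
#'
#' @param tree An `ape::phylo` tree.
#' @param digits Significant digits for branch lengths.
#' @return `write_newick()` a single string; `read_newick()` a `phylo`.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' @rdname write_newick
#' @param text A Newick string.
#' @export
read_newick <- function(text) {
  ape::read.tree(text = text)
}

#' Per-locus UPGMA tree
#'
#' Convenience wrapper: [locus_distance_matrix()] then [upgma()].
#'
#' @inheritParams locus_distance_matrix
#' @return An ultrametric `phylo` tree.
#' @export
locus_tree <- function(geno, locus, level = c("breed", "individual"),
                       max_distance = 10) {
  upgma(locus_distance_matrix(geno, locus, level = level,
                              max_distance = max_distance))
}

#' @exportS3Method ggplot2::autoplot
#' @rdname upgma
#' @param object A `upgma` tree.
#' @param ... Unused.
autoplot.upgma <- function(object, ...) {
  hc <- attr(object, "hclust")
  if (is.null(hc)) abort("tree lacks the attached hclust object")
  # rectangle-dendrogram coordinates from the hclust merge order
  n <- length(hc$labels)
  leaf_x <- setNames(seq_len(n), hc$order)  # leaf index -> x position
  node_x <- numeric(n - 1)
  node_h <- hc$height / 2
  segs <- list()
  x_of <- function(id) if (id < 0) leaf_x[[as.character(-id)]] else node_x[[id]]
  h_of <- function(id) if (id < 0) 0 else node_h[[id]]
  for (m in seq_len(n - 1)) {
    a <- hc$merge[m, 1]; b <- hc$merge[m, 2]
    xa <- x_of(a); xb <- x_of(b)
    node_x[[m]] <- (xa + xb) / 2
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(h_of(a), h_of(b), node_h[[m]]),
      yend = c(node_h[[m]], node_h[[m]], node_h[[m]]))
  }
  segs <- dplyr::bind_rows(segs)
  labs <- tibble::tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs, ggplot2::aes(x = .data$x, y = 0,
                                                 label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous("height (distance / 2)") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::coord_cartesian(clip = "off") +
    ggplot2::theme_minimal()
}
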