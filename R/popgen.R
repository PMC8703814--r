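# Locus summary statistics and variety discrimination from a genotype
# table. Allele frequencies are obtained by gene counting (two gene
# copies per typed variety); missing cells are excluded marker-wise.

#' Per-marker summary statistics
#'
#' For each marker: number of distinct alleles, observed heterozygosity
#' `Ho` (fraction of typed varieties with two distinct alleles), Nei's
#' gene diversity `He = 1 - sum(p_i^2)` and polymorphism information
#' content `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param table Long-format genotype table.
#' @param markers Optional subset of markers.
#' @param unbiased Apply the small-sample correction `2n/(2n-1)` to `He`
#'   (default `FALSE`: the plain gene-diversity estimator).
#' @return Tibble `marker`, `n_typed`, `n_alleles`, `ho`, `he`, `pic`.
#' @export
marker_stats <- function(table, markers = NULL, unbiased = FALSE) {
  table <- dplyr::filter(genotype_table(table), !is.na(.data$allele_a))
  if (!is.null(markers)) table <- table[table$marker %in% markers, ]
  if (nrow(table) == 0) abort_ssr("no typed varieties for the requested markers")
  table |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_modify(function(df, key) {
      p <- as.numeric(table(c(df$allele_a, df$allele_b)))
      p <- p / sum(p)
      sp2 <- sum(p^2)
      he <- 1 - sp2
      if (unbiased) {
        n2 <- 2 * nrow(df)
        he <- he * n2 / (n2 - 1)
      }
      # sum_{i<j} 2 p_i^2 p_j^2 == (sum p^2)^2 - sum p^4
      pic <- 1 - sp2 - (sp2^2 - sum(p^4))
      tibble::tibble(
        n_typed = nrow(df),
        n_alleles = length(p),
        ho = mean(df$allele_a != df$allele_b),
        he = he,
        pic = pic
      )
    }) |>
    dplyr::ungroup()
}

#' Panel averages of marker statistics
#'
#' @param stats Tibble from [marker_stats()] (or any tibble with
#'   `n_alleles`, `ho`, `he`, `pic`).
#' @return One-row tibble with `n_markers` and the arithmetic means
#'   `mean_n_alleles`, `mean_ho`, `mean_he`, `mean_pic`.
#' @export
panel_averages <- function(stats) {
  if (nrow(stats) == 0) abort_ssr("panel_averages() needs at least one marker")
  tibble::tibble(
    n_markers = nrow(stats),
    mean_n_alleles = mean(stats$n_alleles),
    mean_ho = mean(stats$ho),
    mean_he = mean(stats$he),
    mean_pic = mean(stats$pic)
  )
}

#' Find varieties with identical multilocus genotypes
#'
#' Two varieties are indistinguishable when their genotypes agree at every
#' mutually typed marker (and they share at least one typed marker). An
#' empty result means every variety is uniquely fingerprinted.
#'
#' @param table Long-format genotype table.
#' @return Tibble `variety_1`, `variety_2`, `n_shared_markers`.
#' @export
find_identical_genotypes <- function(table) {
  table <- genotype_table(table)
  varieties <- unique(table$variety)
  out <- list()
  typed <- dplyr::filter(table, !is.na(.data$allele_a))
  by_var <- split(typed[, c("marker", "allele_a", "allele_b")], typed$variety)
  for (i in seq_along(varieties)) {
    for (j in seq_len(i - 1L)) {
      a <- by_var[[varieties[i]]]
      b <- by_var[[varieties[j]]]
      if (is.null(a) || is.null(b)) next
      m <- dplyr::inner_join(a, b, by = "marker", suffix = c("_1", "_2"))
      if (nrow(m) == 0) next
      same <- all(m$allele_a_1 == m$allele_a_2 & m$allele_b_1 == m$allele_b_2)
      if (same) {
        out[[length(out) + 1L]] <- tibble::tibble(
          variety_1 = varieties[j], variety_2 = varieties[i],
          n_shared_markers = nrow(m)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(variety_1 = character(), variety_2 = character(),
                          n_shared_markers = integer()))
  }
  dplyr::bind_rows(out)
}

#' Shared-allele distance matrix
#'
#' `d(i, j) = 1 - shared / (2 m)` where `m` is the number of mutually
#' typed markers and `shared` counts, per marker, the multiset
#' intersection of the two genotypes (0, 1 or 2 alleles). Pairs with no
#' mutually typed marker get distance 1 and are listed in the
#' `"no_overlap_pairs"` attribute.
#'
#' @param table Long-format genotype table with at least two varieties.
#' @return A [stats::dist] object labelled by variety.
#' @export
shared_allele_distance <- function(table) {
  table <- genotype_table(table)
  varieties <- unique(table$variety)
  n <- length(varieties)
  if (n < 2) abort_ssr("shared_allele_distance() needs at least two varieties")
  typed <- dplyr::filter(table, !is.na(.data$allele_a))
  by_var <- split(typed[, c("marker", "allele_a", "allele_b")], typed$variety)
  d <- matrix(0, n, n, dimnames = list(varieties, varieties))
  no_overlap <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      a <- by_var[[varieties[i]]]
      b <- by_var[[varieties[j]]]
      m <- if (is.null(a) || is.null(b)) NULL else
        dplyr::inner_join(a, b, by = "marker", suffix = c("_1", "_2"))
      if (is.null(m) || nrow(m) == 0) {
        d[i, j] <- d[j, i] <- 1
        no_overlap[[length(no_overlap) + 1L]] <- c(varieties[j], varieties[i])
        next
      }
      shared <- mapply(function(a1, b1, a2, b2) {
        g1 <- c(a1, b1)
        g2 <- c(a2, b2)
        sum(pmin(table(factor(g1, levels = unique(c(g1, g2)))),
                 table(factor(g2, levels = unique(c(g1, g2))))))
      }, m$allele_a_1, m$allele_b_1, m$allele_a_2, m$allele_b_2)
      d[i, j] <- d[j, i] <- 1 - sum(shared) / (2 * nrow(m))
    }
  }
  out <- as.dist(d)
  attr(out, "no_overlap_pairs") <- no_overlap
  out
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomeration of a distance matrix into an ultrametric
#' tree (leaf heights are half the merge distances). Built on
#' [stats::hclust()] and returned as an [ape::phylo] object; ties are
#' resolved deterministically by the input label order.
#'
#' @param dist A [stats::dist] object (e.g. from
#'   [shared_allele_distance()]).
#' @param newick_path Optional path; when given the tree is also written
#'   in Newick format.
#' @return An `ape` phylogenetic tree.
#' @export
upgma_tree <- function(dist, newick_path = NULL) {
  if (attr(dist, "Size") < 2) abort_ssr("upgma_tree() needs at least two labels")
  hc <- hclust(dist, method = "average")
  tree <- ape::as.phylo(hc)
  if (!is.null(newick_path)) ape::write.tree(tree, file = newick_path)
  tree
}
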