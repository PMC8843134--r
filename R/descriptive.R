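#' Pearson correlations among trait means
#'
#' Correlation matrix of the three trait means (FY, FL, NRPS) across
#' treatments. Zero-variance traits give `NA` entries with a warning.
#'
#' @param table a `trait_table`.
#' @return symmetric 3 x 3 correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(table) {
  rec <- table$records
  if (nrow(rec) < 3) stop("need at least 3 treatments", call. = FALSE)
  m <- as.matrix(rec[paste0(TRAITS, "_mean")])
  colnames(m) <- toupper(TRAITS)
  degenerate <- apply(m, 2, stats::sd) == 0
  if (any(degenerate)) warning("zero-variance trait(s): correlation undefined")
  suppressWarnings(stats::cor(m))
}

#' UPGMA clustering of z-scored treatment profiles
#'
#' Standardizes each trait column of the treatment-mean matrix to zero
#' mean and unit standard deviation, computes Euclidean distances between
#' treatment profiles, and agglomerates by average linkage (UPGMA), whose
#' merge heights are the average pairwise distances between the merged
#' groups and are therefore non-decreasing. Group labels come from cutting
#' the tree into `groups` clusters.
#'
#' @param table a `trait_table`.
#' @param groups number of groups to cut the tree into (1..n).
#' @return list with `hclust` (the tree), `groups` (integer labels per
#'   treatment), and `profiles` (the z-scored matrix, rownames
#'   `"N/K/Mg"`).
#' @export
upgma_cluster <- function(table, groups = 5L) {
  rec <- table$records
  n <- nrow(rec)
  if (groups < 1 || groups > n) {
    stop("groups must lie in [1, number of treatments]", call. = FALSE)
  }
  m <- as.matrix(rec[paste0(TRAITS, "_mean")])
  colnames(m) <- toupper(TRAITS)
  rownames(m) <- paste(rec$n_g, rec$k_g, rec$mg_g, sep = "/")
  z <- scale(m)
  z[, attr(z, "scaled:scale") == 0] <- 0
  tree <- stats::hclust(stats::dist(z), method = "average")
  list(hclust = tree,
       groups = stats::cutree(tree, k = groups),
       profiles = z)
}
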