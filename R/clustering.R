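# Hierarchical clustering of diseases by their age pattern, using
# correlation distance (d = 1 - Pearson r between disease rows).

#' Cluster diseases by age pattern
#'
#' Computes the pairwise Pearson correlation between disease rows of a
#' normalized age-disease matrix, converts it to the distance
#' `d = 1 - r` (anti-correlated patterns are maximally distant) and runs
#' agglomerative hierarchical clustering. Rows with zero variance are
#' removed first (their correlation is undefined).
#'
#' @param matrix A normalized `age_disease_matrix` with at least two
#'   disease rows (after the minimum-instance filter).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of classes `disease_dendrogram` and `hclust`.
#' @export
cluster_diseases <- function(matrix,
                             linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(matrix, "age_disease_matrix"))
  m <- matrix$counts
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("cluster_diseases: removing zero-variance row(s): ",
            paste(rownames(m)[sds == 0], collapse = ", "))
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) {
    stop("cluster_diseases needs at least two disease rows with variance",
         call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = linkage)
  class(hc) <- c("disease_dendrogram", "hclust")
  hc
}

#' Cut a disease dendrogram into k clusters
#'
#' @param dendrogram A [cluster_diseases()] result.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer vector: disease -> cluster id.
#' @export
cut_diseases <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (k < 1L || k > n) {
    stop("k must lie in 1..", n, " (number of diseases)", call. = FALSE)
  }
  stats::cutree(dendrogram, k = k)
}

#' Export a disease dendrogram as a Newick tree
#'
#' Branch lengths follow the merge heights (each leaf sits at half the
#' height of its last merge), so the tip-to-tip path length between two
#' diseases equals the height at which they were merged.
#'
#' @param dendrogram A [cluster_diseases()] result.
#' @param path Output path, or `NULL` to return the Newick string.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_dendrogram <- function(dendrogram, path = NULL) {
  hc <- dendrogram
  class(hc) <- "hclust"
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
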