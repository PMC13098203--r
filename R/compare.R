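## Cohort comparison: reaction presence/absence, distances, hierarchical
## clustering, pathway-completeness queries. Restored disconnected
## reactions count as present — they cannot carry flux, but they are
## genomic evidence and belong in a content comparison.

#' Strain x reaction presence matrix
#' @param pan a [PanModel].
#' @return logical matrix (strains x union reactions).
#' @export
presenceMatrix <- function(pan) pan@presence

#' Pairwise reaction distance between strains
#'
#' `jaccard` (default): 1 - |intersection| / |union| of reaction sets —
#' the standard metric for binary trait matrices. `hamming`: fraction of
#' reactions on which two strains disagree.
#'
#' @param presence logical presence matrix (strains in rows).
#' @param metric `"jaccard"` or `"hamming"`.
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
reactionDistance <- function(presence, metric = c("jaccard", "hamming")) {
  metric <- match.arg(metric)
  if (nrow(presence) < 2L) stop("need at least two strains")
  d <- switch(metric,
    jaccard = stats::dist(presence * 1, method = "binary"),
    hamming = stats::dist(presence * 1, method = "manhattan") / ncol(presence))
  as.matrix(d)
}

#' Hierarchical clustering of strains by reaction distance
#'
#' Deterministic agglomerative clustering; strain order in the distance
#' matrix is the only tie-break, so permuting input strains permutes
#' leaves but not the partition.
#'
#' @param dmat distance matrix from [reactionDistance()].
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @return an `hclust` object.
#' @export
clusterStrains <- function(dmat, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(stats::as.dist(dmat), method = method)
}

#' Cut a strain dendrogram into k groups
#' @param hc an `hclust` from [clusterStrains()].
#' @param k number of groups.
#' @return named integer vector of cluster labels.
#' @export
cutStrains <- function(hc, k) stats::cutree(hc, k = k)

#' Export a strain dendrogram as Newick
#' @param hc an `hclust`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Which reactions of a pathway does a model carry?
#'
#' Simple membership query used e.g. to find the missing final step of a
#' biosynthesis pathway across a cohort.
#'
#' @param model a [GEM].
#' @param reactionIds pathway reaction ids.
#' @return list with `present`, `missing`, `complete`.
#' @export
pathwayCompleteness <- function(model, reactionIds) {
  present <- intersect(reactionIds, model@reactions$id)
  missing <- setdiff(reactionIds, model@reactions$id)
  list(present = present, missing = missing, complete = !length(missing))
}
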