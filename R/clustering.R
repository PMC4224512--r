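# Hierarchical clustering of per-group ddCt profiles: do the most severe
# injury grades resemble each other?

#' Clustering configuration
#'
#' @param distance \code{"euclidean"} or \code{"correlation"}
#'   (1 - Pearson r).
#' @param linkage \code{"average"}, \code{"complete"} or \code{"ward"}
#'   (Ward's D2).
#' @return list of class \code{cluster_config}.
#' @export
cluster_config <- function(distance = c("euclidean", "correlation"),
                           linkage = c("average", "complete", "ward")) {
  structure(list(distance = match.arg(distance), linkage = match.arg(linkage)),
            class = "cluster_config")
}

#' Per-group ddCt profiles
#'
#' Builds the group-level ddCt profile matrix fed to
#' \code{\link{cluster_groups}}: for every injury group, the per-target
#' mean normalized dCt difference against the calibrator, restricted to
#' targets with \code{"valid"} status in \emph{every} group (capped
#' substitutions would distort distances). The number of targets dropped
#' for non-valid status is recorded in attribute \code{"n_dropped"}.
#'
#' @param matrix a \code{\link{ct_matrix}}.
#' @param design a \code{\link{group_design}}.
#' @param det detection thresholds.
#' @param center centering statistic for normalization.
#' @return numeric matrix, targets x injury groups.
#' @export
ddct_profiles <- function(matrix, design, det = detection_thresholds(),
                          center = "mean") {
  de <- run_de_all(matrix, design, det = det, center = center)
  valid <- lapply(de, function(d) d$target[d$ct_status == "valid"])
  shared <- Reduce(intersect, valid)
  if (!length(shared)) stop("no target has valid status in every group")
  prof <- vapply(de, function(d) d$mean_ddct[match(shared, d$target)],
                 numeric(length(shared)))
  prof <- matrix(prof, nrow = length(shared),
                 dimnames = list(shared, names(de)))
  attr(prof, "n_dropped") <- length(Reduce(union, valid)) - length(shared)
  prof
}

#' Hierarchically cluster group profiles
#'
#' Agglomerative clustering of the per-group ddCt profile vectors. Groups
#' are ordered by name before the distance computation so the merge tree is
#' stable under permutation of the input columns.
#'
#' @param profiles numeric matrix, targets x groups (>= 2 groups), e.g. from
#'   \code{\link{ddct_profiles}}; or a named list of equal-length target
#'   vectors.
#' @param config a \code{\link{cluster_config}}.
#' @return list of class \code{group_clustering} with \code{hclust} (the
#'   \code{stats::hclust} tree over groups), \code{merges} (data.frame of
#'   merge heights), \code{first_merge} (the two labels joined first) and
#'   \code{newick} (Newick string with branch lengths).
#' @export
cluster_groups <- function(profiles, config = cluster_config()) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(cbind, profiles)
  if (ncol(profiles) < 2L) stop("need at least two groups to cluster")
  profiles <- profiles[stats::complete.cases(profiles), , drop = FALSE]
  if (!nrow(profiles)) stop("no shared targets across group profiles")
  profiles <- profiles[, order(colnames(profiles)), drop = FALSE]
  x <- t(profiles)
  d <- switch(config$distance,
              euclidean = stats::dist(x),
              correlation = stats::as.dist(1 - stats::cor(profiles)))
  method <- switch(config$linkage, average = "average",
                   complete = "complete", ward = "ward.D2")
  hc <- stats::hclust(d, method = method)
  labs <- hc$labels
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       height = hc$height,
                       members = vapply(seq_len(nrow(hc$merge)), function(i)
                         paste(sort(labs[.tree_members(hc$merge, i)]),
                               collapse = ","), character(1L)))
  first <- sort(labs[-hc$merge[1L, ]])
  nwk <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, merges = merges, first_merge = first,
                 newick = nwk, config = config),
            class = "group_clustering")
}

.tree_members <- function(merge, i) {
  row <- merge[i, ]
  unlist(lapply(row, function(v)
    if (v < 0) -v else .tree_members(merge, v)))
}

#' @export
print.group_clustering <- function(x, ...) {
  cat("group_clustering (", x$config$distance, "/", x$config$linkage,
      "): first merge {", paste(x$first_merge, collapse = ", "), "}\n",
      sep = "")
  cat(x$newick, "\n")
  invisible(x)
}
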