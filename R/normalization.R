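# Per-sample centering of Ct values (global-mean and reference-gene modes).

#' Global (mean-centering) normalization
#'
#' Implements global mean normalization for array-scale qPCR: each sample is
#' centered on the average Ct of the targets that are detected (finite Ct
#' below \code{ct_max}) in \emph{every} sample, so all samples are centered
#' on the identical target set and dropout cannot bias the centering.
#' \eqn{\Delta Ct(t,s) = Ct(t,s) - c(s)} where \eqn{c(s)} is the mean (or
#' median) Ct of the normalization set in sample \eqn{s}. Undetected cells
#' stay undetected; finite cells outside the normalization set are still
#' centered.
#'
#' @param matrix a \code{\link{ct_matrix}}.
#' @param thresholds a \code{\link{detection_thresholds}} supplying
#'   \code{ct_max}.
#' @param center \code{"mean"} (the cited global-mean method) or
#'   \code{"median"} for a robust variant.
#' @return A \code{norm_matrix}: list with \code{dct} (numeric matrix, same
#'   shape, \code{NA} = undetected), \code{norm_set} (targets used for
#'   centering) and \code{center}.
#' @export
global_normalize <- function(matrix, thresholds = detection_thresholds(),
                             center = c("mean", "median")) {
  stopifnot(inherits(matrix, "ct_matrix"))
  center <- match.arg(center)
  detected <- !is.na(matrix$ct) & matrix$ct < thresholds$ct_max
  norm_set <- targets(matrix)[rowSums(detected) == ncol(matrix$ct)]
  if (!length(norm_set))
    stop("empty normalization set: no target is detected in all samples; ",
         "review detection thresholds")
  centering <- apply(matrix$ct[norm_set, , drop = FALSE], 2L,
                     if (center == "mean") mean else stats::median)
  dct <- sweep(matrix$ct, 2L, centering, `-`)
  structure(list(dct = dct, norm_set = norm_set, center = center),
            class = "norm_matrix")
}

#' Reference-gene (endogenous control) normalization
#'
#' Centers each sample on the mean Ct of designated reference targets, as
#' used in singleplex validation assays against stable endogenous controls.
#' Every reference must be detected (finite) in every sample.
#'
#' @param matrix a \code{\link{ct_matrix}}.
#' @param references character vector of reference target names.
#' @return A \code{norm_matrix} (see \code{\link{global_normalize}}).
#' @export
reference_normalize <- function(matrix, references) {
  stopifnot(inherits(matrix, "ct_matrix"))
  references <- normalize_target_name(references)
  missing <- setdiff(references, targets(matrix))
  if (length(missing)) stop("unknown reference target(s): ",
                            paste(missing, collapse = ", "))
  ref_ct <- matrix$ct[references, , drop = FALSE]
  und <- colSums(is.na(ref_ct)) > 0L
  if (any(und))
    stop("reference undetected in sample(s): ",
         paste(samples(matrix)[und], collapse = ", "))
  dct <- sweep(matrix$ct, 2L, colMeans(ref_ct), `-`)
  structure(list(dct = dct, norm_set = references, center = "mean"),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix: %d targets x %d samples, %s-centered on %d targets\n",
              nrow(x$dct), ncol(x$dct), x$center, length(x$norm_set)))
  invisible(x)
}

#' Write a normalized matrix in long format
#'
#' Mirrors the long input dialect with an added \code{dct} column; the
#' normalization set is written to \code{<path>.norm_set.txt}.
#'
#' @param x a \code{norm_matrix}.
#' @param path output TSV path.
#' @export
write_norm_long <- function(x, path) {
  stopifnot(inherits(x, "norm_matrix"))
  df <- data.frame(
    sample = rep(colnames(x$dct), each = nrow(x$dct)),
    target = rep(rownames(x$dct), times = ncol(x$dct)),
    dct = as.vector(x$dct),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(x$norm_set, paste0(path, ".norm_set.txt"))
  invisible(path)
}
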