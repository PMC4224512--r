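# Stepwise selection of stably expressed targets usable as endogenous
# controls for singleplex validation.

#' Stability criteria for endogenous-control selection
#'
#' @param sd_max maximum Ct standard deviation across all samples (default 1
#'   cycle).
#' @param mean_median_max maximum |mean - median| Ct, screening for outlier
#'   skew (default 0.5 cycles).
#' @param ct_window inclusive mean-Ct abundance window (default c(14, 20),
#'   ensuring abundant expression).
#' @return list of class \code{stability_criteria}.
#' @export
stability_criteria <- function(sd_max = 1, mean_median_max = 0.5,
                               ct_window = c(14, 20)) {
  if (!(sd_max > 0)) stop("sd_max must be positive")
  if (mean_median_max < 0) stop("mean_median_max must be >= 0")
  if (length(ct_window) != 2L || !(ct_window[1L] < ct_window[2L]))
    stop("ct_window must be an increasing pair")
  structure(list(sd_max = sd_max, mean_median_max = mean_median_max,
                 ct_window = ct_window), class = "stability_criteria")
}

#' Select stably expressed reference targets
#'
#' Applies the stepwise screen over raw Ct across \emph{all} samples,
#' injured and calibrator alike: (1) eliminate targets with SD above
#' \code{sd_max}; (2) of the rest, eliminate targets whose mean and median
#' Ct differ by more than \code{mean_median_max}; (3) of the rest, keep
#' targets whose mean Ct lies inside \code{ct_window} (inclusive). Targets
#' undetected in any sample are ineligible - stability across every sample
#' is the point of an endogenous control. Each step's pass flag is retained
#' so the report shows where a target fell out.
#'
#' @param matrix a \code{\link{ct_matrix}}.
#' @param criteria a \code{\link{stability_criteria}}.
#' @return data.frame of class \code{stability_report}: target, n_detected,
#'   mean_ct, median_ct, sd_ct, pass_sd, pass_mm, pass_window, pass; ordered
#'   with passing targets first by ascending SD. Attribute
#'   \code{"references"} holds the passing targets in rank order.
#' @export
select_stable_references <- function(matrix, criteria = stability_criteria()) {
  stopifnot(inherits(matrix, "ct_matrix"))
  ct <- matrix$ct
  n_det <- rowSums(!is.na(ct))
  eligible <- n_det == ncol(ct)
  mean_ct <- rowMeans(ct)
  med_ct <- apply(ct, 1L, stats::median)
  sd_ct <- apply(ct, 1L, stats::sd)
  pass_sd <- eligible & sd_ct <= criteria$sd_max
  pass_mm <- pass_sd & abs(mean_ct - med_ct) <= criteria$mean_median_max
  pass_win <- pass_mm & mean_ct >= criteria$ct_window[1L] &
    mean_ct <= criteria$ct_window[2L]
  out <- data.frame(target = targets(matrix), n_detected = n_det,
                    mean_ct = mean_ct, median_ct = med_ct, sd_ct = sd_ct,
                    pass_sd = pass_sd, pass_mm = pass_mm,
                    pass_window = pass_win, pass = pass_win,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(!out$pass, out$sd_ct, out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "references") <- out$target[out$pass]
  class(out) <- c("stability_report", class(out))
  out
}

#' Write a stability report
#'
#' @param x a \code{stability_report}.
#' @param path output TSV path.
#' @export
write_stability_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
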