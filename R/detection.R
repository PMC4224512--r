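# Per-group expression filtering and Ct-status classification.

#' Detection thresholds
#'
#' @param ct_max detection ceiling in cycles: a replicate counts as detected
#'   only when its Ct is strictly below this (default 36).
#' @param max_failures number of undetected / at-or-over-ceiling replicates a
#'   group may contain and still be called expressed. The default 0 encodes
#'   the "1 or more failure in n replicates disqualifies" rule.
#' @param ct_cap substitution ceiling used downstream when computing fold
#'   changes for targets absent in one group (default 40, the last PCR cycle).
#' @return list of class \code{detection_thresholds}.
#' @export
detection_thresholds <- function(ct_max = 36, max_failures = 0L, ct_cap = 40) {
  if (!(ct_max < ct_cap)) stop("ct_max must be below ct_cap")
  if (max_failures < 0) stop("max_failures must be >= 0")
  structure(list(ct_max = ct_max, max_failures = as.integer(max_failures),
                 ct_cap = ct_cap),
            class = "detection_thresholds")
}

#' Is a target expressed in a replicate group?
#'
#' A replicate fails when it is undetected (\code{NA}) or its Ct is at or
#' above \code{ct_max}; the target is expressed when the number of failing
#' replicates does not exceed \code{max_failures}. With the defaults this is
#' "Ct < 36 in every replicate". Note the boundary: Ct exactly 36.0 is a
#' failure.
#'
#' @param group_cts numeric vector of replicate Ct values; \code{NA} =
#'   undetected.
#' @param thresholds a \code{\link{detection_thresholds}}.
#' @return logical flag.
#' @export
is_expressed <- function(group_cts, thresholds = detection_thresholds()) {
  if (!length(group_cts)) stop("empty replicate list")
  sum(is.na(group_cts) | group_cts >= thresholds$ct_max) <= thresholds$max_failures
}

# vectorized over targets: rows of a Ct submatrix
.expressed_flags <- function(ct, thresholds) {
  rowSums(is.na(ct) | ct >= thresholds$ct_max) <= thresholds$max_failures
}

#' Ct status of a target in an injury-vs-calibrator comparison
#'
#' Combines the two per-group expressed flags: \code{"valid"} when the target
#' is detected in both groups, \code{"calibrator_not_detected"} when absent
#' in the sham (calibrator) group only, \code{"target_not_detected"} when
#' absent in the injured group only, and \code{"excluded"} when absent in
#' both (such targets carry no quantity and are dropped before DE).
#'
#' @param sham_expressed,injured_expressed logical flags (vectorized).
#' @return character vector over
#'   \code{c("valid", "calibrator_not_detected", "target_not_detected",
#'   "excluded")}.
#' @export
ct_status <- function(sham_expressed, injured_expressed) {
  ifelse(sham_expressed,
         ifelse(injured_expressed, "valid", "target_not_detected"),
         ifelse(injured_expressed, "calibrator_not_detected", "excluded"))
}

#' Count expressed targets over a sample set
#'
#' @param matrix a \code{\link{ct_matrix}}.
#' @param sample_set sample ids (must exist in the matrix).
#' @param thresholds a \code{\link{detection_thresholds}}.
#' @return integer count of targets expressed across the given samples.
#' @export
expressed_count <- function(matrix, sample_set,
                            thresholds = detection_thresholds()) {
  stopifnot(inherits(matrix, "ct_matrix"))
  if (!length(sample_set)) stop("empty sample set")
  unknown <- setdiff(sample_set, samples(matrix))
  if (length(unknown)) stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  sum(.expressed_flags(matrix$ct[, sample_set, drop = FALSE], thresholds))
}

#' Per-target, per-group detection report
#'
#' @param matrix a \code{\link{ct_matrix}}.
#' @param design a \code{\link{group_design}}.
#' @param thresholds a \code{\link{detection_thresholds}}.
#' @return data.frame with columns target, group, n_detected, expressed,
#'   ct_status (status is relative to the calibrator group; for the
#'   calibrator itself it is \code{NA}).
#' @export
detection_report <- function(matrix, design,
                             thresholds = detection_thresholds()) {
  stopifnot(inherits(matrix, "ct_matrix"), inherits(design, "group_design"))
  groups <- c(design$calibrator, injury_groups(design))
  cal_ct <- matrix$ct[, group_samples(design, design$calibrator), drop = FALSE]
  cal_expr <- .expressed_flags(cal_ct, thresholds)
  out <- lapply(groups, function(g) {
    sub <- matrix$ct[, group_samples(design, g), drop = FALSE]
    expr <- .expressed_flags(sub, thresholds)
    data.frame(
      target = targets(matrix), group = g,
      n_detected = rowSums(!is.na(sub) & sub < thresholds$ct_max),
      expressed = expr,
      ct_status = if (g == design$calibrator) NA_character_
                  else ct_status(cal_expr, expr),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
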