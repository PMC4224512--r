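# Comparative-Ct (2^-ddCt) relative quantitation against the calibrator
# group, replicate-level significance testing and significance calling.

#' Differential-expression thresholds
#'
#' @param fold_min minimum fold modulation in either direction (default 1.5;
#'   a call requires |log10 RQ| >= log10(fold_min)).
#' @param alpha p-value cutoff (default 0.05, uncorrected).
#' @return list of class \code{de_thresholds}.
#' @export
de_thresholds <- function(fold_min = 1.5, alpha = 0.05) {
  if (!(fold_min > 1)) stop("fold_min must exceed 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  structure(list(fold_min = fold_min, alpha = alpha), class = "de_thresholds")
}

#' Substitute undetected / over-cap Ct values
#'
#' For targets absent in one group, the fold change is computed on raw Ct
#' with undetected reactions set to the cap (the final PCR cycle, 40) and
#' observed values above the cap clipped to it; detected values below the
#' cap are kept as-is.
#'
#' @param ct numeric vector; \code{NA} = undetected.
#' @param cap ceiling in cycles (default 40).
#' @return numeric vector with no \code{NA}.
#' @export
substitute_undetected <- function(ct, cap = 40) {
  if (!(cap > 0)) stop("cap must be positive")
  pmin(ifelse(is.na(ct), cap, ct), cap)
}

#' Relative quantity from replicate dCt values
#'
#' \eqn{\Delta\Delta Ct = \overline{\Delta Ct}_{injured} -
#' \overline{\Delta Ct}_{sham}}, \eqn{RQ = 2^{-\Delta\Delta Ct}} and its
#' log10. One cycle fewer in the injured group doubles the relative quantity.
#'
#' @param injured_dct,sham_dct numeric replicate vectors (no \code{NA}).
#' @return list with \code{mean_ddct}, \code{rq}, \code{log10_rq}.
#' @export
relative_quantitation <- function(injured_dct, sham_dct) {
  if (!length(injured_dct) || !length(sham_dct)) stop("empty replicate list")
  if (anyNA(injured_dct) || anyNA(sham_dct)) stop("NA in replicate values")
  mean_ddct <- mean(injured_dct) - mean(sham_dct)
  rq <- 2^(-mean_ddct)
  list(mean_ddct = mean_ddct, rq = rq, log10_rq = log10(rq))
}

# Row-wise Welch (or pooled) two-sample t on two matrices with equal row sets.
# Returns p-values; degenerate rows (both groups constant) get p = 1 when the
# means agree and a 0-adjacent sentinel when they differ, with a warning.
.row_t_p <- function(x, y, var_equal = FALSE) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep_len(n1 + n2 - 2L, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  p <- 2 * stats::pt(abs(m1 - m2) / sqrt(se2), df, lower.tail = FALSE)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, .Machine$double.xmin)
    warning(sum(degen), " comparison(s) with zero variance in both groups; ",
            "p set to 1 (equal means) or to a 0-adjacent sentinel")
  }
  p
}

#' Two-sample test of a group difference
#'
#' Unpaired two-tailed Welch t-test on replicate dCt (or substituted T)
#' values; \code{var_equal = TRUE} switches to the pooled-variance test.
#' When both groups are constant the t statistic is undefined: equal
#' constants return p = 1, unequal constants a 0-adjacent sentinel, each
#' with a warning.
#'
#' @param injured_dct,sham_dct numeric replicate vectors (>= 2 values each).
#' @param var_equal pool the variances?
#' @return two-tailed p-value in [0, 1].
#' @export
test_group_difference <- function(injured_dct, sham_dct, var_equal = FALSE) {
  if (length(injured_dct) < 2L || length(sham_dct) < 2L)
    stop("need at least two replicates per group")
  .row_t_p(matrix(injured_dct, 1L), matrix(sham_dct, 1L), var_equal)
}

#' Significance call from fold change and p-value
#'
#' A target is significantly modulated when |log10 RQ| >= log10(fold_min)
#' (to within 1e-12, guarding the binary representation of the threshold)
#' and p < alpha. Direction follows the sign of log10 RQ for significant
#' targets and is \code{"none"} otherwise.
#'
#' @param log10_rq numeric vector of log10 fold changes.
#' @param p_value parallel vector of p-values.
#' @param thresholds a \code{\link{de_thresholds}}.
#' @return data.frame with logical \code{significant} and character
#'   \code{direction} (\code{"up"}, \code{"down"}, \code{"none"}).
#' @export
call_significant <- function(log10_rq, p_value, thresholds = de_thresholds()) {
  sig <- abs(log10_rq) >= log10(thresholds$fold_min) - 1e-12 &
    p_value < thresholds$alpha
  data.frame(significant = sig,
             direction = ifelse(!sig, "none", ifelse(log10_rq > 0, "up", "down")),
             stringsAsFactors = FALSE)
}

#' Differential expression of one injury group against the calibrator
#'
#' For each non-excluded target: detection status is classified per group
#' (\code{\link{ct_status}}); \code{"valid"} targets are quantified on
#' globally normalized dCt restricted to the samples of the two groups
#' being compared (so every sample is centered on the same commonly
#' detected target set); targets absent in one group
#' (\code{calibrator_not_detected} / \code{target_not_detected}) are
#' quantified on raw Ct after \code{\link{substitute_undetected}} with the
#' cap, without normalization. The p-value is a two-tailed
#' \code{\link{test_group_difference}} on the same replicate values that the
#' fold change uses.
#'
#' @param matrix a \code{\link{ct_matrix}}.
#' @param design a \code{\link{group_design}}.
#' @param group injury-group label (must differ from the calibrator).
#' @param det detection thresholds.
#' @param de DE thresholds.
#' @param var_equal pooled-variance t instead of Welch.
#' @param center centering statistic for \code{\link{global_normalize}}.
#' @param p_adjust \code{"none"} (default; raw p-values against alpha) or
#'   \code{"BH"} for Benjamini-Hochberg across the group's tested targets.
#' @return data.frame of class \code{de_result}: one row per non-excluded
#'   target with target, group, ct_status, mean_ddct, rq, log10_rq, p_value,
#'   significant, direction.
#' @export
run_de <- function(matrix, design, group,
                   det = detection_thresholds(), de = de_thresholds(),
                   var_equal = FALSE, center = "mean",
                   p_adjust = c("none", "BH")) {
  stopifnot(inherits(matrix, "ct_matrix"), inherits(design, "group_design"))
  p_adjust <- match.arg(p_adjust)
  if (group == design$calibrator) stop("group must differ from the calibrator")
  inj_s <- group_samples(design, group)
  cal_s <- group_samples(design, design$calibrator)

  inj_raw <- matrix$ct[, inj_s, drop = FALSE]
  cal_raw <- matrix$ct[, cal_s, drop = FALSE]
  status <- ct_status(.expressed_flags(cal_raw, det),
                      .expressed_flags(inj_raw, det))
  keep <- status != "excluded"
  tg <- targets(matrix)[keep]
  status <- status[keep]

  # valid targets: normalized dCt over just the two groups' samples
  pair <- ct_matrix(matrix$ct[, c(inj_s, cal_s), drop = FALSE],
                    unname(matrix$panel))
  norm <- global_normalize(pair, det, center = center)
  dct_inj <- norm$dct[tg, inj_s, drop = FALSE]
  dct_cal <- norm$dct[tg, cal_s, drop = FALSE]

  # absent-in-one-group targets: substituted raw Ct, unnormalized
  sub_inj <- substitute_undetected(inj_raw[tg, , drop = FALSE], det$ct_cap)
  sub_cal <- substitute_undetected(cal_raw[tg, , drop = FALSE], det$ct_cap)
  nd <- status != "valid"
  use_inj <- dct_inj; use_cal <- dct_cal
  use_inj[nd, ] <- sub_inj[nd, ]
  use_cal[nd, ] <- sub_cal[nd, ]

  mean_ddct <- rowMeans(use_inj) - rowMeans(use_cal)
  p <- .row_t_p(use_inj, use_cal, var_equal)
  if (p_adjust == "BH") p <- stats::p.adjust(p, "BH")
  rq <- 2^(-mean_ddct)
  log10_rq <- log10(rq)
  call <- call_significant(log10_rq, p, de)
  out <- data.frame(target = tg, group = group, ct_status = status,
                    mean_ddct = mean_ddct, rq = rq, log10_rq = log10_rq,
                    p_value = p, significant = call$significant,
                    direction = call$direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", class(out))
  out
}

#' Differential expression of every injury group
#'
#' @inheritParams run_de
#' @return named list of \code{de_result} data.frames, one per injury group
#'   (design order).
#' @export
run_de_all <- function(matrix, design,
                       det = detection_thresholds(), de = de_thresholds(),
                       var_equal = FALSE, center = "mean",
                       p_adjust = c("none", "BH")) {
  groups <- injury_groups(design)
  stats::setNames(
    lapply(groups, function(g)
      run_de(matrix, design, g, det = det, de = de, var_equal = var_equal,
             center = center, p_adjust = p_adjust)),
    groups)
}

#' Write a DE report
#'
#' Columns mirror the published per-group tables: target, group, ct_status,
#' p_value, log10_rq (plus the full quantities).
#'
#' @param x a \code{de_result}.
#' @param path output TSV path.
#' @export
write_de_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
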