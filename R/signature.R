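# Cross-group set operations: per-group significant sets, Venn regions,
# the common signature and its direction split.

.sig_frame <- function(df) {
  # accept de_result frames or fixture frames; default everything significant
  if (!all(c("target", "log10_rq") %in% names(df)))
    stop("each group table needs columns target and log10_rq")
  if (is.null(df$significant)) df$significant <- TRUE
  df$target <- normalize_target_name(df$target)
  df
}

#' Per-group significant target sets
#'
#' @param de_list named list of per-group DE tables (\code{de_result} or any
#'   data.frame with \code{target}, \code{log10_rq} and optionally
#'   \code{significant}).
#' @return named list of character vectors.
#' @export
significant_sets <- function(de_list) {
  if (!length(de_list) || is.null(names(de_list)))
    stop("de_list must be a non-empty named list")
  lapply(de_list, function(df) {
    df <- .sig_frame(df)
    df$target[df$significant]
  })
}

#' Intersect per-group significant sets into a common signature
#'
#' The common signature is the set of targets significantly modulated in
#' every group. Targets are ordered deterministically by descending mean
#' |log10 RQ| across groups, ties broken by name. Direction consistency
#' (same sign of log10 RQ in every group) is assessed per common target.
#'
#' @param de_list named list of per-group DE tables (see
#'   \code{\link{significant_sets}}).
#' @return A \code{signature_result}: list with \code{per_group_sets},
#'   \code{common} (ordered character vector), \code{per_group_log10_rq}
#'   (matrix common x groups), \code{per_group_direction} (same shape,
#'   "up"/"down"), \code{consistent} (named logical), \code{n_up},
#'   \code{n_down} (over direction-consistent targets) and
#'   \code{inconsistent} (names).
#' @export
intersect_significant <- function(de_list) {
  sets <- significant_sets(de_list)
  common <- Reduce(intersect, sets)
  frames <- lapply(de_list, .sig_frame)
  if (length(common)) {
    vals <- vapply(frames, function(df)
      df$log10_rq[match(common, df$target)], numeric(length(common)))
    vals <- matrix(vals, nrow = length(common),
                   dimnames = list(common, names(de_list)))
    ord <- order(-rowMeans(abs(vals)), common)
    common <- common[ord]
    vals <- vals[ord, , drop = FALSE]
  } else {
    vals <- matrix(numeric(0), 0L, length(de_list),
                   dimnames = list(NULL, names(de_list)))
  }
  dir <- ifelse(vals > 0, "up", "down")
  consistent <- apply(vals, 1L, function(v) all(v > 0) || all(v < 0))
  consistent <- stats::setNames(as.logical(consistent), common)
  up <- consistent & rowMeans(vals) > 0
  structure(list(per_group_sets = sets, common = common,
                 per_group_log10_rq = vals, per_group_direction = dir,
                 consistent = consistent,
                 n_up = sum(up), n_down = sum(consistent & !up),
                 inconsistent = common[!consistent]),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result: %d group(s); common signature %d (%d up / %d down%s)\n",
              length(x$per_group_sets), length(x$common), x$n_up, x$n_down,
              if (length(x$inconsistent))
                paste0(", ", length(x$inconsistent), " direction-inconsistent")
              else ""))
  invisible(x)
}

#' Venn region counts over up to five sets
#'
#' Counts every non-empty membership region (2^k - 1 regions for k sets);
#' the counts partition the union. Region names join the member groups with
#' \code{"&"}.
#'
#' @param sets named list of 1-5 character vectors.
#' @return named integer vector over all membership regions.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 1L || k > 5L) stop("venn_counts supports 1-5 sets")
  if (is.null(names(sets))) stop("sets must be named")
  all_t <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_t %in% s, logical(length(all_t)))
  member <- matrix(member, nrow = length(all_t))
  out <- integer(0)
  for (m in seq_len(2^k - 1L)) {
    bits <- as.logical(bitwAnd(m, 2^(seq_len(k) - 1L)))
    region <- paste(names(sets)[bits], collapse = "&")
    inside <- rowSums(member[, bits, drop = FALSE]) == sum(bits) &
      rowSums(member[, !bits, drop = FALSE]) == 0L
    out[region] <- sum(inside)
  }
  out
}

#' Up/down split of the direction-consistent common signature
#'
#' @param common character vector of common targets, or a
#'   \code{signature_result}.
#' @param de_list named list of per-group DE tables (ignored when a
#'   \code{signature_result} is given).
#' @return list with \code{n_up}, \code{n_down} and \code{inconsistent}
#'   (targets whose direction differs between groups, excluded from both
#'   counts).
#' @export
direction_split <- function(common, de_list = NULL) {
  sig <- if (inherits(common, "signature_result")) common
         else {
           frames <- lapply(de_list, function(df) {
             df <- .sig_frame(df)
             miss <- setdiff(normalize_target_name(common), df$target)
             if (length(miss))
               stop("missing direction for target(s): ", paste(miss, collapse = ", "))
             df[df$target %in% normalize_target_name(common), , drop = FALSE]
           })
           intersect_significant(frames)
         }
  list(n_up = sig$n_up, n_down = sig$n_down, inconsistent = sig$inconsistent)
}

#' Assemble the common-signature table
#'
#' One row per common target with the per-group log10 fold values taken
#' unchanged from the per-group DE tables, in the deterministic order of
#' \code{\link{intersect_significant}}.
#'
#' @param common character vector of common targets, or a
#'   \code{signature_result}.
#' @param de_list named list of per-group DE tables (ignored when a
#'   \code{signature_result} is given).
#' @return data.frame: \code{mirna} plus one log10 RQ column per group.
#' @export
assemble_signature_table <- function(common, de_list = NULL) {
  if (inherits(common, "signature_result")) {
    sig <- common
  } else {
    common <- normalize_target_name(common)
    frames <- lapply(de_list, function(df) {
      df <- .sig_frame(df)
      df[df$target %in% common, , drop = FALSE]
    })
    sig <- intersect_significant(frames)
  }
  out <- data.frame(mirna = sig$common, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(sig$per_group_log10_rq, row.names = NULL))
  rownames(out) <- NULL
  out
}
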