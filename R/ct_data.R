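# Data model and I/O for raw Ct matrices from two-panel TaqMan miRNA arrays.

#' Construct a Ct matrix
#'
#' A \code{ct_matrix} holds raw threshold-cycle (Ct) values as a numeric
#' targets-by-samples matrix in which \code{NA} marks an undetected
#' (\dQuote{Undetermined}) reaction, plus the panel (plate) of origin of each
#' target. Undetected stays an explicit state throughout filtering and
#' normalization; it is only replaced by a numeric ceiling inside the fold
#' computation (see \code{\link{substitute_undetected}}).
#'
#' @param ct numeric matrix, targets in rows (rownames = target names),
#'   samples in columns (colnames = sample ids); \code{NA} = undetected.
#' @param panel character vector of panel labels, one per target (recycled if
#'   length one). Defaults to \code{"A"}.
#' @return An object of class \code{ct_matrix}.
#' @export
ct_matrix <- function(ct, panel = "A") {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have target rownames and sample colnames")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate target names: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop("duplicate sample ids")
  rownames(ct) <- normalize_target_name(rownames(ct))
  if (anyDuplicated(rownames(ct)))
    stop("targets collide after name canonicalization")
  panel <- rep_len(as.character(panel), nrow(ct))
  names(panel) <- rownames(ct)
  structure(list(ct = ct, panel = panel), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d targets x %d samples (%d undetected cells, panels: %s)\n",
              nrow(x$ct), ncol(x$ct), sum(is.na(x$ct)),
              paste(unique(x$panel), collapse = "/")))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

targets <- function(x) rownames(x$ct)
samples <- function(x) colnames(x$ct)

#' Canonicalize miRNA target names
#'
#' Trims surrounding whitespace and rewrites a trailing \code{"#"} sigil as
#' \code{"*"}: both denote the passenger (star) strand of a miRNA duplex and
#' array exports mix the two spellings, which would otherwise break set
#' operations across groups. Species prefixes (\code{hsa-}, \code{mmu-},
#' \code{rno-}) are preserved: same-number miRNAs from different species are
#' distinct assay targets. Idempotent.
#'
#' @param raw character vector of target names.
#' @return character vector of canonical names.
#' @examples
#' normalize_target_name("hsa-miR-106b#")  # "hsa-miR-106b*"
#' @export
normalize_target_name <- function(raw) {
  raw <- trimws(as.character(raw))
  if (any(!nzchar(raw)) || anyNA(raw))
    stop("empty target name")
  sub("#$", "*", raw)
}

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a long-format Ct table
#'
#' Reads an exported Ct table with columns \code{sample}, \code{target},
#' \code{ct}, \code{panel} (comma- or tab-delimited, sniffed from the header
#' line). Cells equal to \code{undetected_token} become undetected.
#'
#' @param path file path.
#' @param undetected_token text marking a reaction that never crossed
#'   threshold (default \code{"Undetermined"}, the instrument convention).
#' @return A \code{\link{ct_matrix}}.
#' @export
read_ct_long <- function(path, undetected_token = "Undetermined") {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE, quote = "\"", comment.char = "")
  need <- c("sample", "target", "ct", "panel")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  df$target <- normalize_target_name(df$target)
  key <- paste(df$sample, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (sample, target) row: (%s, %s)", d$sample, d$target))
  }
  is_und <- df$ct == undetected_token
  ct_num <- suppressWarnings(as.numeric(df$ct))
  bad <- which(!is_und & is.na(ct_num))
  if (length(bad))
    stop(sprintf("unparsable ct value '%s' at data line %d", df$ct[bad[1L]], bad[1L]))
  tg <- unique(df$target)
  sm <- unique(df$sample)
  m <- matrix(NA_real_, length(tg), length(sm), dimnames = list(tg, sm))
  m[cbind(match(df$target, tg), match(df$sample, sm))] <-
    ifelse(is_und, NA_real_, ct_num)
  panel <- df$panel[!duplicated(df$target)]
  ct_matrix(m, panel)
}

#' Write a Ct matrix in long format
#'
#' Inverse of \code{\link{read_ct_long}}: every (target, sample) cell becomes
#' one row; undetected cells are written as \code{undetected_token}. A read
#' back of the output reproduces the cell set bit-exactly.
#'
#' @param x a \code{ct_matrix}.
#' @param path output file path.
#' @param undetected_token marker text for undetected cells.
#' @param sep field delimiter.
#' @export
write_ct_long <- function(x, path, undetected_token = "Undetermined", sep = ",") {
  stopifnot(inherits(x, "ct_matrix"))
  df <- data.frame(
    sample = rep(samples(x), each = nrow(x$ct)),
    target = rep(targets(x), times = ncol(x$ct)),
    ct = ifelse(is.na(as.vector(x$ct)), undetected_token,
                format(as.vector(x$ct), digits = 17, trim = TRUE, scientific = FALSE)),
    panel = rep(unname(x$panel), times = ncol(x$ct)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge the two array panels of a sample set
#'
#' Low-density miRNA arrays split the panel over two plates (Pool A / Pool B)
#' run on the same samples; this stacks the two Ct matrices into one. Target
#' sets must be disjoint after canonicalization and the sample sets identical.
#'
#' @param a,b \code{ct_matrix} objects sharing the same samples.
#' @return A merged \code{ct_matrix}; panel provenance is kept per target.
#' @export
merge_panels <- function(a, b) {
  stopifnot(inherits(a, "ct_matrix"), inherits(b, "ct_matrix"))
  if (!setequal(samples(a), samples(b))) {
    off <- c(setdiff(samples(a), samples(b)), setdiff(samples(b), samples(a)))
    stop("sample sets differ between panels: ", paste(off, collapse = ", "))
  }
  dup <- intersect(targets(a), targets(b))
  if (length(dup))
    stop("target(s) present in both panels: ", paste(dup, collapse = ", "))
  bb <- b$ct[, samples(a), drop = FALSE]
  m <- rbind(a$ct, bb)
  out <- ct_matrix(m, c(unname(a$panel), unname(b$panel)))
  out
}

#' Group design: sample-to-group assignment with a calibrator
#'
#' @param sample character vector of sample ids.
#' @param group parallel character vector of group labels.
#' @param calibrator label of the calibrator (sham) group against which
#'   relative quantities are computed.
#' @return An object of class \code{group_design} with fields
#'   \code{assignment} (named character: sample -> group) and
#'   \code{calibrator}.
#' @export
group_design <- function(sample, group, calibrator) {
  sample <- as.character(sample); group <- as.character(group)
  if (length(sample) != length(group)) stop("sample/group length mismatch")
  if (anyDuplicated(sample)) stop("duplicate sample id in design")
  if (!calibrator %in% group)
    stop("calibrator group '", calibrator, "' has no samples")
  assignment <- stats::setNames(group, sample)
  structure(list(assignment = assignment, calibrator = calibrator),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  tab <- table(x$assignment)
  cat("group_design:", paste(sprintf("%s(n=%d)", names(tab), tab), collapse = " "),
      "| calibrator:", x$calibrator, "\n")
  invisible(x)
}

#' Read a sample metadata table
#'
#' Expects columns \code{sample} and \code{group} (TSV or CSV, sniffed).
#'
#' @param path file path.
#' @param calibrator calibrator group label.
#' @return A \code{\link{group_design}}.
#' @export
read_group_design <- function(path, calibrator) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", strip.white = TRUE,
                          comment.char = "")
  if (!all(c("sample", "group") %in% names(df)))
    stop("metadata must have columns sample, group")
  group_design(df$sample, df$group, calibrator)
}

group_samples <- function(design, group) {
  s <- names(design$assignment)[design$assignment == group]
  if (!length(s)) stop("unknown or empty group '", group, "'")
  s
}

injury_groups <- function(design) {
  setdiff(unique(unname(design$assignment)), design$calibrator)
}
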