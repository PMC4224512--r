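# Machine-readable per-severity DE tables and the common-signature table,
# packaged as TSV resources and guarded against transcription drift.

.fixture_labels <- c("IS1", "IS2", "IS3", "IS4", "common")
.fixture_rows <- c(IS1 = 23L, IS2 = 53L, IS3 = 116L, IS4 = 106L, common = 13L)
.fixture_up <- c(IS1 = 14L, IS2 = 35L, IS3 = 70L, IS4 = 66L, common = 9L)

#' Load a packaged per-group result table
#'
#' Loads the transcribed significantly-modulated miRNA table of one injury
#' severity (\code{"IS1"}..\code{"IS4"}: columns mirna, p_value, log10_rq,
#' ct_status) or the cross-severity common table (\code{"common"}: mirna
#' plus one log10 RQ column per severity). Names are canonicalized on load
#' and row counts and up/down tallies are checked against the published
#' legends, so any transcription drift fails loudly.
#'
#' @param label one of \code{"IS1"}, \code{"IS2"}, \code{"IS3"},
#'   \code{"IS4"}, \code{"common"}.
#' @return data.frame; per-group tables additionally carry
#'   \code{significant = TRUE} and a \code{direction} column so they plug
#'   directly into the signature operations.
#' @export
load_fixture <- function(label = .fixture_labels) {
  label <- match.arg(label)
  path <- system.file("extdata",
                      paste0("table_", tolower(label), ".tsv"),
                      package = "ctsig", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  if (nrow(df) != .fixture_rows[[label]])
    stop("fixture ", label, ": expected ", .fixture_rows[[label]],
         " rows, found ", nrow(df))
  if (label == "common") {
    df$mirna <- normalize_target_name(df$mirna)
    n_up <- sum(rowMeans(df[, c("IS1", "IS2", "IS3", "IS4")]) > 0)
  } else {
    names(df)[names(df) == "mirna"] <- "target"
    df$target <- normalize_target_name(df$target)
    df$significant <- TRUE
    df$direction <- ifelse(df$log10_rq > 0, "up", "down")
    n_up <- sum(df$log10_rq > 0)
  }
  if (n_up != .fixture_up[[label]])
    stop("fixture ", label, ": expected ", .fixture_up[[label]],
         " up-regulated rows, found ", n_up)
  df
}

#' Per-severity significant target sets from the packaged tables
#'
#' @return named list (IS1..IS4) of canonical target-name sets, ready for
#'   \code{\link{intersect_significant}}.
#' @export
fixture_sets <- function() {
  lapply(fixture_de(), `[[`, "target")
}

#' Per-severity fixture tables as DE-like frames
#'
#' @return named list (IS1..IS4) of data.frames with target, p_value,
#'   log10_rq, ct_status, significant, direction.
#' @export
fixture_de <- function() {
  labs <- setdiff(.fixture_labels, "common")
  stats::setNames(lapply(labs, load_fixture), labs)
}
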