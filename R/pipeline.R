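# End-to-end driver: detection -> normalization -> DE per group ->
# signature -> stable references -> clustering, with a report bundle and a
# run manifest.

#' Run the full analysis pipeline
#'
#' Accepts either file paths (long-format Ct table plus sample metadata) or
#' in-memory objects, runs every stage against the calibrator group, and
#' writes the report bundle to \code{out_dir}: detection report, normalized
#' matrix, one DE report per injury group, signature table with Venn region
#' counts, stability report, Newick tree, and a \code{manifest.json}
#' echoing package version, thresholds and inputs so a run can be
#' reproduced from the manifest alone.
#'
#' @param ct a \code{\link{ct_matrix}} or path to a long-format Ct table.
#' @param metadata a \code{\link{group_design}} or path to a sample
#'   metadata table.
#' @param out_dir output directory (created if needed); \code{NULL} skips
#'   all file output.
#' @param calibrator calibrator group label (required when \code{metadata}
#'   is a path).
#' @param det detection thresholds.
#' @param de DE thresholds.
#' @param stability stability criteria.
#' @param clustering cluster configuration.
#' @param undetected_token marker for undetected cells when reading.
#' @return invisible list with elements detection, normalized, de (named
#'   list), signature, venn, stability, clustering, manifest.
#' @export
run_pipeline <- function(ct, metadata, out_dir = NULL, calibrator = NULL,
                         det = detection_thresholds(), de = de_thresholds(),
                         stability = stability_criteria(),
                         clustering = cluster_config(),
                         undetected_token = "Undetermined") {
  ct_path <- NULL; meta_path <- NULL
  if (is.character(ct)) { ct_path <- ct; ct <- read_ct_long(ct, undetected_token) }
  if (is.character(metadata)) {
    if (is.null(calibrator)) stop("calibrator label required with a metadata path")
    meta_path <- metadata
    metadata <- read_group_design(metadata, calibrator)
  }
  stopifnot(inherits(ct, "ct_matrix"), inherits(metadata, "group_design"))

  detection <- detection_report(ct, metadata, det)
  normalized <- global_normalize(ct, det)
  de_res <- run_de_all(ct, metadata, det = det, de = de)
  sig <- intersect_significant(de_res)
  venn <- venn_counts(sig$per_group_sets)
  stab <- select_stable_references(ct, stability)
  clust <- tryCatch(cluster_groups(ddct_profiles(ct, metadata, det), clustering),
                    error = function(e) e)

  manifest <- list(
    package = "ctsig",
    version = as.character(utils::packageVersion("ctsig")),
    inputs = list(ct = ct_path, metadata = meta_path,
                  n_targets = nrow(ct$ct), n_samples = ncol(ct$ct),
                  calibrator = metadata$calibrator),
    thresholds = list(detection = unclass(det), de = unclass(de),
                      stability = unclass(stability),
                      clustering = unclass(clustering)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(detection, file.path(out_dir, "detection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_norm_long(normalized, file.path(out_dir, "normalized.tsv"))
    for (g in names(de_res))
      write_de_report(de_res[[g]], file.path(out_dir, paste0("de_", g, ".tsv")))
    utils::write.table(assemble_signature_table(sig),
                       file.path(out_dir, "signature.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(venn), file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE)
    write_stability_report(stab, file.path(out_dir, "stability.tsv"))
    if (!inherits(clust, "error")) {
      writeLines(clust$newick, file.path(out_dir, "clustering.nwk"))
      utils::write.table(clust$merges, file.path(out_dir, "merges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(detection = detection, normalized = normalized, de = de_res,
                 signature = sig, venn = venn, stability = stab,
                 clustering = clust, manifest = manifest))
}
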