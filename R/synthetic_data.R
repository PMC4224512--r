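# Seeded generator of two-panel Ct arrays with the structure the pipeline
# assumes (graded group effects, dropout at a ceiling, designed stable
# references), plus recovery scoring against the simulated truth.

#' Simulation configuration
#'
#' Defaults emulate a two-panel rodent serum miRNA array profiled in five
#' groups of six biological replicates: per-target baseline Ct uniform on
#' [14, 35], additive Gaussian replicate noise on the Ct (log2-abundance)
#' scale, a graded true shift on a fraction of targets whose magnitude
#' scales with injury severity, deterministic dropout above a Ct ceiling,
#' and a handful of designed low-variance, abundant reference targets.
#'
#' @param n_targets panel size (default 368, split over two panels).
#' @param n_groups number of injury groups besides the calibrator
#'   (default 4).
#' @param n_replicates biological replicates per group (default 6).
#' @param baseline_range per-target baseline Ct drawn uniformly from this
#'   range (default c(14, 35)).
#' @param noise_sd replicate Ct noise SD in cycles (default 0.5).
#' @param effect_targets fraction of targets carrying a true effect
#'   (default 0.1).
#' @param effect_logfc per-group true dCt shifts in cycles, negative = up-
#'   regulation; the default grades 1:2:4:4.5 with the severity index.
#'   Each effect target is randomly assigned an up or down orientation that
#'   is consistent across groups.
#' @param dropout_ceiling Ct at or above which a realized reaction is
#'   emitted as undetected (default 36).
#' @param n_stable designed stable reference targets (default 5).
#' @param stable_range baseline Ct range of the stable targets
#'   (default c(15, 16)).
#' @param stable_sd replicate noise SD of the stable targets (default 0.3).
#' @param seed integer seed; the same seed yields an identical experiment.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_targets = 368L, n_groups = 4L, n_replicates = 6L,
                       baseline_range = c(14, 35), noise_sd = 0.5,
                       effect_targets = 0.1,
                       effect_logfc = -0.5 * c(1, 2, 4, 4.5),
                       dropout_ceiling = 36, n_stable = 5L,
                       stable_range = c(15, 16), stable_sd = 0.3,
                       seed = 1L) {
  if (n_targets < 1L || n_replicates < 1L || n_groups < 1L)
    stop("degenerate config: counts must be positive")
  if (!(noise_sd > 0)) stop("noise_sd must be positive")
  if (length(effect_logfc) != n_groups)
    stop("effect_logfc must give one shift per injury group")
  if (n_stable + round(effect_targets * n_targets) > n_targets)
    stop("stable plus effect targets exceed the panel")
  structure(list(n_targets = as.integer(n_targets),
                 n_groups = as.integer(n_groups),
                 n_replicates = as.integer(n_replicates),
                 baseline_range = baseline_range, noise_sd = noise_sd,
                 effect_targets = effect_targets, effect_logfc = effect_logfc,
                 dropout_ceiling = dropout_ceiling,
                 n_stable = as.integer(n_stable),
                 stable_range = stable_range, stable_sd = stable_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a Ct array experiment
#'
#' Ct(t, s) = baseline(t) + shift(t, group(s)) + noise, with realized values
#' at or above the dropout ceiling emitted as undetected. Stable targets get
#' low noise and zero shift. Effect targets are disjoint from stable
#' targets.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{matrix} (a \code{\link{ct_matrix}}),
#'   \code{design} (a \code{\link{group_design}} with calibrator
#'   \code{"sham"}) and \code{truth} (a \code{sim_truth}: data.frame per
#'   target with baseline, designed-stable flag, orientation and one
#'   \code{shift_<group>} column per injury group).
#' @export
simulate_ct_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- config$n_targets
  groups <- paste0("IS", seq_len(config$n_groups))
  all_groups <- c("sham", groups)
  samples <- as.vector(vapply(all_groups, function(g)
    paste0(g, "_", seq_len(config$n_replicates)),
    character(config$n_replicates)))
  design <- group_design(samples, rep(all_groups, each = config$n_replicates),
                         calibrator = "sham")

  tg <- sprintf("sim-miR-%03d", seq_len(nt))
  is_stable <- seq_len(nt) <= config$n_stable
  baseline <- ifelse(is_stable,
                     stats::runif(nt, config$stable_range[1L], config$stable_range[2L]),
                     stats::runif(nt, config$baseline_range[1L], config$baseline_range[2L]))
  n_effect <- round(config$effect_targets * nt)
  effect_idx <- which(!is_stable)[seq_len(n_effect)]
  orientation <- integer(nt)
  orientation[effect_idx] <- sample(c(-1L, 1L), n_effect, replace = TRUE)

  # shift matrix: targets x all groups (sham shift is zero)
  shift <- matrix(0, nt, length(all_groups),
                  dimnames = list(tg, all_groups))
  # orientation +1 keeps the configured (negative = up) shift sign,
  # -1 mirrors it into a down-regulated target
  for (i in seq_along(groups))
    shift[, groups[i]] <- orientation * config$effect_logfc[i]

  sd_t <- ifelse(is_stable, config$stable_sd, config$noise_sd)
  ct <- matrix(NA_real_, nt, length(samples), dimnames = list(tg, samples))
  for (s in samples) {
    g <- design$assignment[[s]]
    ct[, s] <- baseline + shift[, g] +
      stats::rnorm(nt, sd = sd_t)
  }
  ct[ct >= config$dropout_ceiling] <- NA_real_

  panel <- rep(c("A", "B"), c(ceiling(nt / 2), floor(nt / 2)))
  truth <- data.frame(target = tg, baseline = baseline, is_stable = is_stable,
                      orientation = orientation, stringsAsFactors = FALSE)
  for (g in groups) truth[[paste0("shift_", g)]] <- shift[, g]
  class(truth) <- c("sim_truth", class(truth))
  list(matrix = ct_matrix(ct, panel), design = design, truth = truth)
}

#' Score DE calls against simulated truth
#'
#' A (target, group) pair carries a true effect when |true shift| >=
#' log2(fold_min) cycles. Sensitivity is the fraction of true-effect pairs
#' called significant (a truth target absent from \code{calls}, e.g. one
#' excluded by detection, counts as missed); FDR is the fraction of
#' significant calls without a true effect (reported as 0 with
#' \code{fdr_defined = FALSE} when there are no calls); direction accuracy
#' is scored over the called true positives against the sign of the true
#' shift (negative shift = up).
#'
#' @param calls a \code{de_result} (or row-bound results of several groups).
#' @param truth the \code{sim_truth} from
#'   \code{\link{simulate_ct_experiment}}.
#' @param fold_min fold threshold defining a true effect (default 1.5).
#' @return list: sensitivity, fdr, direction_accuracy, n_true, n_called,
#'   fdr_defined.
#' @export
evaluate_recovery <- function(calls, truth, fold_min = 1.5) {
  stopifnot(is.data.frame(calls), inherits(truth, "sim_truth"))
  unknown <- setdiff(calls$target, truth$target)
  if (length(unknown))
    stop("calls contain target(s) unknown to the truth: ",
         paste(unknown[seq_len(min(3L, length(unknown)))], collapse = ", "))
  groups <- unique(calls$group)
  shift_cols <- paste0("shift_", groups)
  if (!all(shift_cols %in% names(truth)))
    stop("truth lacks shifts for group(s): ",
         paste(setdiff(groups, sub("^shift_", "", names(truth))), collapse = ", "))
  cut <- log2(fold_min)
  per_group <- lapply(groups, function(g) {
    true_shift <- truth[[paste0("shift_", g)]]
    sub <- calls[calls$group == g, , drop = FALSE]
    i <- match(truth$target, sub$target)
    data.frame(true_effect = abs(true_shift) >= cut,
               called = !is.na(i) & sub$significant[i],
               dir_ok = !is.na(i) &
                 sub$direction[i] == ifelse(true_shift < 0, "up", "down"))
  })
  tab <- do.call(rbind, per_group)
  n_true <- sum(tab$true_effect)
  n_called <- sum(tab$called)
  tp <- tab$true_effect & tab$called
  list(sensitivity = if (n_true) sum(tp) / n_true else NA_real_,
       fdr = if (n_called) sum(tab$called & !tab$true_effect) / n_called else 0,
       direction_accuracy = if (sum(tp)) mean(tab$dir_ok[tp]) else NA_real_,
       n_true = n_true, n_called = n_called, fdr_defined = n_called > 0)
}

#' Write a simulated experiment to disk
#'
#' Long-format Ct CSV, metadata TSV and truth TSV.
#'
#' @param sim result of \code{\link{simulate_ct_experiment}}.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the three paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ct_path <- file.path(dir, "ct_long.csv")
  meta_path <- file.path(dir, "metadata.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  write_ct_long(sim$matrix, ct_path)
  utils::write.table(
    data.frame(sample = names(sim$design$assignment),
               group = unname(sim$design$assignment)),
    meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ct_path, meta_path, truth_path))
}
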