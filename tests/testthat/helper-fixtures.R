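# Shared test helpers: tiny in-code Ct matrices and an exhaustive
# permutation oracle for the two-sample test.

# Build a ct_matrix from a plain matrix, inventing names as needed.
make_ct <- function(values, targets = NULL, samples = NULL, panel = "A") {
  m <- as.matrix(values)
  rownames(m) <- targets %||% paste0("miR-", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  ct_matrix(m, panel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 2-group design over the columns of a ct_matrix: first n1 samples are
# the calibrator ("sham"), the rest one injury group.
make_design <- function(mat, n_cal, group = "inj") {
  s <- colnames(mat$ct)
  group_design(s, c(rep("sham", n_cal), rep(group, length(s) - n_cal)),
               calibrator = "sham")
}

# Exhaustive two-sided permutation p-value for the difference in means:
# every way of splitting the pooled values into groups of the observed
# sizes, p = fraction of splits with |mean difference| >= observed.
perm_t_p <- function(x, y) {
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  idx <- utils::combn(length(pooled), length(x))
  stats <- apply(idx, 2L, function(i)
    abs(mean(pooled[i]) - mean(pooled[-i])))
  mean(stats >= obs - 1e-12)
}

# Small battery of 3-vs-3 replicate pairs used to compare test orderings.
toy_pairs_3v3 <- function() {
  list(
    list(x = c(1, 2, 3),       y = c(1.1, 2.1, 2.9)),
    list(x = c(0, 0.1, -0.1),  y = c(5, 5.1, 4.9)),
    list(x = c(10, 11, 12),    y = c(12, 13, 14)),
    list(x = c(1, 5, 9),       y = c(2, 6, 10)),
    list(x = c(0.5, 0.6, 0.7), y = c(0.9, 1.0, 1.1)),
    list(x = c(3, 3.2, 2.8),   y = c(3.1, 2.9, 3.3)),
    list(x = c(-1, 0, 1),      y = c(4, 4.5, 5)),
    list(x = c(2, 2.1, 1.9),   y = c(2.6, 2.4, 2.5))
  )
}
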