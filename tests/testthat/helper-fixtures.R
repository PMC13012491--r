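# Shared fixture builders (everything generated in code; no stored data).

make_ct <- function(mat, lineage = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  count_table(mat, rownames(mat), colnames(mat), lineage)
}

rand_ct <- function(n_taxa, n_samples, seed = 1, lambda = 50) {
  set.seed(seed)
  make_ct(matrix(stats::rpois(n_taxa * n_samples, lambda), n_taxa, n_samples))
}

# a noiseless heat curve straight from the model (not via flow integration)
model_heat_curve <- function(t, q_max, mu_max, lag, sample_id = "sim",
                             treatment = "control") {
  structure(
    list(time = t, q = gompertz_heat(t, q_max, mu_max, lag),
         sample_id = sample_id, treatment = treatment),
    class = "heat_curve"
  )
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
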