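# Small deterministic fixtures used across the suite.

random_counts <- function(n_genes = 10, n_samples = 4, seed = 1, lambda = 20,
                          compartment = NULL) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  as_counts(m, compartment)
}

# scaled-down simulator settings used when full default sizes would be
# wasteful in a unit test
tiny_sim_config <- function(seed = 1, blocks = list(
                              sim_block("b1", "host", 1:8, "SOL", 1:4,
                                        loading = 0.9, sign = 1L, "both"),
                              sim_block("b2", "host", 11:18, "SOL", 5:8,
                                        loading = 0.9, sign = 1L, "pos")),
                            ...) {
  sim_config(n_host = 60, n_sol = 24, n_ctput = 16, blocks = blocks,
             n_pathways = 4, pathway_overlap = 3, seed = seed, ...)
}

four_culture_samples <- function(n_reps = 4) {
  tibble::tibble(
    sample_id = paste0(rep(c("5L", "5S", "5Pi", "5Tk"), each = n_reps), "_",
                       rep(seq_len(n_reps), 4)),
    culture = rep(c("5L", "5S", "5Pi", "5Tk"), each = n_reps),
    ctput_status = rep(c(TRUE, TRUE, FALSE, FALSE), each = n_reps),
    replicate = rep(seq_len(n_reps), 4)
  )
}
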