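# Shared fixtures, built once per test session.  The small mixture keeps
# unit tests fast; the heavy full-size runs live in test-acceptance.R.

.fx <- new.env(parent = emptyenv())

fx_n_small <- c(transcriptomic = 300, mitochondrial = 20, immune_locus = 20,
                "repeat" = 80, rdna = 30, low_quality = 30,
                low_complexity = 20, lost_human = 30, hyper_edited = 40,
                ncl_circ = 20, ncl_fusion = 20, ncl_trans = 20,
                immune_vj = 40, microbial = 60)

fx_config <- function() {
  if (is.null(.fx$config)) {
    .fx$config <- sim_config(seed = 42, n_reads = fx_n_small)
  }
  .fx$config
}

fx_bundle <- function() {
  if (is.null(.fx$bundle)) .fx$bundle <- build_references(fx_config())
  .fx$bundle
}

fx_sim <- function() {
  if (is.null(.fx$sim)) .fx$sim <- simulate_reads(fx_bundle(), fx_config())
  .fx$sim
}

fx_result <- function() {
  if (is.null(.fx$result)) {
    .fx$result <- rop_run(fx_sim()$reads, fx_bundle(), rop_config())
  }
  .fx$result
}

# truth class joined with assigned category for the small mixture
fx_truth_vs_assigned <- function() {
  dplyr::left_join(fx_sim()$truth, fx_result()$assignments, by = "read_id")
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_positions <- function(seq, pos, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}
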