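# Shared fixtures: default parameter objects and a memoised reference batch
# (validation-run conditions) reused across test files.
tm_p <- model_parameters()
tm_cc <- physical_constants()

.sim_cache <- new.env(parent = emptyenv())

ref_sim <- function() {
  if (is.null(.sim_cache$ref))
    .sim_cache$ref <- run_batch(tm_p, tm_cc,
                                operating_conditions(t_end = 15))
  .sim_cache$ref
}

noiseless <- function(times = seq(0, 12, 0.5), seed = 1) {
  noise_spec(conc_cv = 0, gas_sd = 0, cum_cv = 0, times = times, seed = seed)
}
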