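# Random valid kinetic parameter sets for property-style tests.
# Rates are drawn log-uniformly over about two decades, influx uniformly;
# everything is reproducible from the seed.
rand_params <- function(n, seed = 42, min_influx = 0.5) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      kinetic_params(
        influx = runif(1, min_influx, 20),
        beta = exp(runif(1, log(0.05), log(5))),
        gamma = exp(runif(1, log(0.05), log(5)))
      )
    })
  })
}

rand_perturbations <- function(n, seed = 43) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      perturbation(exp(runif(1, log(0.1), log(10))),
                   exp(runif(1, log(0.1), log(10))))
    })
  })
}
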