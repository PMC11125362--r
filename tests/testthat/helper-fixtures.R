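# Shared fixtures: the final-model typical values and quick constructors.

typical <- function() structural_params()  # Ka 5.41, Vd/F 61.7, CL/F 16.9, ALAG 0.394

default_pop <- function() population_params()

# random but physiologically plausible structural parameter draws
random_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    structural_params(ka = stats::runif(1, 0.3, 12),
                      v = stats::runif(1, 20, 200),
                      cl = stats::runif(1, 2, 60),
                      tlag = stats::runif(1, 0, 1))
  })
}
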