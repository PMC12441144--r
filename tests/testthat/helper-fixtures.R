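# Shared fixtures built in code: a small design, a tiny population and a
# simulated dataset used across test files.  Everything is seeded.

fix_design <- function(seed = 101) build_design(design_config(), seed = seed)

fix_small_design <- function(seed = 101) {
  build_design(design_config(values = c(8, 50), probabilities = c(0.25, 0.75),
                             repetitions = 4), seed = seed)
}

fix_params <- function(...) {
  modifyList(list(rho = 1, kappa_desc = 6, kappa_exp = 3,
                  psi_safe = 1.5, psi_risky = 1.5, tau = 2), list(...))
}

fix_study <- local({
  cache <- NULL
  function(n_subjects = 6, seed = 202) {
    if (is.null(cache)) {
      pop <- simulate_population(n_subjects, seed = seed)
      des <- fix_design(seed)
      sim <- simulate_study(pop, des, seed = seed)
      cache <<- list(pop = pop, design = des, choices = sim$choices,
                     matches = sim$matches)
    }
    cache
  }
})
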