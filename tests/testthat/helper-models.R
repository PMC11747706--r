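# Shared fixtures, built in code.

final_model <- sertraline_final_model()

# Deterministic variant: no variability anywhere.
det_model <- function() {
  m <- sertraline_final_model()
  m$omega_cl <- 0
  m$sigma_prop <- 0
  m$sigma_add <- 0
  m
}

# Small simulated trough dataset for estimation-layer tests.
sim_dataset <- function(n = 30, seed = 42, troughs = 2, model = final_model,
                        spec_args = list()) {
  spec <- do.call(cohort_spec,
                  c(list(n_subjects = n, seed = seed), spec_args))
  cohort <- generate_cohort(spec)
  simulate_tdm(cohort, model, troughs_per_subject = troughs,
               seed = seed + 1L)
}

# Brute-force steady state by superposing many single doses.
superposition_trough <- function(p, r, n_doses = 400) {
  t_since <- r$tau_h * seq_len(n_doses)
  sum(conc_single_dose(p, r$dose_mg, t_since))
}
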