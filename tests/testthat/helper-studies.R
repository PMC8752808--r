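# Reference-scale studies shared across acceptance tests. Built lazily and
# cached so several criteria can reuse the same study without re-simulation.
.study_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .study_cache))
    assign(name, build(), envir = .study_cache)
  get(name, envir = .study_cache)
}

noiseless_report <- function() cached("noiseless_report", function()
  suppressMessages(run_recovery_experiment(
    study_config(noise_sd = 0, alpha_true = 0.65, seed = 101))))

noisy_study <- function() cached("noisy_study", function()
  simulate_study(study_config(noise_sd = 0.5, alpha_true = 0.65, seed = 202)))

noisy_report <- function() cached("noisy_report", function()
  run_recovery_experiment(study = noisy_study()))

# Replicate null studies (alpha_true = 0.5) for calibration checks.
null_reports <- function(n = 20) cached("null_reports", function()
  lapply(seq_len(n), function(i)
    run_recovery_experiment(
      study_config(noise_sd = 0.5, alpha_true = 0.5, seed = 300 + i),
      single_identification = FALSE)))
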