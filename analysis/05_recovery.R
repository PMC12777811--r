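#!/usr/bin/env Rscript
# Validation by parameter recovery: the estimated partition versus the
# simulator's truth sidecar for the default study, plus a noise-free sweep
# across the lymph-split fraction.

suppressPackageStartupMessages(library(lymphpk))

cfg <- read_study_config(NULL)
dataset <- read_study_dataset(file.path(cfg$output_dir, "study_data"))
analysis <- run_study_analysis(dataset, lloq = cfg$lloq)

rec <- recovery_report(dataset$truth, analysis$transport[
  , c("animal", "period", "f_al", "f_ap", "f", "f_rl")])
cat("Recovery against the truth sidecar (default noisy study):\n")
print(rec, row.names = FALSE)

iv <- analysis$iv_nca
cat(sprintf("\nIV reference: CL %.1f l/h, %.0f%% of AUC_inf extrapolated%s.\n",
            iv$cl, iv$pct_extrapolated,
            if ("extrapolation_above_20pct" %in% iv$flags)
              " (flagged > 20%)" else ""))
cat("F_AL is recovered by direct mass balance and is nearly unbiased.\n")
cat("F_AP (and hence F, F_RL) inherits the error of the single IV reference\n")
cat("animal: its clearance enters every animal's denominator, so residual\n")
cat("noise on its sparse terminal samples shifts all F_AP values together\n")
cat("(between-formulation paired comparisons are unaffected).\n")

## Noise-free sweep across the lymph split: isolates method bias from noise
iv_ref <- nca_intravenous(
  handle_blq(simulate_iv_experiment(default_pig_parameters("nanoemulsion"),
                                    20)$serum, cfg$lloq))
sweep <- do.call(rbind, lapply(seq(0.05, 0.5, by = 0.05), function(phi) {
  p <- pk_parameters(fa = 0.172, phi_lymph = phi, eh = 0.7, ka = 0.2,
                     klt = 0.4, cl = 33.6, vc = 50,
                     k12 = 1.532, k21 = 0.2924)
  r <- simulate_oral_experiment(p, 200,
                                flow = lymph_flow_model(70, 0))
  res <- transport_analysis(r, iv_ref, lloq = cfg$lloq)
  data.frame(phi_lymph = phi,
             f_al_true = r$truth$f_al_true, f_al_est = res$f_al,
             f_al_rel_err_pct = 100 * (res$f_al - r$truth$f_al_true) /
               r$truth$f_al_true,
             f_rl_true = r$truth$f_rl_true, f_rl_est = res$f_rl,
             f_rl_err_pp = res$f_rl - r$truth$f_rl_true)
}))
cat(sprintf("\nNoise-free lymph-split sweep: |F_AL| bias <= %.2f%% relative, |F_RL| error <= %.2f points at 24 h.\n",
            max(abs(sweep$f_al_rel_err_pct)), max(abs(sweep$f_rl_err_pp))))

write_results(list(recovery_default_study = rec,
                   recovery_phi_sweep = sweep), cfg$output_dir)
cat("Recovery tables written under", cfg$output_dir, "\n")
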