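#!/usr/bin/env Rscript
# Fit the warm-up models to noisy synthetic theta curves generated from the
# cohort-mean constants (protocol: 24 samples over 0-69 min, noise sd 0.003),
# then derive the cold-chain quantities both from the recovered fit and from
# the cohort-mean reference constants.

library(rbcwarmup)

dir.create("results", showWarnings = FALSE)

cur <- generate_model_curves(noise_sd = 0.003, seed = 1L)
fm <- fit_exponential(cur$t_min, cur$theta_mean)
fs <- fit_shifted_exponential(cur$t_min, cur$theta_surface, "surface")
fc <- fit_shifted_exponential(cur$t_min, cur$theta_core, "core")
fit <- warmup_fit(fm$tau, fs$tau, fc$tau, fs$delta, fc$delta,
                  r2_mean = fm$r2, r2_surface = fs$r2, r2_core = fc$r2,
                  sd_tau_mean = fm$sd_tau, sd_tau_surface = fs$sd_tau,
                  sd_tau_core = fc$sd_tau, sd_delta_surface = fs$sd_delta,
                  sd_delta_core = fc$sd_delta)
print(fit)
write_fit_report(fit, "results/model_fit.json")

# uncertainty bands on a 1-min grid for plotting
bands <- propagate_uncertainty(fit, seq(0, 69, by = 1))
write.csv(bands, "results/uncertainty_bands.csv", row.names = FALSE)

# cold-chain quantities from the cohort-mean reference constants
ref <- cohort_reference_fit()
cold <- data.frame(
  quantity = c("theta_core_30min", "limit_ambient_storage1_degC",
               "limit_ambient_storage6_degC", "time_to_10C_core_min",
               "time_to_10C_mean_min", "t_spread_min", "theta_spread_max",
               "ratio_tau_surface_mean", "ratio_tau_surface_core"),
  value = c(theta_shifted_model(30, ref$tau_core, ref$delta_core, "core"),
            limit_ambient(1, 30, 10, ref, "core"),
            limit_ambient(6, 30, 10, ref, "core"),
            time_to_threshold(10, 1, 20, ref, "core"),
            time_to_threshold(10, 1, 20, ref, "mean"),
            t_spread(ref), theta_spread(t_spread(ref), ref),
            derived_constants(ref)$ratio_sm, derived_constants(ref)$ratio_sc))
cold$rounded <- round(cold$value, 2)
write.csv(cold, "results/cold_chain.csv", row.names = FALSE)
print(cold, digits = 4)
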