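#!/usr/bin/env Rscript
# Step 3 — validate the whole pipeline on synthetic responders with known
# latent priorities: (i) the noiseless, unquantized study must invert
# exactly; (ii) quantization to the five-point verbal scale alone costs a
# little recovery accuracy; (iii) recovery and consistency degrade
# monotonically as multiplicative judgment noise grows.

suppressPackageStartupMessages(library(ahpelicit))
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

h <- load_hierarchy(system.file("extdata", "ct_hierarchy.yaml",
                                package = "ahpelicit"))

# (i) exact inversion in the noiseless limit
cfg0 <- simulation_config(h, n_responders = 5, sigma = 0,
                          quantize = FALSE, seed = 20260925)
st0 <- simulate_study(cfg0)
rep0 <- run_study(h, st0$matrices)
rr0 <- recovery_report(st0$truth, rep0$global)
cat("Noiseless, unquantized study (5 responders):\n")
cat(sprintf("  max CR = %.2e, max L1 recovery error = %.2e, all rho = %d\n",
            max(rep0$consistency$CR), max(rr0$L1), all(rr0$rho == 1)))

# (ii)-(iii) noise sweep, quantized to the verbal grid, 200 responders per
# level so the mean recovery error is stable; responders are scored
# individually (no concordance needed here)
score_responder <- function(ms, rid) {
  pri <- lapply(ms, principal_priorities)
  crs <- vapply(pri, function(p) consistency_report(p)$CR, numeric(1))
  list(global = global_weights(pri[[h$goal]], pri[h$categories], rid),
       max_cr = max(crs), mean_cr = mean(crs))
}
sweep <- lapply(c(0, 0.1, 0.2, 0.3, 0.45, 0.6), function(sg) {
  cfg <- simulation_config(h, n_responders = 200, sigma = sg,
                           quantize = TRUE, seed = 20260925)
  st <- simulate_study(cfg)
  scored <- Map(score_responder, st$matrices, names(st$matrices))
  rr <- recovery_report(st$truth, lapply(scored, `[[`, "global"))
  data.frame(sigma = sg,
             mean_L1 = mean(rr$L1),
             median_rho = median(rr$rho, na.rm = TRUE),
             mean_top5_overlap = mean(rr$top_k_overlap),
             mean_CR = mean(vapply(scored, `[[`, numeric(1), "mean_cr")),
             frac_pass_cr10 = mean(vapply(scored, `[[`, numeric(1),
                                          "max_cr") <= 0.1))
})
sweep <- do.call(rbind, sweep)
write.csv(sweep, file.path(out_dir, "noise_sweep.csv"), row.names = FALSE)

cat("\nNoise sweep (200 quantized responders per level):\n")
print(sweep, row.names = FALSE, digits = 3)
cat("\nRecovery error (L1) and mean CR rise monotonically with sigma;\n")
cat("the sigma = 0 row isolates the cost of the 5-point verbal grid alone.\n")

# a small quantized study exported in the standard response format
cfg_demo <- simulation_config(h, n_responders = 5, sigma = 0.2,
                              quantize = TRUE, seed = 20260925)
st_demo <- simulate_study(cfg_demo)
export_simulated_study(st_demo, file.path(out_dir, "demo_study"))
rep_demo <- run_study(h, file.path(out_dir, "demo_study", "responses.csv"))
export_reports(rep_demo, file.path(out_dir, "demo_reports"))
cat("\nDemo study (5 responders, sigma = 0.2):",
    sum(rep_demo$gate$pass), "of 5 pass the CR <= 0.1 gate.\n")
cat("Wrote", file.path(out_dir, "noise_sweep.csv"),
    "and the demo study exports.\n")
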