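#!/usr/bin/env Rscript

# Stage 3: robust-design capture-recapture estimation.
#
# Fits a compact model set crossing the three emigration scenarios with
# constant/time-varying survival and capture structures, ranks by AIC,
# reports the best model's demographic estimates and derived abundance,
# and runs the closure and bootstrap goodness-of-fit diagnostics. The
# full 40-model cross-product is available via rd_model_set(); the subset
# here keeps the driver's runtime modest while covering every scenario.

suppressMessages(library(photopop))

records <- grade_records(read_sightings("results/sightings.csv"))
cr <- filter_for_analysis(records, "capture_recapture")
hist <- build_capture_histories(cr, default_calendar())

specs <- c(
  rd_model_set(emigration = c("none", "random", "markovian"),
               survival = "constant",
               capture = c("constant", "primary_varying",
                           "primary_by_secondary"),
               emigration_structure = "constant"),
  rd_model_set(emigration = "random", survival = "primary_varying",
               capture = "primary_by_secondary",
               emigration_structure = "constant"))

ms <- model_selection(hist, specs, n_starts = 2L, seed = 1L, hessian = FALSE)
message("model ranking (top 5):")
print(utils::head(ms$table[, c("emigration", "survival", "capture", "K",
                               "AIC", "dAIC")], 5))

best_spec <- ms$fits[[1]]$spec
best <- fit_rd(hist, best_spec, n_starts = 3L, seed = 2L)   # with SEs
print(best)

closure <- closure_test_all(hist)
message("closure diagnostics (likelihood-ratio, staggered-availability ",
        "alternative):")
print(closure, digits = 3)

gof <- bootstrap_gof(best, replicates = 100L, seed = 3L)
message(sprintf(paste0("parametric-bootstrap GOF (substitutes the standard ",
                       "contingency-table tests): p = %.3f over %d replicates"),
                gof$p_value, gof$n_successful))

write_report(list(model_table = ms$table,
                  estimates = best$estimates,
                  abundance = best$abundance,
                  closure = closure,
                  gof_p_value = gof$p_value,
                  mean_abundance = mean(best$abundance$N)),
             "results/stage3")
message(sprintf("decadal mean derived abundance: %.1f marked adults",
                mean(best$abundance$N)))
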