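#!/usr/bin/env Rscript
# Predictions of the frozen property-to-Dk regression on the packaged
# drug/excipient tables, and the zero-order release profiles it implies
# for the packaged implant configurations.

suppressPackageStartupMessages(library(dkimplant))
dir.create("results", showWarnings = FALSE)

fx <- load_fixtures()
pm <- published_model()

# log10(Dk) for every training drug x excipient combination
grid <- property_grid(fx, "training", efda_source = "Wuxi")
grid$log10_dk_pred <- predict_log10_dk(pm, grid)
grid$dk_pred_mm2_day <- 10^grid$log10_dk_pred
write.csv(grid[, c("drug", "excipient", "cse_mg_ml", "log10_dk_pred",
                   "dk_pred_mm2_day")],
          "results/predicted_dk_training_grid.csv", row.names = FALSE)

cat("Predicted log10(Dk) spans",
    sprintf("%.2f to %.2f", min(grid$log10_dk_pred), max(grid$log10_dk_pred)),
    "across the", nrow(grid), "drug x excipient combinations;\n")
cat("high-CsE excipients (PEGs, propylene glycol) push Dk down through the\n",
    "negative log10(CsE) coefficient, low-solubility oils push it up.\n\n",
    sep = "")

# predicted release profiles for the implant configurations whose
# formulation excipient has a tabulated CsE (the six training-drug designs)
t <- twice_weekly_schedule(70)
profiles <- NULL
for (drug in intersect(fx$configs$drug, fx$table1$drug)) {
  cfgrow <- fx$configs[fx$configs$drug == drug, ]
  cse <- lookup_cse(fx, drug, cfgrow$excipient)
  cfg <- fixture_config(fx, drug)
  props <- fx$table1[fx$table1$drug == drug, ]
  dk <- predict_dk(pm, props, cse)
  ser <- predict_cumulative(dk, cse, cfg, t, truncate_at_loading = TRUE)
  profiles <- rbind(profiles, cbind(
    drug = drug, excipient = cfgrow$excipient,
    dk_pred = dk,
    rate_mg_day = attr(ser, "rate_mg_day"),
    as.data.frame(ser)))
}
write.csv(profiles, "results/predicted_release_profiles.csv",
          row.names = FALSE)

rates <- unique(profiles[, c("drug", "excipient", "dk_pred", "rate_mg_day")])
cat("Predicted zero-order release rates for the packaged implant designs:\n")
print(rates, digits = 3, row.names = FALSE)
cat("\nWall-thickness design example: to release 1 mg/day of the",
    "FTC/castor-oil\nformulation from a 40 mm tube, the membrane should be",
    sprintf("%.0f um thick.\n",
            1000 * design_wall_thickness(
              1, predict_dk(pm, fx$table1[fx$table1$drug == "FTC", ],
                            lookup_cse(fx, "FTC", "Castor Oil")),
              lookup_cse(fx, "FTC", "Castor Oil"),
              lateral_surface_area(fixture_config(fx, "FTC")))))
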