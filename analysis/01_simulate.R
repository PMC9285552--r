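#!/usr/bin/env Rscript
# Simulate every input the analysis needs: the 121-cow model-development
# panel, and a 6-cow feeding trial (2 Latin squares x 3 diets) with 1-Hz
# AMS breath traces, background traces, head-box measurements and activity
# logs. All downstream scripts read only what this one writes.

suppressPackageStartupMessages(library(snifferch4))

out <- "results/analysis"
dir.create(file.path(out, "traces"), recursive = TRUE, showWarnings = FALSE)
set.seed(20210930)

## Model-development panel -------------------------------------------------
panel <- gen_cow_panel(panel_config(seed = NULL))
write.csv(panel, file.path(out, "panel.csv"), row.names = FALSE)
cat(sprintf("panel: %d cows; DMI %.1f +/- %.2f, ECM %.1f +/- %.2f, ratio %.4f, CH4 %.0f L/day\n",
            nrow(panel), mean(panel$DMI), sd(panel$DMI), mean(panel$ECM),
            sd(panel$ECM), mean(panel$CH4CO2), mean(panel$CH4)))

## Feeding trial: cows, diets, visits, head-box measurements ---------------
tcfg <- trace_config(seed = NULL)
eq2 <- load_equation_bundle()$eq2
cows <- expand.grid(square = c("sq1", "sq2"), cow = 1:3,
                    stringsAsFactors = FALSE)
cows$cow_id <- paste0(cows$square, "_cow", cows$cow)
cows$base_ratio <- 0.102 + rnorm(6, 0, 0.005)
cows$LW <- rnorm(6, 690, 25)
cows$ECM <- rnorm(6, 35, 3)
write.csv(cows, file.path(out, "trial_cows.csv"), row.names = FALSE)

visit_index <- list()
headbox_index <- list()
truth <- list()
vid <- 0
for (i in 1:6) {
  for (diet in c("HF", "LF", "MF")) {
    ratio0 <- cows$base_ratio[i] + tcfg$diet_offsets[[diet]]
    true_ch4 <- evaluate_equation(eq2, list(
      LW = cows$LW[i], ECM = cows$ECM[i], CH4CO2 = ratio0))
    # four 15-min head-box replicates per cow-period
    for (k in 1:4) {
      m <- gen_headbox_measurement(true_ch4, true_ratio = ratio0,
                                   noise_sd_ch4 = 5, noise_sd_co2 = 50)
      f <- sprintf("hb_%s_%s_%d.csv", cows$cow_id[i], diet, k)
      write_trace_csv(m$trace, file.path(out, "traces", f))
      headbox_index[[length(headbox_index) + 1]] <- data.frame(
        file = f, cow_id = cows$cow_id[i], square = cows$square[i],
        diet = diet, bg_ch4 = m$bg[["bg_ch4"]], bg_co2 = m$bg[["bg_co2"]])
    }
    # ten AMS visits per cow-period at varying times after eating
    for (v in 1:10) {
      vid <- vid + 1
      tae <- runif(1, 0, 8)
      g <- gen_ams_visit(list(cow_id = cows$cow_id[i],
                              base_ratio = cows$base_ratio[i], diet = diet),
                         tcfg, time_after_eating = tae)
      bg <- gen_background_trace(tcfg)
      fv <- sprintf("ams_%04d.csv", vid)
      fb <- sprintf("bg_%04d.csv", vid)
      write_trace_csv(g$trace, file.path(out, "traces", fv))
      write_trace_csv(bg, file.path(out, "traces", fb))
      visit_index[[length(visit_index) + 1]] <- data.frame(
        visit_id = vid, file = fv, bg_file = fb, cow_id = cows$cow_id[i],
        square = cows$square[i], diet = diet, time_after_eating = tae)
      truth[[length(truth) + 1]] <- data.frame(
        visit_id = vid, latent_ratio = g$truth$latent_ratio,
        n_spikes = g$truth$n_spikes, true_ch4 = true_ch4)
    }
  }
}
write.csv(do.call(rbind, visit_index), file.path(out, "visit_index.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, headbox_index), file.path(out, "headbox_index.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, truth), file.path(out, "truth.csv"),
          row.names = FALSE)
cat(sprintf("trial: %d AMS visits and %d head-box traces written under %s\n",
            vid, length(headbox_index), file.path(out, "traces")))
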