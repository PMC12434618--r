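#!/usr/bin/env Rscript
# Step 2b — semi-corona electric-field statistics and nano-electroporation
# regime map at the three operating fields (150, 300, 650 mT), at 5, 10 and
# 20 nm from the shell surface, for the BV scenario.
#
# Finding: 150 mT stays below the 2e4 V/m response threshold; 300 mT places
# the whole 5 nm corona inside the reversible window (2e4 to 5e4 V/m);
# 650 mT exceeds the 5e4 V/m irreversibility threshold.

suppressPackageStartupMessages(library(menpsim))
dir.create("results", showWarnings = FALSE)

cfg <- scenario_config()
mesh <- build_mesh(cfg$geometry, cfg$mesh_resolution)
op <- suppressMessages(menpsim:::build_coupled_operator(mesh, cfg))
curve <- anhysteretic_curve(cfg$core$Ms_A_per_m, cfg$core$chi0)

rows <- list()
for (H in c(0.15, 0.3, 0.65)) {
  ms <- solve_magnetostatics(mesh, curve, H)
  sol <- menpsim:::solve_coupled_with_operator(op, magnetostrictive_strain(ms$Mz, cfg$core))
  for (d in c(5, 10, 20)) {
    st <- corona_statistics(sol, corona_region(mesh, d, 4000, cfg$random_seed))
    lab <- classify_regime(st)
    rows[[length(rows) + 1]] <- data.frame(
      H_mT = H * 1e3, distance_nm = d, median_V_per_m = st$median,
      p99_V_per_m = st$p99, p1_V_per_m = st$p1, regime = lab$label)
    cat(sprintf("H = %3g mT, d = %2g nm: median %.3g, p1 %.3g, p99 %.3g V/m -> %s\n",
                H * 1e3, d, st$median, st$p1, st$p99, lab$label))
  }
}
write.csv(do.call(rbind, rows), "results/corona_table.csv", row.names = FALSE)
cat("wrote results/corona_table.csv\n")
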