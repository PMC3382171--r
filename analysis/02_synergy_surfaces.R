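#!/usr/bin/env Rscript
# Combination-synergy analysis: checkerboard dose matrices of the primary
# inhibitor (drug A) with the pathway inhibitor (drug B), scored under
# Bliss independence.
#
# The resistant-clone condition is simulated with the rescue model: both
# single agents flat, full kill when both doses clear their gates —
# the situation where the combination works but neither drug does. The
# parental condition is Bliss-additive. Writes ΔBLISS surfaces and synergy
# windows under results/.

suppressMessages(library(metresist))
dir.create("results", showWarnings = FALSE)

flat <- list(lower = 0, upper = 0, ic50 = 1e-9, hill = 1)
kill <- list(lower = 1, upper = 1, ic50 = 1e-9, hill = 1)
doses_a <- build_dilution_ladder(10e-6, 4, 9)   # primary inhibitor
doses_b <- build_dilution_ladder(10e-6, 4, 5)   # pathway inhibitor

asc_a <- sort(as.numeric(doses_a))
asc_b <- sort(as.numeric(doses_b))
conditions <- list(
  # rescue above ~39 nM of A and ~625 nM of B
  clone1 = list(model = "rescue", gate_a = asc_a[5], gate_b = asc_b[3]),
  # rescue above ~39 nM of A and ~2.5 uM of B
  clone3 = list(model = "rescue", gate_a = asc_a[5], gate_b = asc_b[4]),
  parental = list(model = "bliss", gate_a = 0, gate_b = 0)
)

report <- list()
for (nm in names(conditions)) {
  cond <- conditions[[nm]]
  sim <- simulate_combination(flat, flat, cond$model, rescue_params = kill,
                              doses_a = doses_a, doses_b = doses_b,
                              gate_a = cond$gate_a, gate_b = cond$gate_b,
                              noise_cv = 0.02, seed = 10 + match(nm, names(conditions)))
  surf <- delta_bliss_surface(sim$observed, sim$doses_a, sim$doses_b)
  win <- max_synergy_window(surf)
  write_surface_tsv(surf, sprintf("results/synergy_surface_%s.tsv", nm))
  report[[nm]] <- list(max_delta = max(surf$delta),
                       min_excess = min(surf$excess),
                       window = unclass(win))
  if (win$empty) {
    cat(sprintf("%-9s max ΔBLISS %.2f — no synergy window\n", nm,
                max(surf$delta)))
  } else {
    cat(sprintf("%-9s max ΔBLISS %.2f — maximal synergy > %s drug A and > %s drug B\n",
                nm, max(surf$delta),
                format_concentration(win$min_dose_a),
                format_concentration(win$min_dose_b)))
  }
}
write_report_json(report, "results/synergy_windows.json")
cat("\nResistant-clone surfaces reach the ΔBLISS ceiling of 1 (synergy);\n")
cat("the additive parental surface stays near 0. Dose bounds are reported\n")
cat("in the '> X drug A and > Y drug B' convention (exclusive lower bounds).\n")
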