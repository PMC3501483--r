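#!/usr/bin/env Rscript
# Apparent photocurrent kinetics: tau_on / tau_decay from -120 mV Na+
# sweeps, tau_off from the same sweeps' post-light segments, plus
# steady-state/peak inactivation ratios per construct and solution.

source("analysis/_common.R")

man <- load_manifest(file.path(STUDY_DIR, "manifest.json"))
sw <- man$sweeps

kin_idx <- which(sw$solution == "Na" & sw$holding_mV == -120)
kin <- do.call(rbind, lapply(kin_idx, function(i)
  sweep_kinetics(man$load_trace(i))))
write.csv(kin, file.path(TABLE_DIR, "kinetics.csv"), row.names = FALSE)

cat("per-sweep kinetics (", nrow(kin), "sweeps ) ->",
    file.path(TABLE_DIR, "kinetics.csv"), "\n")
for (cn in unique(kin$construct)) {
  k <- kin[kin$construct == cn, ]
  cat(sprintf(
    "  %-12s tau_on %5.2f ms   tau_decay %6.1f ms   tau_off %5.2f ms\n",
    cn, mean(k$tau_on_ms), mean(k$tau_decay_ms), mean(k$tau_off_ms)))
}

ratios <- do.call(rbind, lapply(seq_len(nrow(sw)), function(i) {
  if (sw$holding_mV[i] != -120) return(NULL)
  s <- summarize_sweep(man$load_trace(i))
  data.frame(construct = s$construct, solution = s$solution,
             cell_id = s$cell_id, Iss_over_Ip = s$Iss_over_Ip)
}))
write.csv(ratios, file.path(TABLE_DIR, "inactivation_ratios.csv"),
          row.names = FALSE)
agg <- aggregate(Iss_over_Ip ~ construct + solution, ratios, mean)
cat("mean Iss/Ip at -120 mV (all < 1 under sustained light):\n")
print(agg, row.names = FALSE)
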