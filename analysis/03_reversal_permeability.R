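#!/usr/bin/env Rscript
# Reversal potentials from stationary-current I-V relations, per-cell
# shifts dErev = E_rev,X - E_rev,Na, and GHK permeability ratios.

source("analysis/_common.R")

report <- run_pipeline(file.path(STUDY_DIR, "manifest.json"))

write.csv(report$erev, file.path(TABLE_DIR, "erev.csv"), row.names = FALSE)
write.csv(report$delta_erev, file.path(TABLE_DIR, "delta_erev.csv"),
          row.names = FALSE)
write.csv(report$permeability, file.path(TABLE_DIR, "permeability.csv"),
          row.names = FALSE)

cat("reversal shifts and permeability ratios ->", TABLE_DIR, "\n")
for (cn in unique(report$delta_erev$construct)) {
  d <- report$delta_erev[report$delta_erev$construct == cn, ]
  p <- report$permeability[report$permeability$construct == cn, ]
  cat(sprintf("%s:\n", cn))
  for (k in seq_len(nrow(d)))
    cat(sprintf("  %-3s dErev %+7.2f +- %.2f mV (n=%d)   Px/PNa %.3f\n",
                d$ion[k], d$delta_erev_mV[k], d$sem_mV[k], d$n[k],
                p$ratio[p$ion == d$ion[k]]))
}
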