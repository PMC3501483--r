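# shared settings for the numbered analysis scripts
library(chr2pore)

STUDY_DIR <- "scratch/analysis_study"     # bulky simulated raw data
TABLE_DIR <- "results/tables"             # small derived tables
SEED <- 20260929

# study design: WT plus two serine-swap-like constructs bracketing it --
# one with a constricted pore, one widened -- five alkali baths, the
# full -120..+60 mV family, two cells on one recording day
analysis_config <- function() {
  study_config(
    constructs = c(WT = 3.11, constricted = 2.31, widened = 3.52),
    ions = c("Li", "Na", "K", "Rb", "Cs"),
    n_cells = 2,
    protocol = protocol_spec(sample_rate_Hz = 2000, noise_sd = 0.005),
    expression_cv = 0.2
  )
}

dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)
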