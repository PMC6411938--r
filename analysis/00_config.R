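# Shared study configuration for the analysis scripts.
# Everything downstream is deterministic given this config.

library(pitrimseq)

STUDY_SEED <- 20260921L

study_sim <- function() simulation_config(seed = STUDY_SEED)

study_refs <- function() build_references(study_sim())

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
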