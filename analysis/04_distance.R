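#!/usr/bin/env Rscript
# The core diagnostic: 5'-5' and 3'-3' end-distance profiles of the mutant
# library against the WT top-N uniquely mapped reference piRNAs, plus the
# per-cluster two-track pileup and the phenotype call.

source("analysis/00_config.R")

refs <- study_refs()
wt <- run_pipeline(run_config(sim = study_sim(), mode = "WT"), refs = refs)
mut <- run_pipeline(run_config(sim = study_sim(), mode = "mutant"), refs = refs)
cmp <- suppressWarnings(compare_libraries(wt, mut))

dir <- results_dir("distance")
write_tsv_report(cmp$ref_pirnas, file.path(dir, "reference_pirnas.tsv"))
write_tsv_report(cmp$profile_5p$profile, file.path(dir, "profile_5p.tsv"))
write_tsv_report(cmp$profile_3p$profile, file.path(dir, "profile_3p.tsv"))
write_bed(cmp$pileup$track_a, file.path(dir, "pileup_wt_24_30.bed"))
write_bed(cmp$pileup$track_b, file.path(dir, "pileup_mutant_31_48.bed"))
write_tsv_report(cmp$pileup$shared5, file.path(dir, "pileup_shared5.tsv"))

cat(sprintf("reference piRNAs selected: %d (uniquely mapped, top by count)\n",
            length(unique(cmp$ref_pirnas$sequence))))
cat(sprintf("5'-5' mass at offset 0:   %.4f\n", cmp$mass[["p5_at_zero"]]))
cat(sprintf("3'-3' mass at offset 0:   %.4f\n", cmp$mass[["p3_at_zero"]]))
cat(sprintf("3'-3' downstream (+) mass: %.4f\n", cmp$mass[["p3_positive"]]))
cat(sprintf("3'-3' upstream  (-) mass: %.4f\n", cmp$mass[["p3_negative"]]))
cat(sprintf("shared-5' pairs in pileup window (%s:%d-%d): %d\n",
            cmp$pileup$cluster_id, cmp$pileup$region[1], cmp$pileup$region[2],
            cmp$pileup$n_shared5))
cat(sprintf("3'-extension phenotype: %s\n",
            if (cmp$extension_phenotype) "DETECTED" else "not detected"))
cat("interpretation: mutant reads share WT 5' ends (single 5'-5' peak at 0)\n",
    "with 3' ends displaced only downstream -> defective 3' trimming\n")
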