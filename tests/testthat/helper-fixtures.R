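# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

TEST_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

# small but fully structured simulation: 2 clusters x 50 loci
small_sim <- function(seed = 11L, ...) {
  simulation_config(
    seed = seed, n_clusters = 2L, cluster_length = 4000L,
    n_loci_per_cluster = 50L, n_reads = 8000L,
    decoy_sets = list(coding_RNA = list(n = 6L, length = 600L),
                      noncoding_RNA = list(n = 6L, length = 200L),
                      repeats = list(n = 4L, length = 400L),
                      intron = list(n = 6L, length = 800L)),
    n_mirna_refs = 10L, ...)
}

small_refs <- function() fixture("small_refs", build_references(small_sim()))

small_wt_bundle <- function() fixture("small_wt_bundle", {
  run_pipeline(run_config(sim = small_sim(), mode = "WT"),
               refs = small_refs())
})

small_mut_bundle <- function() fixture("small_mut_bundle", {
  run_pipeline(run_config(sim = small_sim(), mode = "mutant"),
               refs = small_refs())
})

# full-scale simulation at the study conditions (50k reads), for acceptance
full_sim <- function(seed = 101L, ...) simulation_config(seed = seed, ...)

full_refs <- function() fixture("full_refs", build_references(full_sim()))

full_wt_bundle <- function() fixture("full_wt_bundle", {
  run_pipeline(run_config(sim = full_sim(), mode = "WT"), refs = full_refs())
})

full_mut_bundle <- function() fixture("full_mut_bundle", {
  run_pipeline(run_config(sim = full_sim(), mode = "mutant"),
               refs = full_refs())
})

# strip the adapter from a simulated raw read to recover the insert
insert_of <- function(raw_seq, adapter = TEST_ADAPTER) {
  sub(paste0(adapter, ".*$"), "", raw_seq)
}
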