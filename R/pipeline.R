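#' Pipeline run configuration
#'
#' Bundles every tunable of the analysis with the classical defaults: 24-48
#' nt length window, one mismatch for annotation, perfect match for the
#' distance analysis, top 10000 reference piRNAs, a -30..+30 nt window, and
#' 21-23 nt reads as the miRNA normalization proxy.
#'
#' @param sim a [simulation_config()] describing the library to simulate, or
#'   NULL when `fastq` is given.
#' @param fastq path to an input FASTQ (alternative to simulation).
#' @param mode `"WT"` or `"mutant"` (simulation only; NULL follows
#'   `sim$untrimmed_mode`).
#' @param adapter 3' adapter (defaults to the simulator's).
#' @param min_len,max_len inclusive post-clip length filter (nt).
#' @param annotation_max_mismatch substitutions allowed when annotating.
#' @param distance_max_mismatch substitutions allowed in the distance stage.
#' @param top_n reference piRNAs used as anchors.
#' @param half_window distance profile half-width (nt).
#' @param mirna_range inclusive length bounds of the miRNA proxy (nt).
#' @return a `run_config` object.
#' @export
run_config <- function(sim = simulation_config(), fastq = NULL, mode = NULL,
                       adapter = if (!is.null(sim)) sim$adapter else NULL,
                       min_len = 24L, max_len = 48L,
                       annotation_max_mismatch = 1L,
                       distance_max_mismatch = 0L,
                       top_n = 10000L, half_window = 30L,
                       mirna_range = c(21L, 23L)) {
  if (is.null(sim) && is.null(fastq)) stop("either sim or fastq is required")
  if (is.null(adapter)) stop("adapter is required when reading FASTQ input")
  structure(list(sim = sim, fastq = fastq, mode = mode,
                 adapter = toupper(adapter),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 annotation_max_mismatch = as.integer(annotation_max_mismatch),
                 distance_max_mismatch = as.integer(distance_max_mismatch),
                 top_n = as.integer(top_n),
                 half_window = as.integer(half_window),
                 mirna_range = as.integer(mirna_range)),
            class = "run_config")
}

#' Run the full analysis pipeline on one library
#'
#' Stages: simulate (or read FASTQ) -> clip adapter -> collapse -> length
#' filter -> miRNA-normalized length distribution (on the pre-filter
#' library) -> first-nucleotide composition -> hierarchical annotation ->
#' perfect-match alignment to the piRNA clusters. All randomness lives in
#' the simulator; given one config the run is bit-reproducible. When
#' `out_dir` is given, every table is written as TSV/BED plus a
#' `manifest.json` sufficient to re-run identically.
#'
#' @param config a [run_config()].
#' @param refs references from [build_references()]; built from `config$sim`
#'   when NULL. Required when running from FASTQ.
#' @param out_dir optional output directory.
#' @return a result bundle: `config`, `refs`, `ledger`, `reads` (filtered
#'   collapsed reads), `prefilter`, `length_report`, `length_dist`,
#'   `first_nt`, `annotation`, `cluster_aln` (perfect-match, all placements),
#'   `truth` (simulation only), `mode`.
#' @export
run_pipeline <- function(config, refs = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  mode <- config$mode
  if (!is.null(config$fastq)) {
    if (is.null(refs)) stop("refs must be supplied when running from FASTQ")
    raw <- read_fastq(config$fastq)
    if (is.null(mode)) mode <- "input"
  } else {
    if (is.null(refs)) refs <- build_references(config$sim)
    lib <- simulate_library(refs, mode = config$mode)
    raw <- lib$reads
    truth <- lib$truth
    mode <- lib$mode
  }
  pre <- preprocess_reads(
    raw, clip_config(config$adapter, min_len = config$min_len,
                     max_len = config$max_len))
  ldist <- length_distribution(pre$prefilter, normalize = TRUE)
  comp <- first_nt_composition(pre$reads)
  ann <- annotate_hierarchical(
    pre$reads, refs$ref_sets,
    align_config(max_mismatch = config$annotation_max_mismatch,
                 report = "any"))
  cluster_aln <- align_reads(
    pre$reads, refs$ref_sets[[1L]],
    align_config(max_mismatch = config$distance_max_mismatch, report = "all"))

  bundle <- list(config = config, refs = refs, mode = mode,
                 ledger = pre$ledger, reads = pre$reads,
                 prefilter = pre$prefilter,
                 length_report = pre$length_report,
                 length_dist = ldist, first_nt = comp$composition,
                 annotation = ann$summary, assignments = ann$assignments,
                 cluster_aln = cluster_aln, truth = truth)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tsv_report(bundle$length_dist, p("length_distribution.tsv"))
  write_tsv_report(bundle$length_report, p("length_report.tsv"))
  write_tsv_report(bundle$first_nt, p("first_nt_composition.tsv"))
  write_tsv_report(bundle$annotation, p("annotation.tsv"))
  write_tsv_report(bundle$assignments, p("assignments.tsv"))
  write_bed(bundle$cluster_aln, p("cluster_alignments.bed"))
  write_fasta_reads(bundle$reads, p("reads_collapsed.fa"))
  if (!is.null(bundle$truth)) write_tsv_report(bundle$truth, p("truth.tsv"))
  manifest <- list(
    package = "pitrimseq",
    version = as.character(utils::packageVersion("pitrimseq")),
    mode = bundle$mode,
    seed = if (!is.null(bundle$config$sim)) bundle$config$sim$seed else NULL,
    config = serialize_config(bundle$config),
    ledger = as.list(bundle$ledger),
    outputs = c("length_distribution.tsv", "length_report.tsv",
                "first_nt_composition.tsv", "annotation.tsv",
                "assignments.tsv", "cluster_alignments.bed",
                "reads_collapsed.fa",
                if (!is.null(bundle$truth)) "truth.tsv"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$sim)) {
    sim <- unclass(cfg$sim)
    sim$mature_length_dist <- as.list(sim$mature_length_dist)
    sim$extension_dist <- as.list(sim$extension_dist)
    cfg$sim <- sim
  }
  cfg
}

#' Rebuild a run_config from a written manifest and re-run the pipeline
#' @param manifest_path path to a `manifest.json` written by [run_pipeline()].
#' @param out_dir output directory for the re-run.
#' @return the result bundle (see [run_pipeline()]).
#' @export
run_from_manifest <- function(manifest_path, out_dir = NULL) {
  m <- jsonlite::read_json(manifest_path)
  cfg <- m$config
  # JSON has no scalar NULL: empty lists read back from omitted fields
  nn <- function(x) if (length(x) == 0L) NULL else x
  cfg$fastq <- nn(cfg$fastq)
  cfg$mode <- nn(cfg$mode)
  sim <- NULL
  if (!is.null(cfg$sim)) {
    s <- cfg$sim
    sim <- simulation_config(
      seed = s$seed, n_clusters = s$n_clusters,
      cluster_length = s$cluster_length,
      n_loci_per_cluster = s$n_loci_per_cluster,
      mature_length_dist = unlist(s$mature_length_dist),
      extension_dist = unlist(s$extension_dist),
      u_bias = s$u_bias, abundance_exponent = s$abundance_exponent,
      n_reads = s$n_reads, mirna_fraction = s$mirna_fraction,
      decoy_read_fraction = s$decoy_read_fraction, adapter = s$adapter,
      decoy_sets = lapply(s$decoy_sets, function(d)
        list(n = d$n, length = d$length)),
      n_mirna_refs = s$n_mirna_refs, untrimmed_mode = isTRUE(s$untrimmed_mode))
  }
  config <- run_config(
    sim = sim, fastq = cfg$fastq, mode = cfg$mode, adapter = cfg$adapter,
    min_len = cfg$min_len, max_len = cfg$max_len,
    annotation_max_mismatch = cfg$annotation_max_mismatch,
    distance_max_mismatch = cfg$distance_max_mismatch, top_n = cfg$top_n,
    half_window = cfg$half_window, mirna_range = unlist(cfg$mirna_range))
  run_pipeline(config, out_dir = out_dir)
}

#' Compare a query library against a wild-type library
#'
#' Anchors the comparison on the wild-type library: selects its top-N
#' uniquely mapped reference piRNAs, profiles the query's 5'-5' and 3'-3'
#' end distances against them, sets length distributions and first-base
#' compositions side by side, and renders a two-track pileup over the
#' densest cluster. The 3'-extension phenotype is flagged when the 3'-3'
#' positive-offset mass strictly exceeds `flag_3p_positive` while the 5'-5'
#' mass at offset 0 strictly exceeds `flag_5p_peak` (shared 5' ends with
#' extended 3' ends — the trimming-defect signature).
#'
#' @param wt_bundle,query_bundle result bundles from [run_pipeline()] built
#'   on the same reference set.
#' @param flag_5p_peak,flag_3p_positive phenotype-call thresholds on profile
#'   mass.
#' @param pileup_region `c(start, end)` within the densest cluster for the
#'   pileup view (default the first 2 kb).
#' @return list with `ref_pirnas`, `profile_5p`, `profile_3p`,
#'   `length_compare`, `first_nt_compare`, `pileup`, `mass` (named summary
#'   masses) and `extension_phenotype` (logical flag).
#' @export
compare_libraries <- function(wt_bundle, query_bundle,
                              flag_5p_peak = 0.8, flag_3p_positive = 0.25,
                              pileup_region = c(0L, 2000L)) {
  if (!identical(wt_bundle$refs$ref_sets[[1L]]$sequences,
                 query_bundle$refs$ref_sets[[1L]]$sequences)) {
    stop("bundles were built on different piRNA cluster references")
  }
  cfg <- wt_bundle$config
  refs <- select_reference_pirnas(
    wt_bundle$reads, wt_bundle$refs$ref_sets[[1L]], n = cfg$top_n)
  p5 <- distance_profile(refs, query_bundle$cluster_aln, end = "5p",
                         half_window = cfg$half_window)
  p3 <- distance_profile(refs, query_bundle$cluster_aln, end = "3p",
                         half_window = cfg$half_window)
  mass <- c(
    p5_at_zero = profile_mass(p5, 0L, 0L),
    p3_at_zero = profile_mass(p3, 0L, 0L),
    p3_positive = profile_mass(p3, 1L, cfg$half_window),
    p3_negative = profile_mass(p3, -cfg$half_window, -1L))
  flag <- mass[["p3_positive"]] > flag_3p_positive &&
    mass[["p5_at_zero"]] > flag_5p_peak
  ldc <- merge(wt_bundle$length_dist, query_bundle$length_dist,
               by = "length", suffixes = c("_wt", "_query"))
  fnc <- merge(wt_bundle$first_nt, query_bundle$first_nt,
               by = "base", suffixes = c("_wt", "_query"))
  dens <- tapply(wt_bundle$cluster_aln$count, wt_bundle$cluster_aln$ref_id, sum)
  top_cluster <- names(dens)[which.max(dens)]
  pileup <- cluster_pileup(
    wt_bundle$cluster_aln, query_bundle$cluster_aln, top_cluster,
    pileup_region,
    known_clusters = wt_bundle$refs$ref_sets[[1L]]$ids)
  list(ref_pirnas = refs, profile_5p = p5, profile_3p = p3,
       length_compare = ldc, first_nt_compare = fnc, pileup = pileup,
       mass = mass, extension_phenotype = flag)
}

#' Mass of a distance profile over an offset range
#' @param profile result of [distance_profile()].
#' @param from,to inclusive offset bounds.
#' @return summed frequency over the range.
#' @export
profile_mass <- function(profile, from, to) {
  p <- profile$profile
  sum(p$frequency[p$offset >= from & p$offset <= to])
}
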