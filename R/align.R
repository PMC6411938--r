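#' Alignment configuration
#'
#' Two settings cover the pipeline's needs: annotation uses up to one
#' substitution and any-hit reporting (existence of a match is all that
#' matters); end-distance analysis uses perfect match with all placements
#' reported (positions matter).
#'
#' @param max_mismatch 0 or 1 substitutions allowed (no indels).
#' @param strands `"both"` (default; cluster loci sit on either strand) or
#'   `"plus_only"` for transcript-oriented reference sets.
#' @param report `"all"` placements or `"any"` (one deterministic hit per
#'   read if any exists).
#' @return an `align_config` object.
#' @export
align_config <- function(max_mismatch = 0L, strands = c("both", "plus_only"),
                         report = c("all", "any")) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  structure(list(max_mismatch = as.integer(max_mismatch),
                 strands = match.arg(strands),
                 report = match.arg(report)),
            class = "align_config")
}

align_result <- function(hits, reads, ref) {
  if (nrow(hits) == 0L) {
    return(data.frame(read_id = character(), ref_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      count = numeric(), stringsAsFactors = FALSE))
  }
  len <- nchar(reads$sequence)[hits$read]
  out <- data.frame(read_id = reads$id[hits$read],
                    ref_id = ref$ids[hits$ref],
                    start = hits$start,
                    end = hits$start + len,
                    strand = ifelse(hits$strand > 0L, "+", "-"),
                    mismatches = hits$mismatches,
                    count = reads$count[hits$read],
                    stringsAsFactors = FALSE)
  # deterministic ordering: reference id, start, strand, then read id
  out[order(out$ref_id, out$start, out$strand, out$read_id), , drop = FALSE]
}

drop_n_reads <- function(reads) {
  ok <- !grepl("[^ACGT]", reads$sequence)
  if (!all(ok)) {
    message(sum(!ok), " read(s) containing non-ACGT bases dropped before alignment")
  }
  reads[ok, , drop = FALSE]
}

#' Ungapped alignment of collapsed reads to a reference set
#'
#' Substitution-only end-to-end placement of each read (and, for
#' `strands = "both"`, its reverse complement) on every reference sequence,
#' via an exact 12-mer seed index with pigeonhole guarantee for up to one
#' mismatch. Coordinates are 0-based half-open on the reference; a
#' minus-strand hit means the reverse complement of the read matches
#' `reference[start:end]`. N-containing reads are dropped (and counted) up
#' front.
#'
#' @param reads collapsed read data.frame (`id`, `sequence`, `count`).
#' @param ref a [reference_set()].
#' @param config an [align_config()].
#' @return alignment data.frame: `read_id`, `ref_id`, `start`, `end`,
#'   `strand`, `mismatches`, `count`.
#' @export
align_reads <- function(reads, ref, config = align_config()) {
  stopifnot(inherits(ref, "reference_set"), inherits(config, "align_config"))
  reads <- drop_n_reads(reads)
  if (!"count" %in% names(reads)) reads$count <- 1
  if (nrow(reads) == 0L) return(align_result(empty_hits(), reads, ref))
  if (any(nchar(reads$sequence) < 24L) && config$max_mismatch > 0L) {
    stop("reads shorter than 24 nt cannot be aligned with mismatches ",
         "(seed guarantee requires two disjoint 12-mers)")
  }
  if (any(nchar(reads$sequence) < 12L)) {
    stop("reads shorter than 12 nt are not supported by the seed index")
  }
  hits <- cpp_align_seed(reads$sequence, ref$sequences, config$max_mismatch,
                         config$strands == "both", config$report == "all")
  align_result(hits, reads, ref)
}

#' Exhaustive-scan alignment oracle
#'
#' Same contract as [align_reads()], implemented as a brute-force Hamming
#' scan over every reference position and strand. Quadratic; used in tests
#' as the correctness oracle for the seeded aligner.
#'
#' @inheritParams align_reads
#' @return alignment data.frame identical in layout to [align_reads()].
#' @export
brute_force_align <- function(reads, ref, config = align_config()) {
  stopifnot(inherits(ref, "reference_set"), inherits(config, "align_config"))
  reads <- drop_n_reads(reads)
  if (!"count" %in% names(reads)) reads$count <- 1
  if (nrow(reads) == 0L) return(align_result(empty_hits(), reads, ref))
  hits <- cpp_align_brute(reads$sequence, ref$sequences, config$max_mismatch,
                          config$strands == "both", config$report == "all")
  align_result(hits, reads, ref)
}

empty_hits <- function() {
  data.frame(read = integer(), ref = integer(), start = integer(),
             strand = integer(), mismatches = integer())
}
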