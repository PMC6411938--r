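#' Select top-N uniquely mapped reference piRNAs from a wild-type library
#'
#' Among distinct 24-48 nt sequences with exactly one perfect-match placement
#' across the piRNA cluster references (both strands), returns the N most
#' abundant, with deterministic tie-break (count descending, then sequence).
#' These serve as positional anchors for the end-distance profiles: the 5'
#' and 3' ends of each reference define offset 0. With
#' `unique_only = FALSE`, multi-mapping sequences are kept and every
#' placement becomes an anchor ("distinct" rather than "unique" reading).
#'
#' @param wt_reads collapsed, length-filtered wild-type reads.
#' @param cluster_ref the piRNA cluster [reference_set()].
#' @param n number of references to keep (classically 10000).
#' @param unique_only require exactly one perfect-match placement (default).
#' @return data.frame: `sequence`, `cluster_id`, `strand`, `anchor5`,
#'   `anchor3` (genomic positions of the 5'/3' terminal nucleotides,
#'   0-based), `count`, `rank`.
#' @export
select_reference_pirnas <- function(wt_reads, cluster_ref, n = 10000L,
                                    unique_only = TRUE) {
  aln <- align_reads(wt_reads, cluster_ref,
                     align_config(max_mismatch = 0L, report = "all"))
  if (nrow(aln) == 0L) stop("no wild-type read has a perfect-match placement ",
                            "on the piRNA cluster references")
  placements <- table(aln$read_id)
  keep_ids <- if (unique_only) names(placements)[placements == 1L]
              else names(placements)
  if (length(keep_ids) == 0L) {
    stop("no uniquely mapped wild-type sequence qualifies as a reference")
  }
  aln <- aln[aln$read_id %in% keep_ids, , drop = FALSE]
  seqs <- setNames(wt_reads$sequence, wt_reads$id)[aln$read_id]
  refs <- data.frame(
    sequence = unname(seqs),
    cluster_id = aln$ref_id,
    strand = aln$strand,
    anchor5 = ifelse(aln$strand == "+", aln$start, aln$end - 1L),
    anchor3 = ifelse(aln$strand == "+", aln$end - 1L, aln$start),
    count = aln$count,
    stringsAsFactors = FALSE)
  # rank distinct sequences by abundance; a multi-mapper (unique_only = FALSE)
  # keeps one rank across its placements
  seq_rank <- unique(refs[, c("sequence", "count")])
  seq_rank <- seq_rank[order(-seq_rank$count, seq_rank$sequence), , drop = FALSE]
  if (nrow(seq_rank) < n) {
    warning("only ", nrow(seq_rank), " qualifying reference sequences ",
            "(requested ", n, "); returning all")
  }
  seq_rank$rank <- seq_len(nrow(seq_rank))
  top <- seq_rank$sequence[seq_rank$rank <= n]
  refs <- refs[refs$sequence %in% top, , drop = FALSE]
  refs$rank <- seq_rank$rank[match(refs$sequence, seq_rank$sequence)]
  refs <- refs[order(refs$rank, refs$cluster_id, refs$anchor5), , drop = FALSE]
  rownames(refs) <- NULL
  refs
}

#' 5'-5' or 3'-3' end-distance frequency profile
#'
#' For every perfect-match query alignment on the same cluster and strand as
#' a reference piRNA, the signed offset of the query's corresponding end (5'
#' end in `5p` mode, 3' end in `3p` mode) from the reference anchor is
#' measured, with positive meaning downstream along the reference piRNA's
#' own 5'->3' orientation (so a 3' extension is a positive offset on either
#' genomic strand). Offsets within `half_window` accumulate count-weighted;
#' frequencies are normalized over in-window events. A query alignment is
#' scored against every reference whose anchor lies within the window.
#'
#' @param references reference piRNA table from [select_reference_pirnas()].
#' @param query_aln perfect-match query alignments on the cluster references
#'   (from [align_reads()] with `max_mismatch = 0, report = "all"`).
#' @param end `"5p"` or `"3p"`.
#' @param half_window window half-width in nt (profile spans -half_window..
#'   +half_window).
#' @param multimapper `"full"` (every placement contributes the read's full
#'   count) or `"fractional"` (count split evenly across placements).
#' @return list with `end`, `profile` (data.frame: offset, events,
#'   frequency) and `total` in-window events. A zero-event profile is
#'   returned all-zero with a warning.
#' @export
distance_profile <- function(references, query_aln, end = c("5p", "3p"),
                             half_window = 30L,
                             multimapper = c("full", "fractional")) {
  end <- match.arg(end)
  multimapper <- match.arg(multimapper)
  if (nrow(references) == 0L) stop("empty reference piRNA list")
  offsets <- seq(-half_window, half_window)
  if (nrow(query_aln) == 0L) {
    warning("no query alignments; returning an all-zero profile")
    return(list(end = end,
                profile = data.frame(offset = offsets, events = 0,
                                     frequency = 0),
                total = 0))
  }
  w <- query_aln$count
  if (multimapper == "fractional") {
    npl <- table(query_aln$read_id)
    w <- w / as.numeric(npl[query_aln$read_id])
  }
  qpos <- if (end == "5p") {
    ifelse(query_aln$strand == "+", query_aln$start, query_aln$end - 1L)
  } else {
    ifelse(query_aln$strand == "+", query_aln$end - 1L, query_aln$start)
  }
  key <- paste(query_aln$ref_id, query_aln$strand, qpos)
  wmap <- tapply(w, key, sum)
  anchor <- if (end == "5p") references$anchor5 else references$anchor3
  dir <- ifelse(references$strand == "+", 1L, -1L)
  events <- vapply(offsets, function(d) {
    k <- paste(references$cluster_id, references$strand, anchor + d * dir)
    sum(wmap[k], na.rm = TRUE)
  }, numeric(1))
  total <- sum(events)
  if (total == 0) {
    warning("no query end falls within the window of any reference anchor")
    freq <- rep(0, length(offsets))
  } else {
    freq <- events / total
  }
  list(end = end,
       profile = data.frame(offset = offsets, events = events,
                            frequency = freq),
       total = total)
}

#' Two-library read pileup over a cluster region, split by length class
#'
#' Extracts perfect-match alignments of two libraries inside one cluster
#' region and partitions them into length classes (classically 24-30 nt
#' mature piRNAs vs 31-48 nt extended intermediates). Shared-5' pairs —
#' the same genomic 5' position and strand occurring in both tracks — are
#' counted: they are the per-locus signature of an untrimmed intermediate
#' over its mature piRNA.
#'
#' @param aln_a,aln_b alignment data.frames (e.g. WT and mutant libraries).
#' @param cluster_id cluster reference id to extract.
#' @param region `c(start, end)` 0-based half-open interval; alignments must
#'   lie fully inside.
#' @param class_a,class_b inclusive read-length bounds for the two tracks.
#' @param known_clusters optional character vector of valid cluster ids; if
#'   supplied, an unknown `cluster_id` is an error.
#' @return list with `cluster_id`, `region`, `track_a`, `track_b` (each
#'   ordered by start) and `shared5` (data.frame of shared 5'-end positions
#'   with per-track counts) plus `n_shared5`.
#' @export
cluster_pileup <- function(aln_a, aln_b, cluster_id, region,
                           class_a = c(24L, 30L), class_b = c(31L, 48L),
                           known_clusters = NULL) {
  if (!is.null(known_clusters) && !(cluster_id %in% known_clusters)) {
    stop("unknown cluster id: ", cluster_id)
  }
  stopifnot(length(region) == 2L, region[1] < region[2])
  pick <- function(aln, class) {
    len <- aln$end - aln$start
    sel <- aln$ref_id == cluster_id & aln$start >= region[1] &
      aln$end <= region[2] & len >= class[1] & len <= class[2]
    out <- aln[sel, , drop = FALSE]
    out[order(out$start, out$end, out$strand), , drop = FALSE]
  }
  a <- pick(aln_a, class_a)
  b <- pick(aln_b, class_b)
  g5 <- function(x) ifelse(x$strand == "+", x$start, x$end - 1L)
  key_a <- paste(g5(a), a$strand)
  key_b <- paste(g5(b), b$strand)
  shared_keys <- intersect(unique(key_a), unique(key_b))
  shared5 <- if (length(shared_keys)) {
    parts <- do.call(rbind, strsplit(shared_keys, " ", fixed = TRUE))
    data.frame(g5 = as.integer(parts[, 1L]), strand = parts[, 2L],
               count_a = vapply(shared_keys, function(k)
                 sum(a$count[key_a == k]), numeric(1)),
               count_b = vapply(shared_keys, function(k)
                 sum(b$count[key_b == k]), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(g5 = integer(), strand = character(),
               count_a = numeric(), count_b = numeric(),
               stringsAsFactors = FALSE)
  }
  list(cluster_id = cluster_id, region = region, track_a = a, track_b = b,
       shared5 = shared5[order(shared5$g5), , drop = FALSE],
       n_shared5 = nrow(shared5))
}
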