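#' Adapter clipping configuration
#'
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length that counts as a match.
#' @param max_mismatch_per_overlap substitutions tolerated in the matched
#'   adapter prefix (0 for error-free simulated reads).
#' @param min_len,max_len inclusive length bounds applied after clipping
#'   (24-48 nt, the piRNA/pre-piRNA analysis window).
#' @return a `clip_config` object.
#' @export
clip_config <- function(adapter, min_overlap = 6L, max_mismatch_per_overlap = 0L,
                        min_len = 24L, max_len = 48L) {
  adapter <- toupper(adapter)
  if (nchar(adapter) < min_overlap) {
    stop("adapter (", nchar(adapter), " nt) is shorter than min_overlap (",
         min_overlap, ")")
  }
  stopifnot(min_overlap >= 1L, min_len <= max_len)
  structure(list(adapter = adapter, min_overlap = as.integer(min_overlap),
                 max_mismatch = as.integer(max_mismatch_per_overlap),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "clip_config")
}

clip_one <- function(seq, config) {
  n <- nchar(seq)
  ad <- config$adapter
  an <- nchar(ad)
  # leftmost position where a >= min_overlap adapter prefix matches: either
  # the full adapter occurs inside the read, or a read suffix matches an
  # adapter prefix at the 3' end
  for (i in seq_len(n - config$min_overlap + 1L)) {
    k <- min(an, n - i + 1L)
    frag <- substr(seq, i, i + k - 1L)
    pre <- substr(ad, 1L, k)
    if (config$max_mismatch == 0L) {
      hit <- frag == pre
    } else {
      d <- sum(strsplit(frag, "")[[1]] != strsplit(pre, "")[[1]])
      hit <- d <= config$max_mismatch
    }
    if (hit) {
      insert <- substr(seq, 1L, i - 1L)
      return(list(sequence = insert,
                  status = if (i == 1L) "empty_after_clip" else "clipped"))
    }
  }
  list(sequence = seq, status = "no_adapter")
}

#' Clip 3' sequencing-adapter read-through
#'
#' Finds the leftmost occurrence of an adapter prefix of length >=
#' `min_overlap` anywhere in the read (a full internal adapter match, or a
#' read-suffix vs adapter-prefix match at the 3' end) and returns the bases
#' 5' of it. Reads without an adapter match are returned unchanged with
#' status `no_adapter`: they may be genuine long intermediates whose adapter
#' fell off the read end, so they are kept and reported rather than dropped.
#'
#' @param sequences character vector of read sequences.
#' @param config a [clip_config()].
#' @return data.frame with `sequence` (clipped) and `status`
#'   (`clipped` / `no_adapter` / `empty_after_clip`).
#' @export
clip_adapter <- function(sequences, config) {
  stopifnot(inherits(config, "clip_config"))
  sequences <- toupper(sequences)
  # exact-match fast path: regexpr on the two match classes
  if (config$max_mismatch == 0L) {
    full <- regexpr(config$adapter, sequences, fixed = TRUE)
    pos <- ifelse(full > 0L, full, NA_integer_)
    # 3'-end partial adapter (read suffix = adapter prefix, >= min_overlap)
    an <- nchar(config$adapter)
    ks <- if (an - 1L >= config$min_overlap) seq(an - 1L, config$min_overlap) else integer(0)
    for (k in ks) {
      sub <- which(is.na(pos) | pos > nchar(sequences) - k + 1L)
      if (!length(sub)) break
      hit <- endsWith(sequences[sub], substr(config$adapter, 1L, k))
      cand <- nchar(sequences[sub]) - k + 1L
      upd <- sub[hit & (is.na(pos[sub]) | cand < pos[sub])]
      pos[upd] <- nchar(sequences[upd]) - k + 1L
    }
    status <- ifelse(is.na(pos), "no_adapter",
                     ifelse(pos == 1L, "empty_after_clip", "clipped"))
    clipped <- ifelse(is.na(pos), sequences,
                      substr(sequences, 1L, ifelse(is.na(pos), 0L, pos) - 1L))
    return(data.frame(sequence = clipped, status = status,
                      stringsAsFactors = FALSE))
  }
  out <- lapply(sequences, clip_one, config = config)
  data.frame(sequence = vapply(out, `[[`, character(1), "sequence"),
             status = vapply(out, `[[`, character(1), "status"),
             stringsAsFactors = FALSE)
}

#' Filter collapsed reads by insert length
#'
#' Retains reads with `min_len <= length <= max_len` (both bounds
#' inclusive) and reports count-weighted retained/discarded tallies per
#' length.
#'
#' @param reads collapsed read data.frame (`id`, `sequence`, `count`).
#' @param min_len,max_len inclusive bounds (nt).
#' @return list with `retained` (data.frame), `discarded` (data.frame) and
#'   `report` (data.frame: length, retained, discarded — count-weighted).
#' @export
filter_by_length <- function(reads, min_len = 24L, max_len = 48L) {
  stopifnot(min_len <= max_len)
  len <- nchar(reads$sequence)
  keep <- len >= min_len & len <= max_len
  lens <- sort(unique(len))
  report <- data.frame(
    length = lens,
    retained = vapply(lens, function(l)
      sum(reads$count[keep & len == l]), numeric(1)),
    discarded = vapply(lens, function(l)
      sum(reads$count[!keep & len == l]), numeric(1)))
  list(retained = reads[keep, , drop = FALSE],
       discarded = reads[!keep, , drop = FALSE],
       report = report)
}

#' Clip, collapse and length-filter a raw read table
#'
#' Convenience wrapper running the full preprocess stage on raw FASTQ reads:
#' collapse to distinct sequences, clip adapter read-through, re-collapse
#' (clipping can merge sequences), then apply the length filter. The ledger
#' records count-weighted totals at each step.
#'
#' @param raw data.frame of raw reads (`id`, `sequence`), e.g. from
#'   [read_fastq()].
#' @param config a [clip_config()].
#' @return list with `reads` (retained collapsed reads), `prefilter`
#'   (collapsed clipped reads before the length filter, used for the miRNA
#'   normalization proxy), `length_report`, and `ledger` (named counts).
#' @export
preprocess_reads <- function(raw, config) {
  collapsed <- collapse_reads(raw$sequence)
  clip <- clip_adapter(collapsed$sequence, config)
  status_counts <- tapply(collapsed$count, clip$status, sum)
  keep <- clip$status != "empty_after_clip" & nchar(clip$sequence) > 0L
  reclps <- collapse_reads(rep(clip$sequence[keep], collapsed$count[keep]))
  flt <- filter_by_length(reclps, config$min_len, config$max_len)
  ledger <- c(raw = sum(collapsed$count),
              clipped = unname(status_counts["clipped"]) %||% 0,
              no_adapter = unname(status_counts["no_adapter"]) %||% 0,
              empty_after_clip = unname(status_counts["empty_after_clip"]) %||% 0,
              prefilter = sum(reclps$count),
              retained = sum(flt$retained$count),
              discarded = sum(flt$discarded$count))
  list(reads = flt$retained, prefilter = reclps,
       length_report = flt$report, ledger = ledger)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
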