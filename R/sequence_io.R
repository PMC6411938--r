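#' @useDynLib pitrimseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rmultinom setNames
#' @importFrom utils read.delim write.table
NULL

CATEGORIES <- c("piRNA_cluster", "coding_RNA", "noncoding_RNA", "repeats", "intron")

#' Read a FASTQ file as an (id, sequence) table
#'
#' Minimal 4-line FASTQ reader; quality strings are validated for length but
#' not retained (no downstream stage uses base qualities). Gzip input is
#' handled transparently.
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return data.frame with columns `id`, `sequence`, in file order.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at record index ", length(lines) %/% 4L + 1L)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
  if (length(bad)) stop("malformed FASTQ record at record index ", bad[1L])
  badq <- which(nchar(seq) != nchar(qual))
  if (length(badq)) {
    stop("sequence/quality length mismatch at record index ", badq[1L],
         " (id ", sub("^@", "", hdr[badq[1L]]), ")")
  }
  data.frame(id = sub("\\s.*$", "", sub("^@", "", hdr)),
             sequence = toupper(seq), stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33, constant quality)
#'
#' @param reads data.frame with `id` and `sequence`.
#' @param path output path; a ".gz" suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence),
                 function(n) paste(rep("I", n), collapse = ""), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$sequence, "+", qual)),
             con)
  invisible(path)
}

#' Collapse raw reads to distinct sequences with counts
#'
#' Collapsing is lossless: the counts sum to the raw read total, and every
#' downstream statistic is count-weighted so results equal the per-read
#' computation. Output is sorted by count (descending), then sequence.
#'
#' @param sequences character vector of raw read sequences.
#' @return data.frame with `id` (`seq<rank>`), `sequence`, `count`.
#' @export
collapse_reads <- function(sequences) {
  if (length(sequences) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  out$id <- sprintf("seq%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("id", "sequence", "count")]
}

#' Read references or collapsed reads from FASTA
#'
#' Headers of the form `>{id}_x{count}` (the common small-RNA collapsed
#' dialect) are parsed into counts; any other header yields count 1.
#'
#' @param path FASTA file, optionally gzipped.
#' @return data.frame with `id`, `sequence`, `count`.
#' @export
read_fasta_reads <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  m <- regmatches(ids, regexec("^(.*)_x(\\d+)$", ids))
  count <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[3L]) else 1L,
                  integer(1))
  id <- vapply(seq_along(m), function(i) {
    if (length(m[[i]]) == 3L) m[[i]][2L] else ids[i]
  }, character(1))
  data.frame(id = id, sequence = as.character(ss), count = count,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write collapsed reads to FASTA with `>{id}_x{count}` headers
#' @param reads collapsed read data.frame (`id`, `sequence`, `count`).
#' @param path output path.
#' @export
write_fasta_reads <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- sprintf("%s_x%d", reads$id, reads$count)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a category-labeled reference set
#'
#' @param category one of `piRNA_cluster`, `coding_RNA`, `noncoding_RNA`,
#'   `repeats`, `intron`.
#' @param sequences named character vector (or DNAStringSet) of references.
#' @param priority integer rank in the annotation order (1 = first tried).
#' @return a `reference_set` object.
#' @export
reference_set <- function(category, sequences, priority) {
  category <- match.arg(category, CATEGORIES)
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  structure(list(category = category,
                 ids = names(sequences),
                 sequences = unname(toupper(sequences)),
                 priority = as.integer(priority)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %s (priority %d): %d sequence(s), %d nt total\n",
              x$category, x$priority, length(x$sequences),
              sum(nchar(x$sequences))))
  invisible(x)
}

#' Load a reference FASTA into a reference_set
#' @inheritParams reference_set
#' @param path FASTA file.
#' @export
read_reference_set <- function(path, category, priority) {
  ss <- Biostrings::readDNAStringSet(path)
  reference_set(category, ss, priority)
}

#' Validate an ordered list of reference sets for hierarchical annotation
#' @param ref_sets list of `reference_set` objects.
#' @return the list, ordered by priority.
#' @export
check_reference_order <- function(ref_sets) {
  stopifnot(all(vapply(ref_sets, inherits, logical(1), "reference_set")))
  pr <- vapply(ref_sets, `[[`, integer(1), "priority")
  if (anyDuplicated(pr)) stop("duplicate reference set priorities: ",
                              paste(pr[duplicated(pr)], collapse = ", "))
  if (!setequal(pr, seq_along(ref_sets))) {
    stop("reference set priorities must be exactly 1..",
         length(ref_sets), ", got: ", paste(sort(pr), collapse = ", "))
  }
  ref_sets[order(pr)]
}

#' Write alignments as BED6
#'
#' Columns: chrom (reference id), start, end (0-based half-open), name
#' (read id), score (read count), strand. Minus-strand alignments keep
#' genomic start < end.
#'
#' @param alignments alignment data.frame (see [align_reads()]).
#' @param path output path.
#' @export
write_bed <- function(alignments, path) {
  bed <- data.frame(chrom = alignments$ref_id,
                    start = alignments$start,
                    end = alignments$end,
                    name = alignments$read_id,
                    score = alignments$count,
                    strand = alignments$strand,
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file written by [write_bed()]
#' @param path BED6 file, optionally gzipped.
#' @return data.frame with `read_id`, `ref_id`, `start`, `end`, `strand`,
#'   `count` (0-based half-open coordinates).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), ref_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 6L)
  if (length(bad)) stop("malformed BED6 line ", bad[1L], " in ", path)
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  score <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start) | is.na(end) | is.na(score) |
                 !(m[, 6L] %in% c("+", "-")) | start >= end)
  if (length(bad)) stop("malformed BED6 line ", bad[1L], " in ", path)
  data.frame(read_id = m[, 4L], ref_id = m[, 1L], start = start, end = end,
             strand = m[, 6L], count = score, stringsAsFactors = FALSE)
}

#' Write a data.frame as a TSV report
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv_report <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
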