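#' miRNA-normalized read length distribution
#'
#' Count-weighted histogram of read lengths over 18-48 nt. When
#' `normalize = TRUE`, each bin is scaled by `1e6 / (total count of 21-23 nt
#' reads)` — reads per million miRNA-proxy reads — so libraries of different
#' depths are comparable. The proxy is taken literally as all 21-23 nt reads
#' (a reference-matched variant can be obtained by pre-filtering `reads`).
#'
#' @param reads collapsed read data.frame (`sequence`, `count`); should be
#'   the pre-length-filter library so the 21-23 nt proxy reads are present.
#' @param normalize scale by the miRNA proxy (default TRUE).
#' @param range lengths reported (default 18:48; observed lengths outside
#'   the range are still tallied and appended).
#' @return data.frame: `length`, `raw` (count-weighted reads), `normalized`
#'   (NA when `normalize = FALSE`).
#' @export
length_distribution <- function(reads, normalize = TRUE, range = 18:48) {
  len <- nchar(reads$sequence)
  lens <- sort(unique(c(range, len)))
  raw <- vapply(lens, function(l) sum(reads$count[len == l]), numeric(1))
  out <- data.frame(length = lens, raw = raw)
  if (normalize) {
    proxy <- sum(reads$count[len >= 21L & len <= 23L])
    if (proxy == 0) {
      stop("cannot normalize: no 21-23 nt (miRNA proxy) reads in the library")
    }
    out$normalized <- out$raw * 1e6 / proxy
  } else {
    out$normalized <- NA_real_
  }
  out
}

#' First-nucleotide (position 1) composition
#'
#' Count-weighted frequencies of the 5'-most base of each read, as
#' sequenced. A strong U(T) fraction at position 1 is the primary-piRNA 1U
#' hallmark. Reads starting with a base outside ACGT are excluded from the
#' frequencies and reported.
#'
#' @param reads collapsed read data.frame, length-filtered to the 24-48 nt
#'   analysis window.
#' @return list with `composition` (data.frame: base in A,C,G,U; fraction)
#'   and `excluded` (count-weighted reads with non-ACGT first base).
#' @export
first_nt_composition <- function(reads) {
  first <- substr(reads$sequence, 1L, 1L)
  ok <- first %in% c("A", "C", "G", "T")
  tot <- sum(reads$count[ok])
  if (tot == 0) stop("no reads with an ACGT first base")
  frac <- vapply(c("A", "C", "G", "T"), function(b)
    sum(reads$count[ok & first == b]) / tot, numeric(1))
  list(composition = data.frame(base = c("A", "C", "G", "U"),
                                fraction = unname(frac),
                                stringsAsFactors = FALSE),
       excluded = sum(reads$count[!ok]))
}
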