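#' Hierarchical read annotation against ordered reference sets
#'
#' Each read is assigned to the highest-priority reference set in which it
#' has at least one alignment at the configured mismatch allowance
#' (sequential filtering: once assigned, a read is never tested against
#' lower-priority sets). Reads hitting none of the five sets are classified
#' as `other`. The canonical order is piRNA clusters, coding RNAs,
#' non-coding RNAs, repeats, intron.
#'
#' @param reads collapsed, length-filtered read data.frame.
#' @param ref_sets list of [reference_set()]s with priorities 1..5.
#' @param config an [align_config()]; the default allows one mismatch and
#'   reports any hit, on both strands.
#' @return list with `assignments` (data.frame: id, sequence, count,
#'   category) and `summary` (see [annotation_report()]).
#' @export
annotate_hierarchical <- function(reads, ref_sets,
                                  config = align_config(max_mismatch = 1L,
                                                        report = "any")) {
  ref_sets <- check_reference_order(ref_sets)
  reads <- drop_n_reads(reads)
  if (!"count" %in% names(reads)) reads$count <- 1
  category <- rep("other", nrow(reads))
  remaining <- rep(TRUE, nrow(reads))
  for (rs in ref_sets) {
    if (!any(remaining)) break
    hits <- align_reads(reads[remaining, , drop = FALSE], rs, config)
    if (nrow(hits)) {
      mapped <- reads$id[remaining] %in% hits$read_id
      category[remaining][mapped] <- rs$category
      remaining[remaining] <- !mapped
    }
  }
  assignments <- cbind(reads[, c("id", "sequence", "count")],
                       category = category, stringsAsFactors = FALSE)
  list(assignments = assignments, summary = annotation_report(assignments))
}

#' Count-weighted category summary of an annotation
#'
#' Percentages are count-weighted over all annotated reads (each raw read
#' counts once), matching per-read tallies on collapsed data.
#'
#' @param assignments data.frame with `count` and `category`.
#' @return data.frame: `category`, `reads` (count-weighted), `percent`, with
#'   the five reference categories first (in priority order) then `other`.
#' @export
annotation_report <- function(assignments) {
  stopifnot(nrow(assignments) > 0L)
  lev <- c(CATEGORIES, "other")
  reads <- vapply(lev, function(cat)
    sum(assignments$count[assignments$category == cat]), numeric(1))
  data.frame(category = lev, reads = unname(reads),
             percent = unname(100 * reads / sum(reads)),
             stringsAsFactors = FALSE)
}
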