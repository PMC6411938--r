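#' Configuration for the synthetic piRNA library simulator
#'
#' The simulator emulates matched immunoprecipitated piRNA libraries from a
#' wild-type animal (mature, 3'-trimmed piRNAs) and a trimming-deficient
#' mutant (3'-extended pre-piRNA intermediates sharing the wild-type 5'
#' ends), together with category-labeled decoy references and a ground-truth
#' table for every emitted read.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_clusters number of piRNA cluster reference sequences.
#' @param cluster_length length of each cluster (nt).
#' @param n_loci_per_cluster piRNA loci planted per cluster.
#' @param mature_length_dist named probability vector over mature lengths;
#'   names must lie in 24..31 nt.
#' @param extension_dist named probability vector over 3' extensions (+1..+18
#'   nt) applied in mutant mode; default is a geometric(p = 0.5) truncated at
#'   +18 and renormalized.
#' @param u_bias probability that a planted locus begins with U (T in DNA).
#' @param abundance_exponent Zipf exponent for locus read counts (one global
#'   rank list across clusters, so "top N by count" selection is meaningful).
#' @param n_reads total reads emitted per library.
#' @param mirna_fraction fraction of reads emitted as 21-23 nt miRNA
#'   spike-ins (the normalization proxy).
#' @param decoy_read_fraction fraction of reads drawn from the decoy
#'   categories (split equally across the four decoy sets), so that
#'   annotation fractions exercise every category.
#' @param adapter 3' sequencing adapter appended to every emitted read
#'   (read-through; clipped by the preprocess stage).
#' @param decoy_sets per-category list of `list(n, length)` for the
#'   coding_RNA, noncoding_RNA, repeats and intron decoy references.
#' @param n_mirna_refs number of distinct 21-23 nt spike-in sequences.
#' @param untrimmed_mode default library mode: FALSE emits mature reads (WT),
#'   TRUE emits 3'-extended intermediates (mutant). [simulate_library()]'s
#'   `mode` argument overrides this.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(seed = 1L,
                              n_clusters = 4L,
                              cluster_length = 20000L,
                              n_loci_per_cluster = 250L,
                              mature_length_dist = c(
                                "24" = 0.02, "25" = 0.08, "26" = 0.30,
                                "27" = 0.30, "28" = 0.15, "29" = 0.08,
                                "30" = 0.05, "31" = 0.02),
                              extension_dist = truncated_geometric(0.5, 18L),
                              u_bias = 0.9,
                              abundance_exponent = 1,
                              n_reads = 50000L,
                              mirna_fraction = 0.05,
                              decoy_read_fraction = 0.10,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              decoy_sets = list(
                                coding_RNA = list(n = 30L, length = 1500L),
                                noncoding_RNA = list(n = 30L, length = 300L),
                                repeats = list(n = 20L, length = 800L),
                                intron = list(n = 30L, length = 2000L)),
                              n_mirna_refs = 30L,
                              untrimmed_mode = FALSE) {
  cfg <- list(seed = as.integer(seed), n_clusters = as.integer(n_clusters),
              cluster_length = as.integer(cluster_length),
              n_loci_per_cluster = as.integer(n_loci_per_cluster),
              mature_length_dist = mature_length_dist,
              extension_dist = extension_dist,
              u_bias = u_bias, abundance_exponent = abundance_exponent,
              n_reads = as.integer(n_reads),
              mirna_fraction = mirna_fraction,
              decoy_read_fraction = decoy_read_fraction,
              adapter = toupper(adapter), decoy_sets = decoy_sets,
              n_mirna_refs = as.integer(n_mirna_refs),
              untrimmed_mode = isTRUE(untrimmed_mode))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Geometric distribution truncated to 1..kmax, renormalized
#' @param p geometric success probability.
#' @param kmax largest extension (nt).
#' @return named probability vector over `1:kmax`.
#' @export
truncated_geometric <- function(p, kmax = 18L) {
  k <- seq_len(kmax)
  w <- p * (1 - p)^(k - 1)
  setNames(w / sum(w), as.character(k))
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_clusters >= 1L, cfg$cluster_length >= 200L,
            cfg$n_loci_per_cluster >= 1L,
            cfg$u_bias >= 0, cfg$u_bias <= 1,
            cfg$mirna_fraction >= 0, cfg$mirna_fraction < 1,
            cfg$decoy_read_fraction >= 0,
            cfg$mirna_fraction + cfg$decoy_read_fraction < 1,
            cfg$n_reads >= 1L)
  for (nm in c("mature_length_dist", "extension_dist")) {
    d <- cfg[[nm]]
    if (abs(sum(d) - 1) > 1e-9) stop(nm, " must sum to 1 (got ", sum(d), ")")
    if (any(d < 0)) stop(nm, " has negative probabilities")
  }
  ml <- as.integer(names(cfg$mature_length_dist))
  if (any(is.na(ml)) || min(ml) < 24L || max(ml) > 31L) {
    stop("mature_length_dist lengths must lie in 24..31 nt")
  }
  ek <- as.integer(names(cfg$extension_dist))
  if (any(is.na(ek)) || min(ek) < 1L) {
    stop("extension_dist must be over positive extensions (+1 and up)")
  }
  if (max(ml) + max(ek) > 49L) {
    stop("mature length + max extension must be <= 49 nt so intermediates ",
         "stay within the 24-48 nt analysis window")
  }
  if (nchar(cfg$adapter) < 6L) stop("adapter must be at least 6 nt")
  stopifnot(setequal(names(cfg$decoy_sets),
                     c("coding_RNA", "noncoding_RNA", "repeats", "intron")))
  invisible(cfg)
}

## base composition used for all random reference sequence (40% GC)
BASE_PROBS <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)

random_dna <- function(n) {
  paste(sample(names(BASE_PROBS), n, replace = TRUE, prob = BASE_PROBS),
        collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

kmer_set <- function(seqs, k = 24L) {
  out <- character(0)
  for (s in c(seqs, revcomp(seqs))) {
    n <- nchar(s)
    if (n >= k) out <- c(out, substring(s, 1:(n - k + 1L), k:n))
  }
  unique(out)
}

#' Build piRNA cluster references, planted loci, and decoy reference sets
#'
#' Cluster sequences are random DNA carrying `n_loci_per_cluster` planted
#' piRNA loci in non-overlapping slots, on either strand with equal
#' probability, 5' base forced to T with probability `u_bias`. Decoy
#' references (coding RNA, non-coding RNA, repeats, intron) are
#' rejection-sampled so they share no 24-mer with the cluster sequences or
#' with each other; 21-23 nt miRNA spike-in sequences are appended to the
#' non-coding RNA set.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory; if given, one FASTA per category plus a
#'   locus table TSV are written there.
#' @return list with `ref_sets` (ordered [reference_set()] list), `loci`
#'   (data.frame: locus_id, cluster_id, strand, start, end, g5, g3,
#'   mature_len, rank, sequence), `mirna_ids`, and `config`.
#' @export
build_references <- function(config, dir = NULL) {
  validate_simulation_config(config)
  set.seed(config$seed)
  L <- config$cluster_length
  npc <- config$n_loci_per_cluster
  ext_max <- max(as.integer(names(config$extension_dist)))
  mat_lens <- as.integer(names(config$mature_length_dist))

  clusters <- character(config$n_clusters)
  loci <- vector("list", config$n_clusters)
  slot <- L %/% npc
  # one locus per slot, with a small positional jitter: keeps loci (and their
  # possible 3' extensions) inside their slot and guarantees that anchor
  # positions of neighboring loci are farther apart than the 30 nt
  # end-distance window, so profiles of a library against its own references
  # put all mass at offset 0
  jitter <- 10L
  if (slot < 2L * ext_max + jitter + max(mat_lens) + 1L ||
      slot - jitter - max(mat_lens) + 1L <= 30L) {
    stop("cluster_length too small for n_loci_per_cluster: loci need room ",
         "for 3' extensions and >30 nt spacing between neighboring anchors")
  }
  for (ci in seq_len(config$n_clusters)) {
    seq_chars <- strsplit(random_dna(L), "")[[1]]
    len <- mat_lens[sample.int(length(mat_lens), npc, replace = TRUE,
                               prob = config$mature_length_dist)]
    strand <- sample(c("+", "-"), npc, replace = TRUE)
    slot_start <- (seq_len(npc) - 1L) * slot                  # 0-based
    start <- slot_start + ext_max +
      as.integer(floor(runif(npc) * (jitter + 1L)))           # 0-based
    end <- start + len                                        # half-open
    g5 <- ifelse(strand == "+", start, end - 1L)
    g3 <- ifelse(strand == "+", end - 1L, start)
    first <- ifelse(runif(npc) < config$u_bias, "T",
                    sample(c("A", "C", "G"), npc, replace = TRUE))
    seq_chars[g5 + 1L] <- ifelse(strand == "+", first,
                                 chartr("ACGT", "TGCA", first))
    clusters[ci] <- paste(seq_chars, collapse = "")
    locus_seq <- substring(clusters[ci], start + 1L, end)
    locus_seq[strand == "-"] <- revcomp(locus_seq[strand == "-"])
    loci[[ci]] <- data.frame(
      locus_id = sprintf("cl%d_locus%03d", ci, seq_len(npc)),
      cluster_id = sprintf("cluster%d", ci),
      strand = strand, start = start, end = end, g5 = g5, g3 = g3,
      mature_len = len, sequence = locus_seq, stringsAsFactors = FALSE)
  }
  names(clusters) <- sprintf("cluster%d", seq_len(config$n_clusters))
  loci <- do.call(rbind, loci)
  # one global abundance rank list across all clusters
  loci$rank <- sample(nrow(loci))

  forbidden <- kmer_set(clusters)
  decoys <- list()
  for (cat in names(config$decoy_sets)) {
    spec_d <- config$decoy_sets[[cat]]
    seqs <- vapply(seq_len(spec_d$n), function(i) random_dna(spec_d$length),
                   character(1))
    # batch rejection: resample any decoy sharing a 24-mer with the clusters
    # or a previously accepted decoy category (keeps annotation priorities
    # unambiguous on simulated reads)
    for (try in 1:50) {
      # forbidden carries both strands, so forward k-mers suffice here
      km <- lapply(seqs, function(s)
        substring(s, 1:(nchar(s) - 23L), 24:nchar(s)))
      hit <- unlist(km) %in% forbidden
      bad <- vapply(split(hit, rep(seq_along(km), lengths(km))), any,
                    logical(1), USE.NAMES = FALSE)
      if (!any(bad)) break
      if (try == 50L) {
        stop("rejection sampling failed for decoy category ", cat,
             ": cannot avoid 24-mers shared with existing references")
      }
      seqs[bad] <- vapply(which(bad), function(i) random_dna(spec_d$length),
                          character(1))
    }
    names(seqs) <- sprintf("%s_%03d", cat, seq_len(spec_d$n))
    forbidden <- c(forbidden, kmer_set(seqs))
    decoys[[cat]] <- seqs
  }
  # miRNA spike-ins (< 24 nt, cannot collide on 24-mers); ride in the
  # non-coding RNA reference set
  mirna_len <- sample(21:23, config$n_mirna_refs, replace = TRUE)
  mirna <- setNames(vapply(mirna_len, random_dna, character(1)),
                    sprintf("mirna_%03d", seq_len(config$n_mirna_refs)))
  decoys$noncoding_RNA <- c(decoys$noncoding_RNA, mirna)

  ref_sets <- list(
    reference_set("piRNA_cluster", clusters, 1L),
    reference_set("coding_RNA", decoys$coding_RNA, 2L),
    reference_set("noncoding_RNA", decoys$noncoding_RNA, 3L),
    reference_set("repeats", decoys$repeats, 4L),
    reference_set("intron", decoys$intron, 5L))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (rs in ref_sets) {
      ss <- Biostrings::DNAStringSet(setNames(rs$sequences, rs$ids))
      Biostrings::writeXStringSet(ss, file.path(dir, paste0(rs$category, ".fa")))
    }
    write_tsv_report(loci, file.path(dir, "loci.tsv"))
  }
  list(ref_sets = ref_sets, loci = loci, mirna_ids = names(mirna),
       config = config)
}

#' Simulate a sequencing library with ground truth
#'
#' Wild-type mode emits mature-length locus reads; mutant mode emits
#' genome-templated 3'-extended intermediates (the mature locus sequence plus
#' downstream genomic bases drawn from `extension_dist`), sharing the mature
#' locus 5' end. Locus abundances follow a Zipf law over the global rank
#' list; miRNA spike-ins and decoy-category reads are mixed in at the
#' configured fractions. Every read carries the 3' adapter appended
#' (sequencing read-through) and exactly one row in the truth table.
#'
#' @param refs output of [build_references()].
#' @param mode `"WT"` or `"mutant"`; default follows `config$untrimmed_mode`.
#' @param dir optional directory; if given, `<mode>.fastq` and
#'   `<mode>_truth.tsv` are written there.
#' @return list with `reads` (data.frame: id, sequence — adapter included)
#'   and `truth` (data.frame: read_id, locus_id, cluster_id, strand, g5, g3,
#'   state, category), plus `mode`.
#' @export
simulate_library <- function(refs, mode = NULL, dir = NULL) {
  config <- refs$config
  if (is.null(mode)) mode <- if (config$untrimmed_mode) "mutant" else "WT"
  mode <- match.arg(mode, c("WT", "mutant"))
  set.seed(config$seed + if (mode == "WT") 1L else 2L)
  loci <- refs$loci
  clusters <- setNames(
    refs$ref_sets[[1L]]$sequences, refs$ref_sets[[1L]]$ids)

  n_mix <- drop(rmultinom(1, config$n_reads, c(
    pirna = 1 - config$mirna_fraction - config$decoy_read_fraction,
    mirna = config$mirna_fraction,
    decoy = config$decoy_read_fraction)))

  # piRNA reads: Zipf over global locus ranks
  w <- loci$rank^(-config$abundance_exponent)
  cnt <- drop(rmultinom(1, n_mix[["pirna"]], w / sum(w)))
  li <- rep(seq_len(nrow(loci)), cnt)
  ext <- if (mode == "mutant") {
    ks <- as.integer(names(config$extension_dist))
    ks[sample.int(length(ks), length(li), replace = TRUE,
                  prob = config$extension_dist)]
  } else rep(0L, length(li))
  st <- loci$strand[li]
  # genome-templated 3' extension: downstream in read orientation
  a_start <- ifelse(st == "+", loci$start[li], loci$start[li] - ext)
  a_end <- ifelse(st == "+", loci$end[li] + ext, loci$end[li])
  seqs <- substring(clusters[loci$cluster_id[li]], a_start + 1L, a_end)
  seqs[st == "-"] <- revcomp(seqs[st == "-"])
  g3 <- ifelse(st == "+", a_end - 1L, a_start)
  pirna <- data.frame(
    sequence = seqs, locus_id = loci$locus_id[li],
    cluster_id = loci$cluster_id[li], strand = st,
    g5 = loci$g5[li], g3 = g3,
    state = if (mode == "mutant") "extended" else "mature",
    category = "piRNA_cluster", stringsAsFactors = FALSE)

  # miRNA spike-ins: full-length reads of the spike-in references
  nc <- refs$ref_sets[[3L]]
  mirna_seq <- setNames(nc$sequences, nc$ids)[refs$mirna_ids]
  mi <- sample(seq_along(mirna_seq), n_mix[["mirna"]], replace = TRUE)
  mirna <- data.frame(
    sequence = unname(mirna_seq[mi]), locus_id = names(mirna_seq)[mi],
    cluster_id = names(mirna_seq)[mi], strand = "+",
    g5 = 0L, g3 = nchar(mirna_seq[mi]) - 1L,
    state = "mature", category = "miRNA_decoy", stringsAsFactors = FALSE)

  # decoy-category reads: random 24-40 nt substrings of decoy references
  decoy_cats <- c("coding_RNA", "noncoding_RNA", "repeats", "intron")
  per_cat <- drop(rmultinom(1, n_mix[["decoy"]], rep(0.25, 4)))
  decoy <- lapply(seq_along(decoy_cats), function(k) {
    cat <- decoy_cats[k]
    rs <- refs$ref_sets[[k + 1L]]
    ids <- rs$ids
    seqs_all <- setNames(rs$sequences, ids)
    if (cat == "noncoding_RNA") { # spike-ins are sampled separately above
      keep <- !(ids %in% refs$mirna_ids)
      ids <- ids[keep]; seqs_all <- seqs_all[keep]
    }
    n <- per_cat[k]
    ri <- sample(seq_along(ids), n, replace = TRUE)
    len <- sample(24:40, n, replace = TRUE)
    maxs <- nchar(seqs_all[ri]) - len
    start <- floor(runif(n) * (maxs + 1L))
    data.frame(
      sequence = substring(seqs_all[ri], start + 1L, start + len),
      locus_id = ids[ri], cluster_id = ids[ri], strand = "+",
      g5 = start, g3 = start + len - 1L,
      state = "mature", category = cat, stringsAsFactors = FALSE)
  })
  truth <- rbind(pirna, mirna, do.call(rbind, decoy))
  truth$read_id <- sprintf("r%07d", seq_len(nrow(truth)))
  truth <- truth[, c("read_id", "locus_id", "cluster_id", "strand",
                     "g5", "g3", "state", "category", "sequence")]
  reads <- data.frame(id = truth$read_id,
                      sequence = paste0(truth$sequence, config$adapter),
                      stringsAsFactors = FALSE)
  truth$sequence <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(reads, file.path(dir, paste0(mode, ".fastq")))
    write_tsv_report(truth, file.path(dir, paste0(mode, "_truth.tsv")))
  }
  list(reads = reads, truth = truth, mode = mode)
}
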