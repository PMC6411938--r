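# helpers to build constructed reference/query scenarios on a synthetic cluster
make_cluster <- function(len = 3000, seed = 71) {
  reference_set("piRNA_cluster", c(clusterX = random_dna(len, seed = seed)), 1L)
}

reads_df <- function(seqs, counts = 1L) {
  data.frame(id = sprintf("q%03d", seq_along(seqs)), sequence = seqs,
             count = rep_len(counts, length(seqs)), stringsAsFactors = FALSE)
}

test_that("reference selection keeps top-N unique mappers with deterministic ties", {
  set.seed(72)
  clus_seq <- random_dna(3000)
  dup <- substr(clus_seq, 101, 128)
  # plant a duplication so `dup` maps twice
  ref <- reference_set("piRNA_cluster",
                       c(clusterX = paste0(clus_seq, dup, random_dna(50))), 1L)
  starts <- seq(301, by = 60, length.out = 12)
  uniq <- substring(clus_seq, starts, starts + 27)
  reads <- reads_df(c(uniq, dup), counts = c(12:1, 100L))
  sel <- select_reference_pirnas(reads, ref, n = 10L)
  # the duplicated (multi-mapping) sequence is excluded despite top count
  expect_false(dup %in% sel$sequence)
  expect_equal(nrow(sel), 10L)
  expect_equal(sel$count, 12:3)
  expect_equal(sel$rank, 1:10)
  # fewer qualifying than requested: all returned with a warning
  expect_warning(sel_all <- select_reference_pirnas(reads, ref, n = 50L),
                 "only 12")
  expect_equal(nrow(sel_all), 12L)
})

test_that("reference selection matches the simulator abundance truth", {
  refs <- small_refs()
  bundle <- small_wt_bundle()
  sel <- suppressWarnings(
    select_reference_pirnas(bundle$reads, refs$ref_sets[[1L]], n = 10L))
  # oracle: count-weighted truth tally per locus, top 10 by count then sequence
  lib <- fixture("small_wt_lib", simulate_library(refs, mode = "WT"))
  tally <- table(lib$truth$locus_id[lib$truth$category == "piRNA_cluster"])
  loci <- refs$loci
  truth <- data.frame(sequence = loci$sequence,
                      count = as.integer(tally[loci$locus_id]))
  truth <- truth[!is.na(truth$count), ]
  truth <- truth[order(-truth$count, truth$sequence), ][1:10, ]
  expect_setequal(sel$sequence, truth$sequence)
  expect_equal(sort(sel$count), sort(truth$count))
})

test_that("a library profiled against itself peaks entirely at offset 0", {
  set.seed(73)
  ref <- make_cluster()
  starts <- seq(101, by = 80, length.out = 20)
  seqs <- substring(ref$sequences, starts, starts + sample(24:30, 20, TRUE))
  seqs[seq(2, 20, 2)] <- revcomp_chr(seqs[seq(2, 20, 2)])
  reads <- reads_df(seqs, counts = sample(1:30, 20, TRUE))
  sel <- suppressWarnings(select_reference_pirnas(reads, ref, n = 20L))
  aln <- align_reads(reads, ref, align_config(0L, report = "all"))
  for (end in c("5p", "3p")) {
    prof <- distance_profile(sel, aln, end = end)
    expect_equal(prof$profile$frequency[prof$profile$offset == 0], 1.0,
                 label = end)
    expect_equal(prof$total, sum(reads$count), label = end)
  }
})

test_that("a constructed +2 nt 3' extension shifts only the 3p profile", {
  set.seed(74)
  ref <- make_cluster(seed = 74)
  starts <- seq(201, by = 90, length.out = 15)
  mature <- substring(ref$sequences, starts, starts + 27)
  minus <- seq(2, 15, 3)
  queries <- substring(ref$sequences, starts, starts + 29) # +2 downstream (+)
  mature[minus] <- revcomp_chr(substring(ref$sequences, starts[minus] + 2,
                                         starts[minus] + 29))
  queries[minus] <- revcomp_chr(substring(ref$sequences, starts[minus],
                                          starts[minus] + 29))
  refs_reads <- reads_df(mature)
  sel <- suppressWarnings(select_reference_pirnas(refs_reads, ref, n = 15L))
  qaln <- align_reads(reads_df(queries), ref, align_config(0L, report = "all"))
  p5 <- distance_profile(sel, qaln, end = "5p")
  p3 <- distance_profile(sel, qaln, end = "3p")
  expect_equal(p5$profile$frequency[p5$profile$offset == 0], 1.0)
  expect_equal(p3$profile$frequency[p3$profile$offset == 2], 1.0)
})

test_that("3p profile is translation-equivariant in the extension length", {
  set.seed(75)
  ref <- make_cluster(seed = 75)
  starts <- seq(151, by = 100, length.out = 10)
  mature <- substring(ref$sequences, starts, starts + 26)
  sel <- suppressWarnings(
    select_reference_pirnas(reads_df(mature), ref, n = 10L))
  freq_at <- function(k) {
    q <- substring(ref$sequences, starts, starts + 26 + k)
    aln <- align_reads(reads_df(q), ref, align_config(0L, report = "all"))
    distance_profile(sel, aln, end = "3p")$profile
  }
  for (k in c(1L, 5L, 12L)) {
    pk <- freq_at(k)
    expect_equal(pk$frequency[pk$offset == k], 1.0, label = paste("k =", k))
  }
})

test_that("minus-strand extensions report positive (downstream) offsets", {
  set.seed(76)
  ref <- make_cluster(seed = 76)
  start <- 501 # 1-based; mature locus on minus strand, [500, 528) 0-based
  mature <- revcomp_chr(substr(ref$sequences, start, start + 27))
  # 3' extension of a minus-strand read walks genomically leftward
  extended <- revcomp_chr(substr(ref$sequences, start - 4, start + 27))
  sel <- suppressWarnings(select_reference_pirnas(reads_df(mature), ref, n = 1L))
  expect_equal(sel$strand, "-")
  qaln <- align_reads(reads_df(extended), ref, align_config(0L, report = "all"))
  p3 <- distance_profile(sel, qaln, end = "3p")
  expect_equal(p3$profile$frequency[p3$profile$offset == 4], 1.0)
  p5 <- distance_profile(sel, qaln, end = "5p")
  expect_equal(p5$profile$frequency[p5$profile$offset == 0], 1.0)
})

test_that("profile frequencies are a distribution and fractional weighting sums to it", {
  bundle <- small_mut_bundle()
  sel <- suppressWarnings(select_reference_pirnas(
    small_wt_bundle()$reads, small_refs()$ref_sets[[1L]], n = 1000L))
  for (mmode in c("full", "fractional")) {
    prof <- distance_profile(sel, bundle$cluster_aln, end = "3p",
                             multimapper = mmode)
    expect_true(all(prof$profile$frequency >= 0))
    expect_lt(abs(sum(prof$profile$frequency) - 1), 1e-9)
  }
})

test_that("empty references or zero in-window events are handled explicitly", {
  set.seed(77)
  ref <- make_cluster(seed = 77)
  reads <- reads_df(substr(ref$sequences, 101, 128))
  aln <- align_reads(reads, ref, align_config(0L, report = "all"))
  expect_error(distance_profile(data.frame(), aln), "empty reference")
  far <- suppressWarnings(select_reference_pirnas(
    reads_df(substr(ref$sequences, 1001, 1028)), ref, n = 1L))
  expect_warning(prof <- distance_profile(far, aln[0, ], end = "5p"),
                 "no query alignments")
  expect_equal(prof$total, 0)
  expect_true(all(prof$profile$frequency == 0))
})

test_that("cluster pileup partitions by region and length class and counts shared 5' ends", {
  set.seed(78)
  ref <- make_cluster(seed = 78)
  # track A: 30 nt mature at 100 (plus) and 200 (minus); track B: 31+ nt at
  # the same 5' ends; one 31 nt read outside the region
  a_seqs <- c(substr(ref$sequences, 101, 130),
              revcomp_chr(substr(ref$sequences, 201, 230)))
  b_seqs <- c(substr(ref$sequences, 101, 135),
              revcomp_chr(substr(ref$sequences, 196, 230)),
              substr(ref$sequences, 901, 931))
  aln_a <- align_reads(reads_df(a_seqs), ref, align_config(0L, report = "all"))
  aln_b <- align_reads(reads_df(b_seqs), ref, align_config(0L, report = "all"))
  pu <- cluster_pileup(aln_a, aln_b, "clusterX", region = c(0L, 500L))
  expect_equal(nrow(pu$track_a), 2L) # 30 nt reads fall in class A
  expect_equal(nrow(pu$track_b), 2L) # in-region 31+ reads in class B
  expect_equal(pu$n_shared5, 2L)
  expect_equal(sort(pu$shared5$g5), c(100L, 229L))
  # length-class boundary: a 30 nt read never enters track B
  expect_true(all(pu$track_b$end - pu$track_b$start >= 31L))
  expect_error(cluster_pileup(aln_a, aln_b, "nope", c(0L, 500L),
                              known_clusters = "clusterX"), "unknown cluster")
})

test_that("pileup shared-5' count matches the truth table on simulated data", {
  refs <- small_refs()
  wt <- small_wt_bundle()
  mut <- small_mut_bundle()
  cl <- refs$ref_sets[[1L]]$ids[1L]
  region <- c(0L, 4000L)
  pu <- cluster_pileup(wt$cluster_aln, mut$cluster_aln, cl, region)
  # truth: loci of this cluster whose mature length <= 30 and with an
  # extended mutant read of length >= 31 sharing the locus 5' end
  mut_truth <- mut$truth[mut$truth$category == "piRNA_cluster" &
                           mut$truth$cluster_id == cl, ]
  loci <- refs$loci[match(mut_truth$locus_id, refs$loci$locus_id), ]
  ext_len <- abs(mut_truth$g3 - mut_truth$g5) + 1L
  has_b <- tapply(ext_len >= 31L, mut_truth$locus_id, any)
  wt_truth <- wt$truth[wt$truth$category == "piRNA_cluster" &
                         wt$truth$cluster_id == cl, ]
  wt_len <- abs(wt_truth$g3 - wt_truth$g5) + 1L
  has_a <- tapply(wt_len <= 30L & wt_len >= 24L, wt_truth$locus_id, any)
  shared_loci <- intersect(names(has_b)[has_b], names(has_a)[has_a])
  expect_equal(pu$n_shared5, length(shared_loci))
})
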