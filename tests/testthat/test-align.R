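make_ref <- function(seq, id = "chr", category = "piRNA_cluster") {
  reference_set(category, setNames(seq, id), 1L)
}

test_that("exact substrings and single substitutions align as expected", {
  set.seed(41)
  ref_seq <- random_dna(500)
  ref <- make_ref(ref_seq)
  read <- substr(ref_seq, 11, 40) # 0-based [10, 40)
  reads <- data.frame(id = "q1", sequence = read, count = 1L,
                      stringsAsFactors = FALSE)
  hit <- align_reads(reads, ref, align_config(0L))
  expect_equal(hit$start, 10L)
  expect_equal(hit$end, 40L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$mismatches, 0L)

  mutated <- read
  substr(mutated, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                     substr(read, 15, 15))[1]
  reads$sequence <- mutated
  expect_equal(nrow(align_reads(reads, ref, align_config(0L))), 0L)
  hit1 <- align_reads(reads, ref, align_config(1L))
  expect_equal(hit1$mismatches, 1L)
  expect_equal(hit1$start, 10L)
})

test_that("minus-strand hits satisfy the reverse-complement contract", {
  set.seed(42)
  ref_seq <- random_dna(400)
  ref <- make_ref(ref_seq)
  fwd <- substr(ref_seq, 101, 130)
  reads <- data.frame(id = "q1", sequence = revcomp_chr(fwd), count = 1L,
                      stringsAsFactors = FALSE)
  hit <- align_reads(reads, ref, align_config(0L))
  expect_equal(hit$strand, "-")
  expect_equal(hit$start, 100L)
  expect_equal(hit$end, 130L)
  expect_identical(revcomp_chr(reads$sequence),
                   substr(ref_seq, hit$start + 1L, hit$end))
})

test_that("aligning the reverse complement flips strand and keeps coordinates", {
  set.seed(43)
  ref <- make_ref(random_dna(2000))
  starts <- sample(0:1960, 30)
  seqs <- substring(ref$sequences, starts + 1L, starts + 30L)
  reads <- data.frame(id = sprintf("q%d", 1:30), sequence = seqs,
                      count = 1L, stringsAsFactors = FALSE)
  rc <- reads
  rc$sequence <- revcomp_chr(reads$sequence)
  a <- align_reads(reads, ref, align_config(0L))
  b <- align_reads(rc, ref, align_config(0L))
  key <- function(x) x[order(x$read_id), c("read_id", "start", "end")]
  expect_equal(key(a), key(b))
  flip <- setNames(b$strand, b$read_id)[a$read_id]
  expect_true(all(ifelse(a$strand == "+", "-", "+") == flip))
})

test_that("seeded aligner equals the brute-force oracle on random instances", {
  set.seed(44)
  ref <- reference_set("piRNA_cluster",
                       c(r1 = random_dna(6000), r2 = random_dna(4000)), 1L)
  planted <- vapply(1:120, function(i) {
    src <- sample(ref$sequences, 1)
    st <- sample(nchar(src) - 48, 1)
    x <- substr(src, st, st + sample(24:48, 1) - 1)
    if (runif(1) < 0.5) x <- revcomp_chr(x)
    if (runif(1) < 0.5) {
      p <- sample(nchar(x), 1)
      substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    x
  }, character(1))
  noise <- vapply(1:60, function(i) random_dna(sample(24:48, 1)), character(1))
  reads <- collapse_reads(c(planted, noise))
  for (mm in 0:1) {
    for (str in c("both", "plus_only")) {
      cfg <- align_config(mm, str, "all")
      expect_identical(align_reads(reads, ref, cfg),
                       brute_force_align(reads, ref, cfg),
                       label = sprintf("mm=%d strands=%s", mm, str))
    }
  }
})

test_that("hit set at max_mismatch 0 is a subset of the set at 1", {
  set.seed(45)
  ref <- make_ref(random_dna(3000))
  reads <- collapse_reads(vapply(1:80, function(i) {
    st <- sample(2970, 1)
    x <- substr(ref$sequences, st, st + 27)
    if (runif(1) < 0.7) {
      p <- sample(28, 1)
      substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    x
  }, character(1)))
  k <- function(a) paste(a$read_id, a$ref_id, a$start, a$strand)
  h0 <- align_reads(reads, ref, align_config(0L))
  h1 <- align_reads(reads, ref, align_config(1L))
  expect_true(all(k(h0) %in% k(h1)))
})

test_that("report = any yields exactly one deterministic hit per mapped read", {
  set.seed(46)
  base <- random_dna(100)
  # duplicated segment: every read maps twice
  ref <- make_ref(paste0(base, random_dna(50), base))
  reads <- data.frame(id = c("q1", "q2"),
                      sequence = c(substr(base, 10, 40), random_dna(30)),
                      count = 1L, stringsAsFactors = FALSE)
  all_hits <- align_reads(reads, ref, align_config(0L, report = "all"))
  expect_equal(nrow(all_hits), 2L)
  any_hits <- align_reads(reads, ref, align_config(0L, report = "any"))
  expect_equal(nrow(any_hits), 1L)
  expect_equal(any_hits$start, min(all_hits$start))
})

test_that("Biostrings matchPattern agrees with the aligner on plus-strand hits", {
  set.seed(47)
  ref_seq <- random_dna(2500)
  ref <- make_ref(ref_seq)
  reads <- collapse_reads(vapply(1:25, function(i) {
    st <- sample(2470, 1)
    substr(ref_seq, st, st + 25)
  }, character(1)))
  mine <- align_reads(reads, ref, align_config(0L, strands = "plus_only"))
  bios <- do.call(rbind, lapply(seq_len(nrow(reads)), function(i) {
    m <- Biostrings::matchPattern(reads$sequence[i],
                                  Biostrings::DNAString(ref_seq))
    if (length(m) == 0) return(NULL)
    data.frame(read_id = reads$id[i], start = BiocGenerics::start(m) - 1L)
  }))
  key <- function(x) sort(paste(x$read_id, x$start))
  expect_equal(key(mine), key(bios))
})

test_that("N-containing reads are dropped and absent reads give zero hits", {
  set.seed(48)
  ref <- make_ref(random_dna(300))
  reads <- data.frame(id = c("qn", "qa"),
                      sequence = c(paste0("NN", substr(ref$sequences, 1, 26)),
                                   random_dna(28)),
                      count = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(suppressMessages(align_reads(reads, ref, align_config(1L)))), 0L)
  # read longer than the reference: zero hits, not an error
  long <- data.frame(id = "q", sequence = random_dna(400), count = 1L)
  expect_equal(nrow(align_reads(long, ref, align_config(0L))), 0L)
})
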