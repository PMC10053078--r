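toy_locus <- locus(toy_chrom, 1L, toy_len, "+", "toy1")

test_that("skip gaps map to 1-based intron-anchored junction coordinates", {
  sam <- write_test_sam(data.frame(
    qname = c("r1", "r2"), flag = qualifying_flag,
    pos = c(101L, 501L), cigar = c("50M200N50M", "30M100N30M100N30M"),
    xs = "+", stringsAsFactors = FALSE))
  gal <- extract_spliced_alignments(sam, toy_locus)
  j <- junctions_from_alignments(gal)
  r1 <- j[j$read == which(BiocGenerics::start(gal) == 101L), ]
  expect_equal(r1$donor, 151L)
  expect_equal(r1$acceptor, 350L)
  r2 <- j[j$read == which(BiocGenerics::start(gal) == 501L), ]
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$donor, c(531L, 661L))
  expect_equal(r2$acceptor, c(630L, 760L))
  expect_true(all(j$donor < j$acceptor))
})

test_that("policy flags and the spliced requirement exclude records", {
  # 50 spliced in-locus records: 10 secondary, 5 duplicates, 35 qualifying
  flags <- c(rep(qualifying_flag + 256L, 10),
             rep(qualifying_flag + 1024L, 5),
             rep(qualifying_flag, 35))
  rec <- data.frame(qname = sprintf("r%02d", 1:50), flag = flags,
                    pos = 1000L + 10L * (1:50), cigar = "50M100N50M",
                    xs = "+", stringsAsFactors = FALSE)
  sam <- write_test_sam(rec)
  expect_length(extract_spliced_alignments(sam, toy_locus), 35L)

  # a duplicate-flagged spliced in-locus record on its own is excluded
  sam_dup <- write_test_sam(data.frame(
    qname = "d1", flag = qualifying_flag + 1024L, pos = 1000L,
    cigar = "50M100N50M", xs = "+", stringsAsFactors = FALSE))
  expect_length(extract_spliced_alignments(sam_dup, toy_locus), 0L)

  # an unspliced primary record in-locus is excluded
  sam_uns <- write_test_sam(data.frame(
    qname = "u1", flag = qualifying_flag, pos = 1000L, cigar = "100M",
    xs = NA, stringsAsFactors = FALSE))
  expect_length(extract_spliced_alignments(sam_uns, toy_locus), 0L)
})

test_that("strand handling: mismatches excluded, missing XS skipped and tallied", {
  rec <- data.frame(qname = c("p1", "m1", "n1"), flag = qualifying_flag,
                    pos = c(1000L, 1100L, 1200L), cigar = "50M100N50M",
                    xs = c("+", "-", NA), stringsAsFactors = FALSE)
  sam <- write_test_sam(rec)
  gal <- extract_spliced_alignments(sam, toy_locus)
  expect_length(gal, 1L)
  expect_equal(S4Vectors::mcols(gal)$XS, "+")
  expect_equal(S4Vectors::metadata(gal)$n_strand_unresolved, 1L)

  # with strand matching off all three spliced records come back
  gal2 <- extract_spliced_alignments(
    sam, toy_locus, alignment_filter_policy(require_strand_match = FALSE))
  expect_length(gal2, 3L)
  expect_equal(S4Vectors::metadata(gal2)$n_strand_unresolved, 0L)
})

test_that("enabling any additional policy flag never increases records", {
  set.seed(71)
  n <- 80
  flags <- qualifying_flag +
    sample(c(0L, 256L, 1024L), n, replace = TRUE, prob = c(.6, .2, .2)) -
    sample(c(0L, 2L), n, replace = TRUE) # some not properly paired
  rec <- data.frame(qname = sprintf("r%02d", 1:n), flag = flags,
                    pos = 1000L + 5L * (1:n), cigar = "40M80N40M",
                    xs = sample(c("+", "-", NA), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  sam <- write_test_sam(rec)
  base <- alignment_filter_policy(FALSE, FALSE, FALSE, FALSE)
  n_base <- length(extract_spliced_alignments(sam, toy_locus, base))
  for (fl in c("require_primary", "require_properly_paired",
               "exclude_duplicates", "require_strand_match")) {
    pol <- base
    pol[[fl]] <- TRUE
    n_fl <- length(extract_spliced_alignments(sam, toy_locus, pol))
    expect_lte(n_fl, n_base)
  }
  # all flags on is at most any single flag
  n_all <- length(extract_spliced_alignments(sam, toy_locus,
                                             alignment_filter_policy()))
  expect_lte(n_all, n_base)
})

test_that("count matrix equals a naive re-scan of the SAM text", {
  set.seed(42)
  mk_sample <- function(id) {
    n <- sample(20:60, 1)
    donors <- sample(c(1201L, 1901L, 2601L), n, replace = TRUE)
    gaps <- ifelse(donors == 1201L, 500L, 200L)
    rec <- data.frame(
      qname = sprintf("%s_r%03d", id, seq_len(n)),
      flag = qualifying_flag +
        sample(c(0L, 256L, 1024L), n, replace = TRUE, prob = c(.8, .1, .1)),
      pos = donors - 50L,
      cigar = sprintf("50M%dN50M", gaps),
      xs = sample(c("+", "-", NA), n, replace = TRUE, prob = c(.8, .1, .1)),
      stringsAsFactors = FALSE)
    write_test_sam(rec)
  }
  files <- c(A = mk_sample("A"), B = mk_sample("B"), C = mk_sample("C"))
  counts <- extract_cohort_junctions(files, toy_locus)
  for (s in names(files)) {
    oracle <- sam_junction_tally_oracle(files[[s]])
    got <- unclass(counts)[, s]
    got <- got[got > 0]
    expect_mapequal(as.list(got), as.list(oracle))
  }
  # conservation: totals bounded by reads x max junctions per read (1 here)
  expect_true(all(colSums(unclass(counts)) <=
                    vapply(files, function(f)
                      sum(!startsWith(readLines(f), "@")), 1)))
})

test_that("multi-junction reads increment every spanned junction", {
  sam <- write_test_sam(data.frame(
    qname = c("a", "b", "c"), flag = qualifying_flag,
    pos = c(101L, 101L, 101L),
    cigar = c("50M100N50M", "50M100N50M", "50M100N50M100N50M"),
    xs = "+", stringsAsFactors = FALSE))
  counts <- count_junctions(
    list(S1 = extract_spliced_alignments(sam, toy_locus)))
  m <- unclass(counts)
  expect_equal(m["chrT:151-250:+", "S1"], 3L)   # shared first junction
  expect_equal(m["chrT:301-400:+", "S1"], 1L)   # second gap of read c
})

test_that("simulated junctions re-extract bit-identically to the model", {
  cfg <- simulation_config(n_samples = 3, depth = 60,
                           noise_junction_rate = 0, unspliced_rate = 0,
                           seed = 9L)
  sim <- simulate_cohort(cfg, dir = tempfile("rt"))
  counts <- extract_cohort_junctions(sim$files, sim$locus)
  model_keys <- c(
    sprintf("chrT:%d-%d:+", sim$model$canonical_junctions$donor,
            sim$model$canonical_junctions$acceptor),
    sprintf("chrT:%d-%d:+", sim$model$variant_junctions$donor,
            sim$model$variant_junctions$acceptor))
  expect_true(all(rownames(counts) %in% model_keys))
  # reference junction support matches truth exactly
  ref <- unclass(counts)["chrT:1201-1700:+", ]
  tr <- sim$truth$samples
  tr_ref <- tr$n_reference_reads[!duplicated(tr$sample)]
  names(tr_ref) <- tr$sample[!duplicated(tr$sample)]
  expect_equal(ref[names(tr_ref)], tr_ref)
})
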