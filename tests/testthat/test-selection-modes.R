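test_that("input already under the cap passes through record-identical", {
  ref <- simulate_reference(5000, seed = 2)
  bam <- simulate_alignments(ref, tempfile(fileext = ".bam"),
                             mode = "long_single_end", target_depth = 5,
                             read_length_mean = 500, seed = 3)
  out <- tempfile(fileext = ".bam")
  suppressMessages(downsample_single_end(bam, out, coverage_cap = 50,
                                         seed = 1))
  a <- read_alignment_records(bam)
  b <- read_alignment_records(out)
  expect_identical(a[c("qname", "flag", "start", "end")],
                   b[c("qname", "flag", "start", "end")])
})

test_that("identical full-overlap reads are cut down to exactly N records", {
  sam <- identical_reads_sam(10, span = 100)
  out <- tempfile(fileext = ".sam")
  suppressMessages(downsample_single_end(sam, out, coverage_cap = 4,
                                         seed = 2109))
  got <- read_alignment_records(out)
  expect_equal(nrow(got), 4)
  # identities match the sweep's own selection for this seed
  df <- read_alignment_records(sam)
  res <- sweep_intervals(df[df$participates, ], 4, seed = 2109)
  expect_setequal(got$qname, df$qname[df$participates][res$kept])
})

test_that("header-only input yields a valid empty output with a header", {
  sam <- tempfile(fileext = ".sam")
  write_sam(data.frame(qname = character(0), flag = integer(0),
                       rname = character(0), pos = integer(0),
                       cigar = character(0)),
            c(ref1 = 1000L), sam)
  out <- tempfile(fileext = ".sam")
  suppressMessages(downsample_alignments(sam, out, coverage_cap = 5,
                                         seed = 1))
  df <- read_alignment_records(out)
  expect_equal(nrow(df), 0)
  expect_equal(attr(df, "ref_lengths"), c(ref1 = 1000L))
})

test_that("single-end output never exceeds the cap and stays sorted", {
  ref <- simulate_reference(20000, seed = 11)
  bam <- simulate_alignments(ref, tempfile(fileext = ".bam"),
                             mode = "long_single_end", target_depth = 80,
                             read_length_mean = 1500, seed = 12)
  out <- tempfile(fileext = ".bam")
  suppressMessages(downsample_alignments(bam, out, coverage_cap = 25,
                                         seed = 2109))
  expect_lte(unname(max_depth(compute_depth(out))), 25)
  expect_silent(invisible(read_alignment_records(out)))  # sortedness check
})

test_that("both mates of a selected template are written, even unmapped", {
  # one pair, mate unmapped, placed at its mate's position
  sam <- tempfile(fileext = ".sam")
  write_sam(data.frame(
    qname = "t1", flag = c(73L, 133L), rname = "ref1", pos = 11L,
    cigar = c("50M", "*"), mapq = c(60L, 0L), rnext = "=",
    pnext = 11L, tlen = 0L), c(ref1 = 1000L), sam)
  out <- tempfile(fileext = ".sam")
  suppressMessages(downsample_paired(sam, out, coverage_cap = 5, seed = 1))
  got <- read_alignment_records(out)
  expect_equal(nrow(got), 2)
  expect_setequal(got$category, c("primary_mapped", "unmapped"))
})

test_that("fully-overlapping pairs select N templates and write all mates", {
  recs <- do.call(rbind, lapply(1:10, function(i) data.frame(
    qname = sprintf("t%02d", i), flag = c(99L, 147L), rname = "ref1",
    pos = c(1L, 201L), cigar = "100M", rnext = "=", pnext = c(201L, 1L),
    tlen = c(300L, -300L))))
  sam <- tempfile(fileext = ".sam")
  write_sam(recs, c(ref1 = 1000L), sam)
  out <- tempfile(fileext = ".sam")
  run <- suppressMessages(
    downsample_paired(sam, out, coverage_cap = 4, seed = 2109))
  got <- read_alignment_records(out)
  expect_equal(length(unique(got$qname)), 4)
  expect_equal(nrow(got), 8)
  expect_equal(run$selected_templates, 4)
})

test_that("forced second mates can push depth transiently above the cap", {
  # R1s of t1..t3 overlap at the left locus; their R2s overlap t4/t5's R1s
  # at the right locus, where forced keeps overshoot N=2
  mk <- function(q, p1, p2) data.frame(
    qname = q, flag = c(99L, 147L), rname = "ref1", pos = c(p1, p2),
    cigar = "50M", rnext = "=", pnext = c(p2, p1),
    tlen = c(p2 - p1 + 50L, -(p2 - p1 + 50L)))
  recs <- rbind(mk("t1", 1L, 301L), mk("t2", 3L, 303L), mk("t3", 5L, 305L),
                mk("t4", 299L, 601L), mk("t5", 300L, 603L))
  sam <- tempfile(fileext = ".sam")
  write_sam(recs, c(ref1 = 1000L), sam)
  out <- tempfile(fileext = ".sam")
  run <- suppressMessages(
    downsample_paired(sam, out, coverage_cap = 2, seed = 2109))
  expect_gt(run$counts[["forced_mate_keeps"]], 0)
  expect_gt(unname(max_depth(compute_depth(out))), 2)
})

test_that("paired downsampling preserves template integrity", {
  ref <- simulate_reference(20000, seed = 21)
  bam <- simulate_alignments(ref, tempfile(fileext = ".bam"),
                             mode = "paired_end", target_depth = 40,
                             unmapped_mate_rate = 0.05, seed = 22)
  out <- tempfile(fileext = ".bam")
  suppressMessages(downsample_alignments(bam, out, coverage_cap = 15,
                                         seed = 2109))
  cin <- name_counts(bam)
  cout <- name_counts(out)
  # every selected template keeps all of its input records; no orphans
  expect_true(all(cout == cin[names(cout)]))
  expect_true(all(cout == 2))
  expect_silent(invisible(read_alignment_records(out)))
})

test_that("selection is deterministic in (input, seed) and seed-sensitive", {
  sam <- identical_reads_sam(20, span = 100)
  out1 <- tempfile(fileext = ".sam")
  out2 <- tempfile(fileext = ".sam")
  suppressMessages(downsample_alignments(sam, out1, 5, seed = 2109))
  suppressMessages(downsample_alignments(sam, out2, 5, seed = 2109))
  expect_identical(read_alignment_records(out1)$qname,
                   read_alignment_records(out2)$qname)
  out3 <- tempfile(fileext = ".sam")
  suppressMessages(downsample_alignments(sam, out3, 5, seed = 2110))
  expect_false(setequal(read_alignment_records(out1)$qname,
                        read_alignment_records(out3)$qname))
})

test_that("mode is auto-detected from the paired FLAG", {
  ref <- simulate_reference(5000, seed = 31)
  pe <- simulate_alignments(ref, tempfile(fileext = ".bam"),
                            mode = "paired_end", target_depth = 10,
                            seed = 32)
  run <- suppressMessages(
    downsample_alignments(pe, tempfile(fileext = ".bam"), 50, seed = 1))
  expect_equal(run$mode, "paired")
  se <- simulate_alignments(ref, tempfile(fileext = ".bam"),
                            mode = "long_single_end", target_depth = 10,
                            read_length_mean = 500, seed = 33)
  run2 <- suppressMessages(
    downsample_alignments(se, tempfile(fileext = ".bam"), 50, seed = 1))
  expect_equal(run2$mode, "single")
})
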