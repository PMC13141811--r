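# Fixture builders. Everything is generated in code at test time.

# M identical full-overlap reads [0, span) on one reference.
identical_reads_sam <- function(m, span = 100L, ref_len = 1000L,
                                path = tempfile(fileext = ".sam")) {
  write_sam(
    data.frame(qname = sprintf("r%03d", seq_len(m)), flag = 0L,
               rname = "ref1", pos = 1L, cigar = sprintf("%dM", span)),
    c(ref1 = as.integer(ref_len)), path)
}

# As above but sorted+indexed BAM (for the fetch strategy).
identical_reads_bam <- function(m, span = 100L, ref_len = 1000L,
                                stem = tempfile()) {
  sam <- identical_reads_sam(m, span, ref_len)
  Rsamtools::asBam(sam, destination = stem, overwrite = TRUE,
                   indexDestination = TRUE)
}

# Random single-end interval instance as a sorted data.frame the sweep
# accepts directly (ref_index/start/end/qname/ordinal).
random_instance <- function(n_max = 50, ref_len = 500, n_refs = 1) {
  n <- sample.int(n_max, 1)
  start <- sample.int(ref_len, n, replace = TRUE) - 1L
  len <- sample.int(60, n, replace = TRUE)
  df <- data.frame(
    ref_index = sample.int(n_refs, n, replace = TRUE),
    start = start,
    end = pmin(start + len, ref_len),
    qname = sprintf("q%04d", seq_len(n)))
  df <- df[df$end > df$start, , drop = FALSE]
  df <- df[order(df$ref_index, df$start), , drop = FALSE]
  df$ordinal <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

# Write an interval data.frame as an indexed BAM.
intervals_to_bam <- function(df, ref_len = 500L, stem = tempfile()) {
  recs <- data.frame(qname = df$qname, flag = 0L,
                     rname = paste0("ref", df$ref_index),
                     pos = df$start + 1L,
                     cigar = sprintf("%dM", df$end - df$start))
  refs <- stats::setNames(rep(as.integer(ref_len), max(df$ref_index)),
                          paste0("ref", seq_len(max(df$ref_index))))
  sam <- tempfile(fileext = ".sam")
  write_sam(recs, refs, sam)
  Rsamtools::asBam(sam, destination = stem, overwrite = TRUE,
                   indexDestination = TRUE)
}

# qname -> record count of a SAM/BAM file (all records).
name_counts <- function(file) {
  df <- read_alignment_records(file)
  table(df$qname)
}
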