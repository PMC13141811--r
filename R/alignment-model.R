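#' Reference span of a CIGAR string
#'
#' Number of reference bases consumed by an alignment: the summed lengths of
#' the M, D, N, `=` and X operations. Insertions, soft/hard clips and padding
#' consume no reference. A read's half-open reference interval is
#' `[start, start + reference_span(cigar))`.
#'
#' @param cigar character vector of SAM CIGAR strings.
#' @return integer vector of reference-consumed widths (0 if no
#'   reference-consuming operation).
#' @examples
#' reference_span(c("100M", "50M10I40M", "50M10D40M"))
#' @export
reference_span <- function(cigar) {
  ok <- grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (!all(ok)) {
    stop("malformed CIGAR string: '", cigar[which(!ok)[1]], "'")
  }
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Classify a SAM record from its FLAG
#'
#' Every record falls in exactly one category, tested in this order:
#' `unmapped` (0x4), `secondary` (0x100), `supplementary` (0x800), else
#' `primary_mapped`. Only `primary_mapped` records participate in the sweep
#' and in depth accounting; duplicate-flagged records (0x400) are treated as
#' ordinary primaries.
#'
#' @param flag integer vector of SAM FLAG values.
#' @return character vector of categories.
#' @examples
#' classify_record(c(0L, 4L, 256L, 2048L, 1024L))
#' @export
classify_record <- function(flag) {
  flag <- as.integer(flag)
  ifelse(bitwAnd(flag, 0x4L) != 0L, "unmapped",
    ifelse(bitwAnd(flag, 0x100L) != 0L, "secondary",
      ifelse(bitwAnd(flag, 0x800L) != 0L, "supplementary", "primary_mapped")))
}

# Which segment of the template a record is: "first" (0x40), "last" (0x80),
# "only" for unpaired records.
segment_index <- function(flag) {
  flag <- as.integer(flag)
  ifelse(bitwAnd(flag, 0x1L) == 0L, "only",
    ifelse(bitwAnd(flag, 0x40L) != 0L, "first",
      ifelse(bitwAnd(flag, 0x80L) != 0L, "last", "only")))
}

#' Read alignment records as half-open reference intervals
#'
#' Scans a coordinate-sorted SAM or BAM file and returns one row per record
#' with the fields the sweep needs. Coordinates are converted to 0-based
#' half-open `[start, end)` at ingest (SAM's POS is 1-based). `participates`
#' marks the records the sweep considers: primary mapped records with a
#' positive reference span. Zero-span primaries (fully clipped or
#' insertion-only) cover no position and are dropped from the sweep with a
#' warning.
#'
#' @param file path to a SAM or BAM file (SAM is converted on the fly).
#' @param validate check coordinate sorting (header `SO:coordinate` and
#'   non-decreasing positions within each reference); a violation is a fatal
#'   error naming the first offending record.
#' @return a `data.frame` with columns `ordinal` (1-based position of the
#'   record in file order), `qname`, `flag`, `ref_index`, `rname`, `start`,
#'   `end`, `category`, `segment`, `is_paired`, `participates`, plus
#'   attributes `ref_lengths` (named integer vector from the header) and
#'   `bam` (path to the BAM actually scanned).
#' @export
read_alignment_records <- function(file, validate = TRUE) {
  bam <- as_bam_path(file)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  ref_lengths <- hdr$targets
  if (validate) check_sorted_header(hdr, file)

  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar"))
  )[[1]]

  n <- length(res$flag)
  category <- if (n) classify_record(res$flag) else character(0)
  span <- integer(n)
  mapped <- !is.na(res$pos) & category != "unmapped"
  span[mapped] <- reference_span(res$cigar[mapped])
  start <- ifelse(is.na(res$pos), NA_integer_, res$pos - 1L)

  df <- data.frame(
    ordinal = seq_len(n),
    qname = as.character(res$qname),
    flag = res$flag,
    ref_index = as.integer(res$rname),
    rname = as.character(res$rname),
    start = as.integer(start),
    end = as.integer(start + span),
    category = category,
    segment = if (n) segment_index(res$flag) else character(0),
    is_paired = bitwAnd(as.integer(res$flag), 0x1L) != 0L,
    stringsAsFactors = FALSE
  )
  df$participates <- df$category == "primary_mapped" & !is.na(df$start) &
    df$end > df$start
  zero_span <- df$category == "primary_mapped" & !is.na(df$start) &
    df$end == df$start
  if (any(zero_span)) {
    warning(sum(zero_span), " primary record(s) consume no reference ",
            "(fully clipped); dropped from the sweep")
  }
  if (validate) check_sorted_records(df, file)

  attr(df, "ref_lengths") <- ref_lengths
  attr(df, "bam") <- bam
  df
}

# Header must declare SO:coordinate.
check_sorted_header <- function(hdr, file) {
  hd <- hdr$text[["@HD"]]
  so <- grep("^SO:", unlist(hd), value = TRUE)
  if (length(so) == 0L || !identical(so[1], "SO:coordinate")) {
    stop_format("input '", file, "' is not declared coordinate-sorted ",
                "(header @HD SO:coordinate missing)")
  }
  invisible(TRUE)
}

# Mapped positions must be non-decreasing within each reference block.
check_sorted_records <- function(df, file) {
  m <- df[!is.na(df$ref_index) & !is.na(df$start), , drop = FALSE]
  if (nrow(m) < 2L) return(invisible(TRUE))
  same_ref <- m$ref_index[-1L] == m$ref_index[-nrow(m)]
  decreasing <- m$start[-1L] < m$start[-nrow(m)]
  bad <- which(same_ref & decreasing)
  if (length(bad)) {
    stop_format("input '", file, "' is not coordinate-sorted: record ",
                m$ordinal[bad[1] + 1L], " at ", m$rname[bad[1] + 1L], ":",
                m$start[bad[1] + 1L] + 1L, " is before its predecessor")
  }
  invisible(TRUE)
}

# Accept SAM or BAM; SAM is converted to a temporary BAM. Returns a BAM path.
as_bam_path <- function(file) {
  if (!file.exists(file)) stop_io("input file not found: '", file, "'")
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    file
  }
}
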