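#' Per-position retained coverage of an alignment file
#'
#' Depth at a position is the number of primary mapped records whose
#' reference-consuming span covers it (deletion/skip-spanned positions
#' count, insertions and clips cannot; secondary and supplementary records
#' do not count). This is the package's own verification instrument for the
#' coverage cap.
#'
#' @param file coordinate-sorted SAM or BAM file.
#' @return a `depth_profile`: list with `depth` (one integer
#'   [S4Vectors::Rle] per reference, length = reference length) and
#'   `ref_lengths`.
#' @examples
#' \donttest{
#' ref <- simulate_reference(5000, seed = 7)
#' bam <- simulate_alignments(ref, tempfile(fileext = ".bam"),
#'                            target_depth = 20, read_length_mean = 500,
#'                            seed = 7)
#' max(max_depth(compute_depth(bam)))
#' }
#' @export
compute_depth <- function(file) {
  df <- read_alignment_records(file)
  ref_lengths <- attr(df, "ref_lengths")
  part <- df[df$participates, , drop = FALSE]
  depth <- lapply(seq_along(ref_lengths), function(i) {
    rows <- part$ref_index == i
    IRanges::coverage(
      IRanges::IRanges(start = part$start[rows] + 1L, end = part$end[rows]),
      width = ref_lengths[[i]])
  })
  names(depth) <- names(ref_lengths)
  structure(list(depth = depth, ref_lengths = ref_lengths),
            class = "depth_profile")
}

#' @rdname compute_depth
#' @param profile a `depth_profile`.
#' @return `max_depth()`: named integer vector, maximum depth per reference
#'   (0 for an uncovered reference).
#' @export
max_depth <- function(profile) {
  vapply(profile$depth,
         function(d) if (length(d)) max(as.integer(max(d)), 0L) else 0L,
         integer(1))
}

#' Cap-compliance summary of a depth profile
#'
#' Summarises how a (typically downsampled) file relates to a coverage cap:
#' maximum depth, mean depth over covered positions, and the count/fraction
#' of positions above and exactly at the cap. Fractions are over all
#' reference positions (reference lengths are known from the header).
#'
#' @param profile a `depth_profile` from [compute_depth()].
#' @param cap coverage cap to compare against.
#' @return list with `max_depth`, `mean_depth_covered`, `total_positions`,
#'   `positions_above_cap`, `fraction_above_cap`, `positions_at_cap`,
#'   `fraction_at_cap`.
#' @export
cap_report <- function(profile, cap) {
  total <- sum(as.numeric(unlist(profile$ref_lengths)))
  above <- 0; at <- 0; covered <- 0; bases <- 0; mx <- 0L
  for (d in profile$depth) {
    v <- S4Vectors::runValue(d)
    l <- S4Vectors::runLength(d)
    above <- above + sum(l[v > cap])
    at <- at + sum(l[v == cap])
    covered <- covered + sum(l[v > 0])
    bases <- bases + sum(as.numeric(v) * l)
    if (length(v)) mx <- max(mx, max(v))
  }
  list(max_depth = as.integer(mx),
       mean_depth_covered = if (covered > 0) bases / covered else 0,
       total_positions = total,
       positions_above_cap = above,
       fraction_above_cap = if (total > 0) above / total else 0,
       positions_at_cap = at,
       fraction_at_cap = if (total > 0) at / total else 0)
}

#' Write a depth profile as TSV
#'
#' One line per position — `reference`, 1-based `position`, `depth` — the
#' same shape as `samtools depth -a` output, so downstream tooling can
#' consume either.
#'
#' @param profile a `depth_profile`.
#' @param path output file; `""` writes to stdout.
#' @export
write_depth_tsv <- function(profile, path = "") {
  con <- if (nzchar(path)) file(path, open = "wt") else stdout()
  if (nzchar(path)) on.exit(close(con))
  for (nm in names(profile$depth)) {
    d <- as.integer(profile$depth[[nm]])
    if (!length(d)) next
    utils::write.table(
      data.frame(nm, seq_along(d), d),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(profile)
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("depth_profile over", length(x$depth), "reference(s)\n")
  for (nm in names(x$depth)) {
    d <- x$depth[[nm]]
    cat(sprintf("  %s: length %d, max depth %d, mean %.2f\n", nm,
                length(d), as.integer(max(c(0L, max(d)))),
                mean(d)))
  }
  invisible(x)
}
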