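#' Downsample an alignment file to a per-position coverage cap
#'
#' Top-level entry point. Dispatches to the single-pass sweep for single-end
#' (long-read) data, the two-pass sweep for paired-end data, or the
#' index-based batched-fetching strategy. With `mode = "auto"` the mode is
#' taken from the paired FLAG of the first participating record.
#'
#' @param input coordinate-sorted SAM or BAM file (the fetch strategy
#'   requires an indexed BAM).
#' @param output output path; `.sam` or `.bam` extension selects the format.
#' @param coverage_cap target coverage cap `N` (reads per position).
#' @param seed seed for the priority stream; when `NULL` a random seed is
#'   drawn and reported.
#' @param strategy `"sweep"` (streaming sweep-line, default) or `"fetch"`
#'   (batched window fetching via the BAM index).
#' @param mode `"auto"`, `"single"` or `"paired"`.
#' @param swap_distance maximum start separation for priority swaps (bp).
#' @param window_size fetch-strategy window size (bp); ignored (with a
#'   warning) for the sweep strategy when set explicitly.
#' @param add_pg record the run as a `@PG` line in the output header
#'   (requires the samtools binary; skipped with a message otherwise).
#' @return a `covcap_run` object: run metadata and counts, invisibly.
#' @examples
#' \donttest{
#' ref <- simulate_reference(10000, seed = 1)
#' bam <- simulate_alignments(ref, tempfile(fileext = ".bam"),
#'                            mode = "long_single_end", target_depth = 30,
#'                            read_length_mean = 1000, seed = 1)
#' run <- downsample_alignments(bam, tempfile(fileext = ".bam"),
#'                              coverage_cap = 10, seed = 2109)
#' run
#' }
#' @export
downsample_alignments <- function(input, output, coverage_cap, seed = NULL,
                                  strategy = c("sweep", "fetch"),
                                  mode = c("auto", "single", "paired"),
                                  swap_distance = 5, window_size = NULL,
                                  add_pg = TRUE) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  stopifnot(coverage_cap >= 1, swap_distance >= 0)
  if (strategy == "sweep" && !is.null(window_size)) {
    warning("--window-size applies to the fetch strategy only; ignored")
  }
  if (strategy == "fetch") {
    return(downsample_fetch(input, output, coverage_cap, seed = seed,
                            mode = mode,
                            window_size = if (is.null(window_size)) 10000
                                          else window_size,
                            add_pg = add_pg))
  }
  df <- read_alignment_records(input)
  mode <- resolve_mode(mode, df)
  if (mode == "paired") {
    downsample_paired(input, output, coverage_cap, seed = seed,
                      swap_distance = swap_distance, add_pg = add_pg,
                      .records = df)
  } else {
    downsample_single_end(input, output, coverage_cap, seed = seed,
                          swap_distance = swap_distance, add_pg = add_pg,
                          .records = df)
  }
}

resolve_mode <- function(mode, records) {
  if (mode != "auto") return(mode)
  part <- which(records$participates)
  if (!length(part)) return("single")
  if (records$is_paired[part[1]]) "paired" else "single"
}

#' Single-pass downsampling of single-end alignments
#'
#' Runs the sweep over the primary mapped records and writes the kept records
#' to `output` in input order (hence coordinate-sorted). Supplementary
#' records of kept templates are passed through; secondary records are
#' dropped. The per-position depth of the output never exceeds the cap, and
#' an input whose depth never exceeds the cap is returned unchanged.
#'
#' @inheritParams downsample_alignments
#' @param .records pre-scanned records (internal, avoids a second scan).
#' @return a `covcap_run`, invisibly.
#' @export
downsample_single_end <- function(input, output, coverage_cap, seed = NULL,
                                  swap_distance = 5, add_pg = TRUE,
                                  .records = NULL) {
  seed <- check_seed(seed)
  df <- if (is.null(.records)) read_alignment_records(input) else .records
  part <- df[df$participates, , drop = FALSE]
  res <- sweep_intervals(part, coverage_cap, seed,
                         swap_distance = swap_distance, paired = FALSE)
  kept_ordinals <- part$ordinal[res$kept]
  kept_names <- unique(part$qname[res$kept])

  ord_set <- new_name_set(as.character(kept_ordinals))
  name_set <- new_name_set(kept_names)
  keep_fun <- function(qname, flag, ordinal) {
    suppl <- bitwAnd(flag, 0x800L) != 0L & bitwAnd(flag, 0x104L) == 0L
    in_set(ord_set, as.character(ordinal)) | (suppl & in_set(name_set, qname))
  }
  written <- write_filtered(attr(df, "bam"), output, keep_fun)

  finish_run(input, output, strategy = "sweep", mode = "single",
             coverage_cap = coverage_cap, seed = seed,
             swap_distance = swap_distance, window_size = NA,
             records_read = nrow(df), counts = res$counts,
             records_written = written, add_pg = add_pg)
}

#' Two-pass downsampling of paired-end alignments
#'
#' Pass 1 sweeps the primary mapped records to build the final set of
#' selected template names (a template's fate is decided at its first
#' encountered mate; its second mate is force-kept, which may transiently
#' exceed the cap at mate loci). Pass 2 re-reads the file and writes every
#' non-secondary record whose name is in the selection set — recovering
#' unmapped mates and mates that are physically distant in the file — in
#' input order.
#'
#' @inheritParams downsample_single_end
#' @return a `covcap_run`, invisibly.
#' @export
downsample_paired <- function(input, output, coverage_cap, seed = NULL,
                              swap_distance = 5, add_pg = TRUE,
                              .records = NULL) {
  seed <- check_seed(seed)
  df <- if (is.null(.records)) read_alignment_records(input) else .records
  part <- df[df$participates, , drop = FALSE]
  res <- sweep_intervals(part, coverage_cap, seed,
                         swap_distance = swap_distance, paired = TRUE)

  name_set <- new_name_set(res$selected_names)
  keep_fun <- function(qname, flag, ordinal) {
    bitwAnd(flag, 0x100L) == 0L & in_set(name_set, qname)
  }
  written <- write_filtered(attr(df, "bam"), output, keep_fun)

  finish_run(input, output, strategy = "sweep", mode = "paired",
             coverage_cap = coverage_cap, seed = seed,
             swap_distance = swap_distance, window_size = NA,
             records_read = nrow(df), counts = res$counts,
             records_written = written, add_pg = add_pg,
             selected_templates = length(res$selected_names))
}

# Hash-set membership (base %in% hashes the table once per chunk).
new_name_set <- function(names) unique(as.character(names))
in_set <- function(set, keys) keys %in% set

# Retrieval pass: stream the BAM through filterBam, keeping records for
# which keep_fun(qname, flag, ordinal) is TRUE. Order (and therefore
# coordinate sorting) is preserved. Returns the number of records written.
write_filtered <- function(bam, output, keep_fun) {
  to_sam <- grepl("\\.sam$", output, ignore.case = TRUE)
  dest_bam <- if (to_sam) tempfile(fileext = ".bam") else output
  offset <- 0L
  rule <- S4Vectors::FilterRules(list(keep = function(x) {
    idx <- offset + seq_len(nrow(x))
    offset <<- offset + nrow(x)
    keep_fun(as.character(x$qname), as.integer(x$flag), idx)
  }))
  Rsamtools::filterBam(
    bam, destination = dest_bam, index = character(0), filter = rule,
    indexDestination = FALSE,
    param = Rsamtools::ScanBamParam(what = c("qname", "flag")))
  if (to_sam) {
    out <- Rsamtools::asSam(dest_bam,
                            destination = sub("\\.sam$", "", output,
                                              ignore.case = TRUE),
                            overwrite = TRUE)
    stopifnot(identical(normalizePath(out), normalizePath(output)))
  }
  Rsamtools::countBam(dest_bam)$records
}

# Assemble run metadata, stamp the @PG record, report one summary line.
finish_run <- function(input, output, strategy, mode, coverage_cap, seed,
                       swap_distance, window_size, records_read, counts,
                       records_written, add_pg, selected_templates = NA) {
  run <- structure(list(
    input = input, output = output, strategy = strategy, mode = mode,
    coverage_cap = coverage_cap, seed = seed,
    swap_distance = swap_distance, window_size = window_size,
    generator = PRIORITY_GENERATOR,
    records_read = records_read,
    records_written = records_written,
    selected_templates = selected_templates,
    counts = counts
  ), class = "covcap_run")
  if (add_pg) add_pg_header(output, run)
  message(sprintf(
    "covcap: cap %d, seed %.0f, %s/%s: %d records in, %d written (%d swaps)",
    coverage_cap, seed, strategy, mode, records_read, records_written,
    counts[["swaps"]]))
  invisible(run)
}

#' @export
print.covcap_run <- function(x, ...) {
  cat("covcap run\n")
  cat(sprintf("  input:     %s\n  output:    %s\n", x$input, x$output))
  cat(sprintf("  strategy:  %s (%s mode)\n", x$strategy, x$mode))
  cat(sprintf("  cap:       %d  seed: %.0f  generator: %s\n",
              x$coverage_cap, x$seed, x$generator))
  if (!is.na(x$swap_distance))
    cat(sprintf("  swap_distance: %d bp\n", x$swap_distance))
  if (!is.na(x$window_size))
    cat(sprintf("  window_size:   %d bp\n", x$window_size))
  cat(sprintf("  records:   %d read, %d written\n",
              x$records_read, x$records_written))
  cat("  sweep counts: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Record the run in the output header as a @PG line (samtools reheader for
# BAM; plain text insertion for SAM). Silently skipped if samtools is absent.
add_pg_header <- function(output, run) {
  cl <- sprintf("covcap aln -c %d -s %.0f --strategy %s --mode %s %s -o %s",
                run$coverage_cap, run$seed, run$strategy, run$mode,
                run$input, run$output)
  pg <- paste("@PG", "ID:covcap", "PN:covcap",
              paste0("VN:", as.character(utils::packageVersion("covcap"))),
              paste0("DS:priority-generator=", run$generator),
              paste0("CL:", cl), sep = "\t")
  if (grepl("\\.sam$", output, ignore.case = TRUE)) {
    lines <- readLines(output)
    at <- which(!startsWith(lines, "@"))
    insert <- if (length(at)) at[1] - 1L else length(lines)
    writeLines(append(lines, pg, after = insert), output)
    return(invisible(TRUE))
  }
  samtools <- Sys.which("samtools")
  if (!nzchar(samtools)) {
    message("samtools not found; @PG record not written to header")
    return(invisible(FALSE))
  }
  hdr <- tempfile(fileext = ".sam")
  tmp <- tempfile(fileext = ".bam")
  writeLines(c(system2(samtools, c("view", "-H", output), stdout = TRUE), pg),
             hdr)
  system2(samtools, c("reheader", hdr, output), stdout = tmp)
  file.copy(tmp, output, overwrite = TRUE)
  invisible(TRUE)
}
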