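#' Tile references into contiguous fetch windows
#'
#' The fetch strategy queries the BAM index in large contiguous windows
#' (default 10 kbp) instead of locus by locus. Windows tile each reference
#' without overlap, `[0, W), [W, 2W), ...`, the last clamped to the
#' reference length; a read belongs to (and is decided in) the window
#' containing its start.
#'
#' @param reference_lengths named integer vector of reference lengths, in
#'   header order.
#' @param window_size window width in bp (>= 1).
#' @return `data.frame` with columns `ref_index`, `rname`, `start`, `end`
#'   (0-based half-open).
#' @examples
#' plan_windows(c(chr = 25000L), 10000)
#' @export
plan_windows <- function(reference_lengths, window_size) {
  stopifnot(window_size >= 1)
  out <- lapply(seq_along(reference_lengths), function(i) {
    L <- reference_lengths[[i]]
    if (L <= 0) return(NULL)
    starts <- seq(0L, L - 1L, by = window_size)
    data.frame(ref_index = i,
               rname = names(reference_lengths)[i],
               start = as.integer(starts),
               end = as.integer(pmin(starts + window_size, L)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(ref_index = integer(0), rname = character(0),
                      start = integer(0), end = integer(0))
  }
  out
}

#' Greedy cap-respecting selection within one fetch window
#'
#' Candidates (reads starting in the window) are scanned in shuffled order —
#' the shuffle keys come from the run's seeded priority stream — and each is
#' accepted iff adding it keeps the depth at or below the cap at every
#' position of its span, counted against the running depth (carried reads
#' from earlier windows plus candidates already accepted here). Accepted
#' spans update the running depth, carrying into later windows. This makes
#' the strategy strictly cap-respecting by construction for single-end data.
#'
#' @param candidates `data.frame` with `start`, `end` (0-based half-open,
#'   reference coordinates).
#' @param depth integer vector of running per-position depth over the whole
#'   reference.
#' @param cap coverage cap `N`.
#' @param shuffle_keys numeric vector, one key per candidate; candidates are
#'   scanned in increasing key order (ties by row, earlier first).
#' @return list with `selected` (logical per candidate) and the updated
#'   `depth`.
#' @export
select_in_window <- function(candidates, depth, cap, shuffle_keys) {
  n <- nrow(candidates)
  stopifnot(length(shuffle_keys) == n)
  selected <- logical(n)
  for (i in order(shuffle_keys, seq_len(n))) {
    span <- (candidates$start[i] + 1L):candidates$end[i]
    if (all(depth[span] < cap)) {
      selected[i] <- TRUE
      depth[span] <- depth[span] + 1L
    }
  }
  list(selected = selected, depth = depth)
}

#' Downsample via index-based batched fetching
#'
#' Alternative strategy to the streaming sweep: reads are fetched window by
#' window through the BAM index, shuffled with the seeded generator, and
#' greedily accepted under the cap ([select_in_window()]). Paired inputs use
#' the same template policy as the sweep (first-encountered mate decides;
#' the second mate is force-accepted) and the same name-set retrieval pass,
#' so mates are recovered even when unmapped or distant.
#'
#' @inheritParams downsample_alignments
#' @param window_size fetch window width in bp (default 10000).
#' @return a `covcap_run`, invisibly.
#' @export
downsample_fetch <- function(input, output, coverage_cap, seed = NULL,
                             mode = c("auto", "single", "paired"),
                             window_size = 10000, add_pg = TRUE) {
  mode <- match.arg(mode)
  stopifnot(coverage_cap >= 1, window_size >= 1)
  seed <- check_seed(seed)
  if (grepl("\\.sam$", input, ignore.case = TRUE)) {
    stop_usage("the fetch strategy requires an indexed BAM; convert the SAM ",
               "or use --strategy sweep")
  }
  if (!file.exists(paste0(input, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", input, ignore.case = TRUE))) {
    stop_usage("no BAM index (.bai) found for '", input, "'; create one ",
               "(samtools index) or use --strategy sweep")
  }

  hdr <- Rsamtools::scanBamHeader(input)[[1]]
  check_sorted_header(hdr, input)
  ref_lengths <- hdr$targets
  windows <- plan_windows(ref_lengths, window_size)

  first_paired <- NA
  selected_names <- character(0)
  tmpl_state <- new.env(parent = emptyenv())  # name -> TRUE/FALSE
  draws_used <- 0
  n_candidates <- 0L
  n_forced <- 0L
  depth <- NULL
  cur_ref <- 0L

  for (w in seq_len(nrow(windows))) {
    if (windows$ref_index[w] != cur_ref) {
      cur_ref <- windows$ref_index[w]
      depth <- integer(ref_lengths[[cur_ref]])
    }
    gr <- GenomicRanges::GRanges(
      windows$rname[w],
      IRanges::IRanges(windows$start[w] + 1L, windows$end[w]))
    res <- Rsamtools::scanBam(
      input,
      param = Rsamtools::ScanBamParam(
        which = gr, what = c("qname", "flag", "pos", "cigar")))[[1]]
    if (!length(res$flag)) next
    cat_ <- classify_record(res$flag)
    start0 <- res$pos - 1L
    keep <- cat_ == "primary_mapped" & !is.na(start0) &
      start0 >= windows$start[w] & start0 < windows$end[w]
    if (!any(keep)) next
    cand <- data.frame(
      qname = as.character(res$qname[keep]),
      start = start0[keep],
      end = start0[keep] + reference_span(res$cigar[keep]),
      is_paired = bitwAnd(as.integer(res$flag[keep]), 0x1L) != 0L,
      stringsAsFactors = FALSE)
    cand <- cand[cand$end > cand$start, , drop = FALSE]
    m <- nrow(cand)
    if (!m) next
    if (is.na(first_paired)) first_paired <- cand$is_paired[1]
    n_candidates <- n_candidates + m
    keys <- .priority_draws(seed, draws_used + 1, m)
    draws_used <- draws_used + m

    paired <- switch(mode, paired = TRUE, single = FALSE, auto = first_paired)
    if (!paired) {
      sel <- select_in_window(cand, depth, coverage_cap, keys)
      depth <- sel$depth
      if (any(sel$selected)) {
        selected_names <- c(selected_names,
                            unique(cand$qname[sel$selected]))
      }
    } else {
      # template policy: scan in shuffled order; first encounter competes,
      # second encounter is forced (selected) or skipped (rejected)
      for (i in order(keys, seq_len(m))) {
        nm <- cand$qname[i]
        span <- (cand$start[i] + 1L):cand$end[i]
        prev <- get0(nm, envir = tmpl_state)
        if (!is.null(prev)) {
          if (isTRUE(prev)) {
            depth[span] <- depth[span] + 1L
            n_forced <- n_forced + 1L
          }
        } else if (all(depth[span] < coverage_cap)) {
          depth[span] <- depth[span] + 1L
          assign(nm, TRUE, envir = tmpl_state)
          selected_names <- c(selected_names, nm)
        } else {
          assign(nm, FALSE, envir = tmpl_state)
        }
      }
    }
  }

  name_set <- new_name_set(selected_names)
  keep_fun <- function(qname, flag, ordinal) {
    bitwAnd(flag, 0x100L) == 0L & in_set(name_set, qname)
  }
  written <- write_filtered(input, output, keep_fun)
  n_read <- Rsamtools::countBam(input)$records

  finish_run(input, output, strategy = "fetch",
             mode = if (isTRUE(first_paired)) "paired" else "single",
             coverage_cap = coverage_cap, seed = seed,
             swap_distance = NA, window_size = window_size,
             records_read = n_read,
             counts = c(considered = n_candidates,
                        kept = length(name_set),
                        discarded = n_candidates - length(name_set) -
                          n_forced,
                        swaps = 0L, forced_mate_keeps = n_forced),
             records_written = written, add_pg = add_pg,
             selected_templates = length(name_set))
}
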