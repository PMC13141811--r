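# Independent oracles, deliberately naive: plain loops and lists, no shared
# code with the package's active-set or coverage machinery.

# Per-position depth by scanning every interval (0-based half-open input,
# returns an integer vector of length ref_len).
naive_depth <- function(start, end, ref_len) {
  d <- integer(ref_len)
  for (i in seq_along(start)) {
    if (end[i] > start[i]) {
      idx <- (start[i] + 1L):min(end[i], ref_len)
      d[idx] <- d[idx] + 1L
    }
  }
  d
}

# Literal step-by-step replay of the selection logic: evict ended reads,
# keep below cap, otherwise compare against the worst member found by a
# linear scan and swap if better and close enough. List-based, no heaps.
naive_sweep <- function(intervals, cap, seed, swap_distance = 5) {
  n <- nrow(intervals)
  pri <- priority_draws(seed, n)
  ord <- if (!is.null(intervals$ordinal)) intervals$ordinal else seq_len(n)
  kept <- logical(n)
  active <- list()
  cur_ref <- NA
  for (i in seq_len(n)) {
    if (!identical(cur_ref, intervals$ref_index[i])) {
      active <- list()
      cur_ref <- intervals$ref_index[i]
    }
    keep_idx <- vapply(active, function(a) a$end > intervals$start[i],
                       logical(1))
    active <- active[keep_idx]
    me <- list(i = i, start = intervals$start[i], end = intervals$end[i],
               pri = pri[i], ord = ord[i])
    if (length(active) < cap) {
      active[[length(active) + 1L]] <- me
      kept[i] <- TRUE
    } else {
      w <- 1L
      for (j in seq_along(active)) {
        if (active[[j]]$pri > active[[w]]$pri ||
            (active[[j]]$pri == active[[w]]$pri &&
             active[[j]]$ord > active[[w]]$ord)) w <- j
      }
      better <- me$pri < active[[w]]$pri ||
        (me$pri == active[[w]]$pri && me$ord < active[[w]]$ord)
      if (better && (me$start - active[[w]]$start) <= swap_distance) {
        kept[active[[w]]$i] <- FALSE
        active[[w]] <- me
        kept[i] <- TRUE
      }
    }
  }
  kept
}
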