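#' Active set of retained reads overlapping the sweep position
#'
#' The sweep advances across each reference in start order, keeping the
#' currently retained reads that still overlap the frontier. The set supports
#' end-based eviction, worst-member lookup (maximum `(priority, ordinal)`
#' lexicographically — lower priority is better) and swap. Capacity is the
#' coverage cap `N`; in paired mode forced mate insertions may transiently
#' push the live size above `N`.
#'
#' @param cap coverage cap `N` (positive integer).
#' @return an `active_set` object.
#' @export
new_active_set <- function(cap) {
  stopifnot(cap >= 1)
  s <- new.env(parent = emptyenv())
  s$cap <- cap
  s$id <- integer(0)       # row id of the interval (caller's key)
  s$name <- character(0)   # template name
  s$start <- integer(0)
  s$end <- integer(0)
  s$priority <- numeric(0)
  s$ordinal <- integer(0)
  class(s) <- "active_set"
  s
}

#' @rdname new_active_set
#' @param set an `active_set`.
#' @export
active_size <- function(set) length(set$id)

as_insert <- function(set, id, name, start, end, priority, ordinal) {
  k <- length(set$id) + 1L
  set$id[k] <- id
  set$name[k] <- name
  set$start[k] <- start
  set$end[k] <- end
  set$priority[k] <- priority
  set$ordinal[k] <- ordinal
  invisible(set)
}

as_remove <- function(set, k) {
  for (f in c("id", "name", "start", "end", "priority", "ordinal")) {
    set[[f]] <- set[[f]][-k]
  }
  invisible(set)
}

# Index of the worst member: maximum (priority, ordinal) lexicographically.
as_worst <- function(set) {
  if (!length(set$id)) return(NA_integer_)
  top <- which(set$priority == max(set$priority))
  top[which.max(set$ordinal[top])]
}

#' Evict members ending at or before a position
#'
#' Intervals are half-open, so a read whose `end` equals the sweep position
#' no longer covers it and is evicted. Called with the start of each incoming
#' interval before the interval is considered.
#'
#' @param set an `active_set`.
#' @param position current sweep position (0-based).
#' @return integer vector of evicted member ids (invisibly empty when none).
#' @export
evict_before <- function(set, position) {
  gone <- which(set$end <= position)
  ids <- set$id[gone]
  if (length(gone)) as_remove(set, gone)
  ids
}

#' Is a priority swap permitted at this distance?
#'
#' A better-priority incoming read may replace the worst active member only
#' if their start positions are within `swap_distance` (inclusive). This
#' bounds how far back an eviction can open a coverage gap in the already
#' processed region.
#'
#' @param new_start start of the incoming read (0-based).
#' @param evictee_start start of the candidate evictee.
#' @param swap_distance maximum separation in bp (default 5).
#' @return logical.
#' @examples
#' swap_permitted(105, 100, 5)  # boundary: permitted
#' swap_permitted(106, 100, 5)
#' @export
swap_permitted <- function(new_start, evictee_start, swap_distance = 5) {
  new_start - evictee_start <= swap_distance
}

#' Decide the fate of an incoming read
#'
#' Core selection logic, applied after [evict_before()] at the incoming
#' start: if the live size is below the cap the read is kept; otherwise it
#' may swap with the worst member if it has strictly better
#' `(priority, ordinal)` and the swap distance permits; otherwise it is
#' discarded and the set is unchanged. A priority tie never swaps (the
#' earlier record, already a member, wins).
#'
#' @param set an `active_set`.
#' @param id caller's key for the interval (returned in decisions).
#' @param name template name.
#' @param start,end half-open interval.
#' @param priority,ordinal selection keys (lower is better, lexicographic).
#' @param swap_distance see [swap_permitted()].
#' @return a list with `action` (`"keep"`, `"swap"` or `"discard"`) and, for
#'   swaps, `evicted_id` and `evicted_name`.
#' @export
consider <- function(set, id, name, start, end, priority, ordinal,
                     swap_distance = 5) {
  if (length(set$id) < set$cap) {
    as_insert(set, id, name, start, end, priority, ordinal)
    return(list(action = "keep"))
  }
  w <- as_worst(set)
  better <- priority < set$priority[w] ||
    (priority == set$priority[w] && ordinal < set$ordinal[w])
  if (better && swap_permitted(start, set$start[w], swap_distance)) {
    evicted_id <- set$id[w]
    evicted_name <- set$name[w]
    as_remove(set, w)
    as_insert(set, id, name, start, end, priority, ordinal)
    return(list(action = "swap", evicted_id = evicted_id,
                evicted_name = evicted_name))
  }
  list(action = "discard")
}

# Remove every member of a template (used when a swap evicts one mate of a
# selected pair: the whole template is dropped so depth accounting and the
# selection set stay consistent).
as_remove_name <- function(set, name) {
  k <- which(set$name == name)
  ids <- set$id[k]
  if (length(k)) as_remove(set, k)
  ids
}

#' Sweep coordinate-sorted intervals under a coverage cap
#'
#' Runs the full sweep over a set of alignment intervals: priorities are
#' drawn sequentially from the seeded generator in row order (one draw per
#' interval), each interval triggers eviction of members ending at or before
#' its start and is then kept, swapped in, or discarded. The active set is
#' reset at every reference boundary.
#'
#' In paired mode (`paired = TRUE`) a template's fate is decided at its
#' first-encountered mate: the second mate never competes on priority — it is
#' force-inserted (with the template's priority) if the template is still
#' selected, even when the set is full (the documented source of occasional
#' cap overshoot at mate loci), and silently discarded if the template was
#' rejected or evicted. A swap that evicts any member of a template removes
#' the whole template from the selection.
#'
#' @param intervals `data.frame` with columns `ref_index`, `start`, `end`
#'   (0-based half-open), `qname` and optionally `ordinal` (defaults to row
#'   number); must be sorted by `(ref_index, start)`.
#' @param cap coverage cap `N`.
#' @param seed seed for the priority stream (see [priority_draws()]).
#' @param swap_distance see [swap_permitted()].
#' @param paired apply the paired-end template policy.
#' @return a list with `kept` (logical per row, final), `action` (per-row
#'   `"keep"`, `"swap"`, `"forced_keep"` or `"discard"` at encounter time),
#'   `priority` (the draws), `selected_names` (unique template names kept),
#'   `seed`, and `counts`.
#' @export
sweep_intervals <- function(intervals, cap, seed, swap_distance = 5,
                            paired = FALSE) {
  stopifnot(cap >= 1, swap_distance >= 0)
  n <- nrow(intervals)
  ref <- intervals$ref_index
  start <- intervals$start
  end <- intervals$end
  name <- as.character(intervals$qname)
  ordinal <- if (!is.null(intervals$ordinal)) intervals$ordinal else seq_len(n)

  if (n > 1L) {
    bad <- which(ref[-1L] == ref[-n] & start[-1L] < start[-n])
    if (length(bad)) {
      stop("intervals not sorted by (reference, start): row ", bad[1] + 1L)
    }
  }

  seed <- check_seed(seed)
  priority <- if (n) .priority_draws(seed, 1, n) else numeric(0)
  kept <- logical(n)
  action <- character(n)
  n_swaps <- 0L
  n_forced <- 0L

  # paired-mode template state: priority of the first-seen mate, or NA once
  # rejected/evicted; row ids per template for cascade un-keeping
  tmpl_pri <- new.env(parent = emptyenv(), size = max(n, 29L))
  tmpl_rows <- new.env(parent = emptyenv(), size = max(n, 29L))

  set <- new_active_set(cap)
  cur_ref <- NA_integer_

  reject_template <- function(nm) {
    assign(nm, NA_real_, envir = tmpl_pri)
    rows <- get0(nm, envir = tmpl_rows)
    if (!is.null(rows)) kept[rows] <<- FALSE
  }

  for (i in seq_len(n)) {
    if (is.na(cur_ref) || ref[i] != cur_ref) {
      set <- new_active_set(cap)
      cur_ref <- ref[i]
    }
    evict_before(set, start[i])

    if (paired) {
      prev <- get0(name[i], envir = tmpl_pri)
      if (!is.null(prev)) {
        # second-encountered mate: no priority competition
        if (is.na(prev)) {
          action[i] <- "discard"
        } else {
          as_insert(set, i, name[i], start[i], end[i], prev, ordinal[i])
          kept[i] <- TRUE
          action[i] <- "forced_keep"
          n_forced <- n_forced + 1L
          assign(name[i], c(get0(name[i], envir = tmpl_rows), i),
                 envir = tmpl_rows)
        }
        next
      }
    }

    d <- consider(set, i, name[i], start[i], end[i], priority[i], ordinal[i],
                  swap_distance)
    action[i] <- d$action
    if (d$action != "discard") {
      kept[i] <- TRUE
      if (paired) {
        assign(name[i], priority[i], envir = tmpl_pri)
        assign(name[i], i, envir = tmpl_rows)
      }
      if (d$action == "swap") {
        n_swaps <- n_swaps + 1L
        kept[d$evicted_id] <- FALSE
        if (paired) {
          # drop the evictee's whole template, including its other mate
          reject_template(d$evicted_name)
          as_remove_name(set, d$evicted_name)
        }
      }
    } else if (paired) {
      assign(name[i], NA_real_, envir = tmpl_pri)
    }
  }

  selected <- unique(name[kept])
  list(kept = kept, action = action, priority = priority,
       selected_names = selected, seed = seed,
       counts = c(considered = n, kept = sum(kept),
                  discarded = n - sum(kept), swaps = n_swaps,
                  forced_mate_keeps = n_forced))
}
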