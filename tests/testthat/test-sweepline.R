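mk_set <- function(cap, start, end, priority, ordinal = seq_along(start)) {
  s <- new_active_set(cap)
  for (i in seq_along(start)) {
    consider(s, id = i, name = as.character(i), start = start[i],
             end = end[i], priority = priority[i], ordinal = ordinal[i])
  }
  s
}

test_that("evict_before removes exactly the members ending at or before p", {
  s <- mk_set(10, start = c(0, 0, 0), end = c(5, 10, 20),
              priority = c(1, 2, 3))
  gone <- evict_before(s, 10)
  expect_setequal(gone, c(1, 2))  # half-open: a read ending at 10 is gone
  expect_equal(active_size(s), 1)

  s2 <- mk_set(10, 0, 5, 1)
  expect_length(evict_before(s2, 0), 0)
  expect_equal(active_size(s2), 1)

  s3 <- new_active_set(3)
  expect_length(evict_before(s3, 100), 0)
})

test_that("swap_permitted is inclusive at the boundary", {
  expect_true(swap_permitted(105, 100, 5))
  expect_false(swap_permitted(106, 100, 5))
  expect_true(swap_permitted(100, 100, 0))
})

test_that("consider keeps below cap, swaps on better priority, else discards", {
  s <- new_active_set(2)
  expect_equal(consider(s, 1, "a", 0, 50, 9, 1)$action, "keep")

  # full at N=1, incoming strictly better and within distance -> swap
  s <- mk_set(1, start = 100, end = 200, priority = 7)
  d <- consider(s, 2, "new", 103, 190, 3, 2)
  expect_equal(d$action, "swap")
  expect_equal(d$evicted_id, 1)
  expect_equal(s$priority, 3)

  # full, incoming worse -> discard, set unchanged
  s <- mk_set(1, start = 100, end = 200, priority = 3)
  expect_equal(consider(s, 2, "new", 103, 190, 7, 2)$action, "discard")
  expect_equal(s$priority, 3)

  # priority tie never swaps (earlier ordinal wins)
  s <- mk_set(1, start = 100, end = 200, priority = 5)
  expect_equal(consider(s, 2, "new", 100, 190, 5, 2)$action, "discard")

  # better priority but out of swap range -> discard
  s <- mk_set(1, start = 100, end = 200, priority = 7)
  expect_equal(consider(s, 2, "new", 106, 190, 3, 2)$action, "discard")
})

test_that("non-overlapping intervals are all kept at any cap", {
  df <- data.frame(ref_index = 1L, start = seq(0, 900, by = 100),
                   end = seq(50, 950, by = 100),
                   qname = sprintf("q%d", 1:10))
  res <- sweep_intervals(df, cap = 1, seed = 4)
  expect_true(all(res$kept))
  expect_true(all(res$action == "keep"))
})

test_that("identical full-overlap reads retain the N lowest priorities", {
  df <- data.frame(ref_index = 1L, start = 0L, end = 100L,
                   qname = sprintf("q%02d", 1:10))
  res <- sweep_intervals(df, cap = 4, seed = 2109)
  expect_equal(sum(res$kept), 4)
  expect_setequal(which(res$kept), order(res$priority)[1:4])
})

test_that("the active set resets at each reference boundary", {
  df <- data.frame(ref_index = rep(c(1L, 2L), each = 5),
                   start = rep(0L, 10), end = rep(100L, 10),
                   qname = sprintf("q%02d", 1:10))
  res <- sweep_intervals(df, cap = 2, seed = 5)
  # first record of the second reference enters an empty set
  expect_equal(res$action[6], "keep")
  expect_equal(sum(res$kept[1:5]), 2)
  expect_equal(sum(res$kept[6:10]), 2)
})

test_that("unsorted interval input is rejected", {
  df <- data.frame(ref_index = 1L, start = c(100L, 50L),
                   end = c(200L, 150L), qname = c("a", "b"))
  expect_error(sweep_intervals(df, 5, 1), "not sorted")
})

test_that("kept depth never exceeds the cap on randomized instances", {
  set.seed(202)
  for (rep in 1:40) {
    df <- random_instance()
    cap <- sample(1:5, 1)
    res <- sweep_intervals(df, cap, seed = 1000 + rep)
    d <- naive_depth(df$start[res$kept], df$end[res$kept], 500)
    expect_lte(max(d), cap)
  }
})

test_that("inputs already under the cap pass through unchanged", {
  set.seed(303)
  for (rep in 1:30) {
    df <- random_instance(n_max = 30)
    cap <- max(naive_depth(df$start, df$end, 500))
    res <- sweep_intervals(df, cap, seed = rep)
    expect_true(all(res$kept))
  }
})

test_that("with co-located starts the region kept in full is the
           min(depth, N) lowest-priority sample", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    len <- sample(50:100, 1)
    start <- sort(sample(0:5, n, replace = TRUE))  # all within swap_distance
    df <- data.frame(ref_index = 1L, start = start, end = start + len,
                     qname = sprintf("q%02d", 1:n))
    cap <- sample(2:4, 1)
    res <- sweep_intervals(df, cap, seed = rep)
    # every swap is permitted, so the survivors over the jointly covered
    # region [max start, min end) are exactly the N best priorities
    expect_setequal(which(res$kept),
                    order(res$priority)[seq_len(min(cap, n))])
    d <- naive_depth(df$start[res$kept], df$end[res$kept], max(df$end))
    region <- (max(df$start) + 1L):min(df$end)
    expect_true(all(d[region] == min(cap, n)))
  }
})

test_that("the sweep agrees with a naive step-by-step replay", {
  set.seed(505)
  for (rep in 1:30) {
    df <- random_instance()
    cap <- sample(1:5, 1)
    res <- sweep_intervals(df, cap, seed = 7000 + rep)
    expect_identical(res$kept, naive_sweep(df, cap, seed = 7000 + rep))
  }
})
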