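# A stratification whose one group has known fit values is easiest to build
# in 1-D: records at centroid +/- offsets give fits equal to the offsets.

test_that("split regions follow the threshold rule with inclusive ties", {
  strat <- stratification(list(g = paste0("r", 1:8)))
  vals <- setNames(1:8, paste0("r", 1:8))
  res <- split_by_values(strat, "g", vals, split_spec(4.5, 6.5))
  expect_equal(unname(lengths(result_strat(res)$groups)), c(4L, 2L, 2L))

  # thresholds at the max: single region, identity up to naming
  res <- split_by_values(strat, "g", vals, split_spec(8, 8))
  expect_length(result_strat(res)$groups, 1L)
  expect_identical(result_strat(res)$groups[[1L]], paste0("r", 1:8))

  # everything below t1: one good group only
  res <- split_by_values(strat, "g", vals, split_spec(100, 200))
  expect_length(result_strat(res)$groups, 1L)
  expect_match(names(result_strat(res)$groups), "good")

  # a value equal to t1 is good, equal to t2 is ambiguous (ties fall better)
  res <- split_by_values(strat, "g", vals, split_spec(4, 6))
  g <- result_strat(res)$groups
  expect_true("r4" %in% g[["g (good)"]])
  expect_true("r6" %in% g[["g (ambiguous)"]])
})

test_that("similarity-oriented split reverses the region inequalities", {
  strat <- stratification(list(g = paste0("r", 1:4)))
  vals <- setNames(c(0.9, 0.7, 0.5, 0.2), paste0("r", 1:4))
  res <- split_by_values(strat, "g", vals,
                         split_spec(0.4, 0.8, orientation = "similarity"))
  g <- result_strat(res)$groups
  expect_identical(g[["g (good)"]], "r1")             # >= t2
  expect_setequal(g[["g (ambiguous)"]], c("r2", "r3")) # in [t1, t2)
  expect_identical(g[["g (bad)"]], "r4")              # < t1
})

test_that("split through the fit profile uses the new centroids afterwards", {
  set.seed(61)
  m <- named_matrix(c(rnorm(6, 0, 0.2), rnorm(4, 8, 0.2)), 10, 1)
  strat <- stratification(list(g = rownames(m)))
  res <- split_cluster(m, strat, "g", metric = "euclidean")
  s2 <- result_strat(res)
  expect_gt(length(s2$groups), 1L)
  # fits against the new centroids are tighter than against the old one
  old_fit <- within_cluster_fit(m, strat)$fit
  new_fit <- within_cluster_fit(m, s2)$fit
  expect_lt(mean(new_fit), mean(old_fit))
  expect_error(split_cluster(m, strat, "nope"), class = "unknown_record_error")
})

test_that("shifting moves the stray record in the 1-D hand trace", {
  m <- matrix(c(0, 0.1, 9, 10), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), "f"))
  strat <- stratification(list(A = c("a", "b", "c"), B = "d"))
  res <- shift_records(m, strat, "euclidean")
  s2 <- result_strat(res)
  expect_setequal(s2$groups$A, c("a", "b"))
  expect_setequal(s2$groups$B, c("c", "d"))
  expect_equal(count_fixed_point_moves(m, s2, metric_spec("euclidean")), 0L)
})

test_that("an already-optimal assignment is a shift fixed point", {
  blobs <- make_blobs(k = 3, per_cluster = 10, d = 4, separation = 12, seed = 62)
  res <- shift_records(blobs$matrix, blobs$truth, "euclidean")
  expect_equal(res$log$moves, 0L)
  expect_identical(result_strat(res)$groups, blobs$truth$groups)
})

test_that("shift is monotone and ends at a brute-force fixed point", {
  for (seed in 1:10) {
    m <- random_matrix(60, 4, seed = 1000 + seed)
    strat <- random_strat(m, 3, seed = 2000 + seed)
    # squared-euclidean shares the euclidean assignment rule but its total
    # is the Lloyd objective, which is provably non-increasing
    res <- shift_records(m, strat, "sq_euclidean")
    obj <- res$log$objective_trace
    expect_true(all(diff(obj) <= 1e-9 * max(obj)), info = seed)
    expect_equal(count_fixed_point_moves(m, result_strat(res),
                                         metric_spec("euclidean")), 0L,
                 info = seed)
  }
})

test_that("shift respects scope and drops emptied groups with a log entry", {
  # group C straddles the two blobs: its own centroid is far from both of its
  # records, so in-scope shifting empties it
  m <- matrix(c(0, 0.1, 5, 5.1, 4.9, 0.2), 6, 1,
              dimnames = list(letters[1:6], "f"))
  strat <- stratification(list(A = c("a", "b"), B = c("c", "d"),
                               C = c("e", "f")))
  res <- shift_records(m, strat, "euclidean", scope = "C")
  s2 <- result_strat(res)
  expect_setequal(s2$groups$A, c("a", "b", "f"))
  expect_setequal(s2$groups$B, c("c", "d", "e"))
  expect_false("C" %in% names(s2$groups))
  expect_true("C" %in% res$log$dropped)
})

test_that("merge concatenates in group-then-original order and is associative", {
  strat <- stratification(list(A = c("r1", "r2"), B = "r3", C = c("r4", "r5")))
  res <- merge_clusters(strat, c("A", "B"), new_name = "AB")
  expect_identical(result_strat(res)$groups$AB, c("r1", "r2", "r3"))

  all1 <- merge_clusters(result_strat(res), c("AB", "C"))
  all2 <- merge_clusters(strat, c("A", "B", "C"))
  expect_setequal(result_strat(all1)$groups[[1L]],
                  result_strat(all2)$groups[[1L]])
  expect_length(result_strat(all2)$groups, 1L)
  expect_error(merge_clusters(strat, "A"), class = "param_error")
  expect_error(merge_clusters(strat, c("A", "Z")), class = "unknown_record_error")
})

test_that("exclude conserves records, is recoverable, and improves fit", {
  strat <- stratification(list(A = paste0("r", 1:7), B = paste0("r", 8:10)))
  res <- exclude_records(strat, groups = "B")
  expect_length(strat_records(result_strat(res)), 7L)
  expect_setequal(res$excluded, paste0("r", 8:10))

  back <- include_records(res, into = "B")
  expect_setequal(strat_records(result_strat(back)), paste0("r", 1:10))
  expect_setequal(result_strat(back)$groups$B, paste0("r", 8:10))
  expect_length(back$excluded, 0L)

  # excluding a gross outlier strictly reduces the group's mean fit
  set.seed(63)
  m <- named_matrix(c(rnorm(9), 100), 10, 1)
  s <- stratification(list(g = rownames(m)))
  before <- mean(within_cluster_fit(m, s)$fit)
  res2 <- exclude_records(s, records = "r10")
  after <- mean(within_cluster_fit(m, result_strat(res2))$fit)
  expect_lt(after, before)
  expect_error(exclude_records(s, records = "zz"), class = "unknown_record_error")
})

test_that("random operator sequences conserve the record multiset", {
  for (seq_i in 1:20) {
    set.seed(3000 + seq_i)
    m <- random_matrix(30, 3, seed = 4000 + seq_i)
    state <- list(strat = random_strat(m, 4, seed = 5000 + seq_i),
                  pool = character(0))
    universe <- sort(strat_records(state$strat))
    for (step in 1:10) {
      op <- sample(c("split", "shift", "merge", "exclude", "include"), 1L)
      gs <- names(state$strat$groups)
      res <- switch(op,
        split = {
          big <- gs[which.max(lengths(state$strat$groups))]
          if (length(state$strat$groups[[big]]) < 2L) NULL
          else split_cluster(m, state$strat, big, pool = state$pool)
        },
        shift = if (length(gs) < 2L) NULL
                else shift_records(m, state$strat, pool = state$pool),
        merge = if (length(gs) < 2L) NULL
                else merge_clusters(state$strat, sample(gs, 2L),
                                    new_name = paste0("m", step),
                                    pool = state$pool),
        exclude = {
          ids <- strat_records(state$strat)
          if (length(ids) < 3L) NULL
          else exclude_records(state$strat, records = sample(ids, 1L),
                               pool = state$pool)
        },
        include = {
          if (length(state$pool) == 0L) NULL
          else include_records(
            structure(list(stratification = state$strat,
                           excluded = state$pool, log = list()),
                      class = "refinement_result"),
            into = names(state$strat$groups)[1L])
        })
      if (is.null(res)) next
      state <- list(strat = result_strat(res), pool = res$excluded)
      expect_identical(sort(c(strat_records(state$strat), state$pool)),
                       universe)
    }
  }
})

test_that("split then merge restores the original record set", {
  m <- random_matrix(12, 2, seed = 81)
  strat <- random_strat(m, 2, seed = 82)
  g <- names(strat$groups)[1L]
  orig <- strat$groups[[g]]
  res <- split_cluster(m, strat, g)
  parts <- grep(paste0("^", g, " \\("), names(result_strat(res)$groups),
                value = TRUE)
  if (length(parts) >= 2L) {
    merged <- merge_clusters(result_strat(res), parts, new_name = g)
    expect_setequal(result_strat(merged)$groups[[g]], orig)
  } else {
    expect_setequal(result_strat(res)$groups[[parts]], orig)
  }
})
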