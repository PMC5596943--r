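test_that("overlap matrix counts shared records per group pair", {
  A <- stratification(list(a1 = c("r1", "r2"), a2 = "r3"))
  B <- stratification(list(b1 = "r1", b2 = c("r2", "r3")))
  M <- overlap_matrix(A, B)
  expect_equal(unname(M), rbind(c(1L, 1L), c(0L, 1L)), ignore_attr = TRUE)

  MA <- overlap_matrix(A, A)
  expect_equal(unname(MA), diag(c(2L, 1L)), ignore_attr = TRUE)

  C <- stratification(list(c1 = c("x", "y")))
  expect_error(overlap_matrix(A, C), class = "empty_universe_error")
})

test_that("overlap marginals equal group sizes over the shared universe", {
  for (seed in 1:15) {
    m <- random_matrix(40, 2, seed = 6000 + seed)
    A <- random_strat(m, sample(2:5, 1), seed = 7000 + seed)
    B <- random_strat(m, sample(2:5, 1), seed = 8000 + seed)
    M <- overlap_matrix(A, B)
    expect_equal(unname(rowSums(M)), unname(lengths(A$groups)))
    expect_equal(unname(colSums(M)), unname(lengths(B$groups)))
    expect_equal(sum(M), attr(M, "universe_size"))
  }
  # records in only one stratification are excluded from the universe
  A <- stratification(list(g = c("r1", "r2", "zz")))
  B <- stratification(list(h = c("r1", "r2", "ww")))
  expect_equal(attr(overlap_matrix(A, B), "universe_size"), 2L)
})

test_that("fuzzy memberships are rejected by overlap comparison", {
  U <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("r1", c("c1", "c2")))
  mem <- fuzzy_membership(U)
  strat <- stratification(list(g = "r1"))
  expect_error(overlap_matrix(mem, strat), class = "param_error")
  expect_error(overlap_matrix(strat, mem), class = "param_error")
})

test_that("adjusted Rand index matches its closed forms and the oracle", {
  A <- stratification(list(a = c("r1", "r2"), b = c("r3", "r4")))
  expect_equal(adjusted_rand(A, A), 1)

  # all-singletons vs all-in-one on n = 4: index 0 (chance level)
  S <- stratification(setNames(as.list(paste0("r", 1:4)), paste0("g", 1:4)))
  O <- stratification(list(all = paste0("r", 1:4)))
  expect_equal(adjusted_rand(S, O), 0)

  # invariant to group relabelling
  A2 <- stratification(list(zz = c("r3", "r4"), yy = c("r1", "r2")))
  expect_equal(adjusted_rand(A, A2), 1)

  for (seed in 1:20) {
    m <- random_matrix(25, 2, seed = 9000 + seed)
    A <- random_strat(m, 3, seed = 9100 + seed)
    B <- random_strat(m, 4, seed = 9200 + seed)
    expect_equal(adjusted_rand(A, B),
                 naive_ari(strat_labels(A)[rownames(m)],
                           strat_labels(B)[rownames(m)]),
                 tolerance = 1e-12)
  }
})

test_that("adjusted Rand agrees with mclust's implementation", {
  skip_if_not_installed("mclust")
  for (seed in 1:10) {
    m <- random_matrix(30, 2, seed = 9500 + seed)
    A <- random_strat(m, 3, seed = 9600 + seed)
    B <- random_strat(m, 3, seed = 9700 + seed)
    expect_equal(adjusted_rand(A, B),
                 mclust::adjustedRandIndex(strat_labels(A)[rownames(m)],
                                           strat_labels(B)[rownames(m)]),
                 tolerance = 1e-12)
  }
})

test_that("Kaplan-Meier reproduces the hand-worked product-limit values", {
  # event at 10, censorings at 5 and 15: risk set at t=10 is 2, so S(10)=0.5
  df <- data.frame(record_id = c("a", "b", "c"), time = c(10, 5, 15),
                   event = c(1L, 0L, 0L))
  cv <- km_curve(df)
  expect_equal(km_survival_at(cv, 9.9), 1)
  expect_equal(km_survival_at(cv, 10), 0.5)
  expect_equal(cv$n_risk, 2)

  # all events, distinct times, n=4: steps 0.75, 0.5, 0.25, 0
  df <- data.frame(record_id = letters[1:4], time = c(2, 4, 6, 8),
                   event = 1L)
  cv <- km_curve(df)
  expect_equal(cv$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(cv$median, 4)        # smallest time with S <= 0.5

  # no events: flat at 1 with a warning, median not reached
  df$event <- 0L
  expect_warning(cv <- km_curve(df), class = "all_censored_warning")
  expect_equal(km_survival_at(cv, c(0, 5, 100)), c(1, 1, 1))
  expect_true(is.na(cv$median))
})

test_that("KM with no censoring equals one minus the empirical CDF", {
  set.seed(91)
  t <- rexp(60, rate = 0.3)
  df <- data.frame(record_id = paste0("r", 1:60), time = t, event = 1L)
  cv <- km_curve(df)
  grid <- sort(t)
  expect_equal(km_survival_at(cv, grid),
               1 - ecdf(t)(grid), tolerance = 1e-12)
  # invariant to record order
  cv2 <- km_curve(df[sample.int(60), ])
  expect_equal(cv2$surv, cv$surv)
})

test_that("doubling one group's hazard lowers its survival curve", {
  truth <- stratification(list(lo = sprintf("a%03d", 1:500),
                               hi = sprintf("b%03d", 1:500)))
  surv <- make_survival(truth, hazards = c(lo = 0.1, hi = 0.2),
                        censor_rate = 0.1, seed = 92)
  res <- survival_by_group(truth, surv)
  shared <- sort(unique(c(res$curves$lo$time, res$curves$hi$time)))
  s_lo <- km_survival_at(res$curves$lo, shared)
  s_hi <- km_survival_at(res$curves$hi, shared)
  expect_true(all(s_hi <= s_lo + 1e-12))
  expect_lt(res$summary$median[res$summary$group == "hi"],
            res$summary$median[res$summary$group == "lo"])
})

test_that("categorical composition counts per group with explicit unknowns", {
  strat <- stratification(list(A = c("r1", "r2", "r3"), B = c("r4", "r5", "r6")))
  cats <- data.frame(record_id = paste0("r", 1:5),
                     stage = c("II", "II", "III", "III", "III"),
                     stringsAsFactors = FALSE)   # r6 missing -> unknown
  M <- categorical_composition(strat, cats, "stage")
  expect_equal(M["A", "II"], 2L)
  expect_equal(M["A", "III"], 1L)
  expect_equal(M["B", "III"], 2L)
  expect_equal(M["B", "unknown"], 1L)
  expect_error(categorical_composition(strat, cats, "nope"),
               class = "param_error")

  one <- data.frame(record_id = paste0("r", 1:6), grade = "x",
                    stringsAsFactors = FALSE)
  M1 <- categorical_composition(strat, one, "grade")
  expect_equal(ncol(M1), 1L)
  expect_equal(sum(M1), 6L)
})
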