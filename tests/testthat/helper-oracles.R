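# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (double loops, direct formulas) and never calls the code
# paths it is used to check.

named_matrix <- function(values, nrow, ncol, prefix = "r") {
  m <- matrix(values, nrow, ncol)
  dimnames(m) <- list(paste0(prefix, seq_len(nrow)), paste0("f", seq_len(ncol)))
  m
}

random_matrix <- function(n, d, seed) {
  set.seed(seed)
  named_matrix(rnorm(n * d), n, d)
}

# random partition of the rows of `mat` into k non-empty named groups
random_strat <- function(mat, k, seed) {
  set.seed(seed)
  n <- nrow(mat)
  repeat {
    lab <- sample.int(k, n, replace = TRUE)
    if (length(unique(lab)) == k) break
  }
  groups <- lapply(seq_len(k), function(j) rownames(mat)[lab == j])
  names(groups) <- paste("Group", seq_len(k) - 1L)
  stratification(groups)
}

# naive reference metrics, written directly from the textbook formulas
naive_metric <- function(a, b, name) {
  switch(name,
    euclidean    = sqrt(sum((a - b)^2)),
    sq_euclidean = sum((a - b)^2),
    manhattan    = sum(abs(a - b)),
    chebyshev    = max(abs(a - b)),
    canberra     = {
      s <- 0
      for (i in seq_along(a)) {
        den <- abs(a[i]) + abs(b[i])
        if (den > 0) s <- s + abs(a[i] - b[i]) / den
      }
      s
    },
    pearson      = sum((a - mean(a)) * (b - mean(b))) /
                   sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
    spearman     = {
      ra <- rank(a); rb <- rank(b)
      sum((ra - mean(ra)) * (rb - mean(rb))) /
        sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    })
}

# double-loop recomputation of within- and between-cluster fits
naive_within_fit <- function(mat, strat, name) {
  out <- numeric(0)
  for (g in names(strat$groups)) {
    ids <- strat$groups[[g]]
    ctr <- colMeans(mat[ids, , drop = FALSE])
    for (id in ids) out[id] <- naive_metric(mat[id, ], ctr, name)
  }
  out
}

naive_between_fit <- function(mat, strat, name) {
  ids <- unlist(strat$groups, use.names = FALSE)
  M <- matrix(NA_real_, length(ids), length(strat$groups),
              dimnames = list(ids, names(strat$groups)))
  lab <- rep(names(strat$groups), lengths(strat$groups))
  names(lab) <- ids
  for (g in names(strat$groups)) {
    ctr <- colMeans(mat[strat$groups[[g]], , drop = FALSE])
    for (id in ids) if (lab[id] != g) M[id, g] <- naive_metric(mat[id, ], ctr, name)
  }
  M
}

# adjusted Rand index straight from the pair-counting contingency formula
naive_ari <- function(labA, labB) {
  M <- table(labA, labB)
  ch2 <- function(x) x * (x - 1) / 2
  n <- sum(M)
  sij <- sum(ch2(M)); sa <- sum(ch2(rowSums(M))); sb <- sum(ch2(colSums(M)))
  e <- sa * sb / ch2(n)
  (sij - e) / ((sa + sb) / 2 - e)
}

# brute-force check that an assignment is a nearest-centroid fixed point
count_fixed_point_moves <- function(mat, strat, metric) {
  lab <- strat_labels(strat)
  centers <- lapply(strat$groups, function(ids)
    colMeans(mat[ids, , drop = FALSE]))
  moves <- 0L
  for (id in names(lab)) {
    d <- vapply(centers, function(c)
      to_dissimilarity(record_distance(mat[id, ], c, metric), metric),
      numeric(1))
    if (names(which.min(d)) != lab[id]) moves <- moves + 1L
  }
  moves
}

expect_same_partition <- function(a, b) {
  keyify <- function(s) {
    sets <- lapply(s$groups, function(g) paste(sort(g), collapse = ","))
    sort(unlist(sets, use.names = FALSE))
  }
  expect_identical(keyify(a), keyify(b))
}
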