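# The four clustering algorithms offered by the tool. All of them speak the
# metric registry via to_dissimilarity(), so distance and correlation metrics
# are interchangeable. Every randomized algorithm is a pure function of its
# seed; the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

group_names <- function(k) paste("Group", seq_len(k) - 1L)

#' k-means clustering with a pluggable metric
#'
#' Lloyd iteration: centroids are arithmetic means; the assignment step uses
#' the chosen metric through the dissimilarity scale, so correlation metrics
#' assign each record to the centroid it correlates with best. Ties go to the
#' lowest cluster index. An emptied cluster is re-seeded from the record
#' farthest from its current centroid, so exactly `k` non-empty groups are
#' returned. Deterministic given `seed`.
#'
#' Note the documented limitation: under non-Euclidean metrics the mean is not
#' the metric's own minimizer, so the result is a nearest-centroid fixed
#' point, not a minimizer of that metric's objective.
#'
#' @param mat Records x features matrix.
#' @param k Number of clusters, 2 <= k <= n.
#' @param metric Metric name or `metric_spec` (default `"euclidean"`).
#' @param seed Integer seed (default 0) controlling the restarts' initial
#'   centroids (k distinct records each).
#' @param max_iter Iteration cap per restart (default 300).
#' @param nstart Number of random restarts (default 25); the restart with the
#'   smallest total within-cluster dissimilarity wins.
#' @return A [stratification()] with groups "Group 0", "Group 1", ...
#' @export
run_kmeans <- function(mat, k, metric = "euclidean", seed = 0L, max_iter = 300L,
                       nstart = 25L) {
  mat <- as_data_matrix(mat)
  n <- nrow(mat)
  if (!is.numeric(k) || length(k) != 1L || k < 2L || k > n)
    stop_param(sprintf("k must satisfy 2 <= k <= n records (k=%s, n=%d)", k, n))
  k <- as.integer(k)
  inits <- with_seed(seed, lapply(seq_len(max(1L, nstart)), function(i)
    sample.int(n, k)))
  best <- NULL
  for (init in inits) {
    fit <- .kmeans_once(mat, k, metric, init, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  groups <- lapply(seq_len(k), function(j) rownames(mat)[best$assign == j])
  names(groups) <- group_names(k)
  stratification(groups, provenance = sprintf(
    "kmeans(k=%d, metric=%s, seed=%d, nstart=%d)",
    k, metric_spec(metric)$name, as.integer(seed), max(1L, nstart)))
}

.kmeans_once <- function(mat, k, metric, init, max_iter) {
  n <- nrow(mat)
  centers <- mat[init, , drop = FALSE]
  assign <- rep(NA_integer_, n)
  D <- NULL
  for (iter in seq_len(max_iter)) {
    D <- vapply(seq_len(k), function(j)
      dissim_to_centroid(mat, centers[j, ], metric), numeric(n))
    if (n == 1L) D <- matrix(D, nrow = 1L)
    new_assign <- max.col(-D, ties.method = "first")
    # re-seed emptied clusters from the farthest record
    for (j in setdiff(seq_len(k), unique(new_assign))) {
      own <- D[cbind(seq_len(n), new_assign)]
      far <- which.max(own)
      new_assign[far] <- j
      centers[j, ] <- mat[far, ]
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k))
      centers[j, ] <- centroid(mat[assign == j, , drop = FALSE])
  }
  list(assign = assign,
       objective = sum(D[cbind(seq_len(n), assign)]))
}

#' Agglomerative hierarchical clustering
#'
#' Builds the merge tree with [stats::hclust()] on the pairwise dissimilarity
#' matrix induced by `metric`. Ward linkage requires Euclidean geometry and is
#' rejected for any other metric.
#'
#' @param mat Records x features matrix.
#' @param linkage One of `"single"`, `"complete"`, `"average"`, `"ward"`.
#' @param metric Metric name or `metric_spec`.
#' @return A `linkage_tree`: the hclust merge sequence plus leaf ids.
#' @export
run_hierarchical <- function(mat, linkage = "average", metric = "euclidean") {
  mat <- as_data_matrix(mat)
  linkage <- match.arg(linkage, c("single", "complete", "average", "ward"))
  m <- metric_spec(metric)
  if (linkage == "ward" && m$name != "euclidean")
    stop_param("ward linkage requires the euclidean metric")
  D <- stats::as.dist(pairwise_dissimilarity(mat, m))
  hc <- stats::hclust(D, method = if (linkage == "ward") "ward.D2" else linkage)
  structure(list(hclust = hc, leaf_ids = rownames(mat), linkage = linkage,
                 metric = m$name),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat("Linkage tree:", length(x$leaf_ids), "leaves,", x$linkage,
      "linkage,", x$metric, "metric\n")
  invisible(x)
}

#' Cut a linkage tree into discrete clusters
#'
#' Cut either into exactly `k` groups or at a merge height `h` (groups are the
#' connected components whose merges happened at heights <= `h`).
#'
#' @param tree A `linkage_tree` from [run_hierarchical()].
#' @param k Number of groups (1 <= k <= n), or `NULL`.
#' @param h Cut height, or `NULL`. Exactly one of `k`/`h` must be given.
#' @return A [stratification()]; group order follows first appearance in the
#'   leaf order of the input matrix.
#' @export
cut_tree <- function(tree, k = NULL, h = NULL) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- length(tree$leaf_ids)
  if (is.null(k) == is.null(h))
    stop_param("give exactly one of k or h")
  if (!is.null(k) && (k < 1L || k > n))
    stop_param(sprintf("k must satisfy 1 <= k <= %d", n))
  cl <- if (!is.null(k)) stats::cutree(tree$hclust, k = k)
        else stats::cutree(tree$hclust, h = h)
  ids <- tree$leaf_ids
  lev <- unique(cl[ids])               # first-appearance order
  groups <- lapply(lev, function(g) ids[cl[ids] == g])
  names(groups) <- group_names(length(lev))
  stratification(groups, provenance = sprintf(
    "hierarchical(linkage=%s, metric=%s, cut=%s)", tree$linkage, tree$metric,
    if (!is.null(k)) paste0("k=", k) else paste0("h=", h)))
}

#' Affinity propagation clustering
#'
#' Message passing between records over the similarity matrix
#' `s = -to_dissimilarity(metric)`. The number of clusters is not fixed by the
#' user; it emerges from the shared `preference` (self-similarity), which
#' defaults to the median off-diagonal similarity. Every group contains its
#' exemplar record. If the exemplar set has not stabilized after `max_iter`
#' sweeps, a convergence warning is emitted and the best current result is
#' returned.
#'
#' @param mat Records x features matrix.
#' @param preference Self-similarity; default median off-diagonal similarity.
#' @param damping Update damping in \[0.5, 1), default 0.9.
#' @param metric Metric name or `metric_spec`.
#' @param max_iter Sweep cap (default 300).
#' @param conv_iter Sweeps of unchanged exemplars counted as convergence
#'   (default 20).
#' @return A [stratification()]; each group's exemplar is recorded in the
#'   `exemplars` attribute.
#' @export
run_affinity_propagation <- function(mat, preference = NULL, damping = 0.9,
                                     metric = "euclidean", max_iter = 300L,
                                     conv_iter = 20L) {
  mat <- as_data_matrix(mat)
  if (damping < 0.5 || damping >= 1) stop_param("damping must lie in [0.5, 1)")
  n <- nrow(mat)
  if (n == 1L) {
    out <- stratification(stats::setNames(list(rownames(mat)), group_names(1L)),
                          provenance = "affinity_propagation(n=1)")
    attr(out, "exemplars") <- rownames(mat)
    return(out)
  }
  S <- -pairwise_dissimilarity(mat, metric)
  if (is.null(preference)) preference <- stats::median(S[row(S) != col(S)])
  diag(S) <- preference
  # tiny deterministic jitter breaks exact ties without a random source
  S <- S + S * 1e-12 * outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 7 - 3)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L; last_ex <- integer(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS, 1L, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0); diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, last_ex) && length(ex) > 0L) stable <- stable + 1L
    else { stable <- 0L; last_ex <- ex }
    if (stable >= conv_iter) { converged <- TRUE; break }
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (length(ex) == 0L) ex <- which.max(diag(R) + diag(A))
  if (!converged)
    warn_stratkit("convergence_warning", sprintf(
      "affinity propagation did not converge in %d iterations; returning best-so-far",
      max_iter))
  assign <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign[ex] <- ex                      # exemplars belong to their own group
  keep <- sort(unique(assign))
  groups <- lapply(keep, function(e) rownames(mat)[assign == e])
  names(groups) <- group_names(length(keep))
  out <- stratification(groups, provenance = sprintf(
    "affinity_propagation(preference=%.6g, damping=%.3g, metric=%s)",
    preference, damping, metric_spec(metric)$name))
  attr(out, "exemplars") <- stats::setNames(rownames(mat)[keep], names(groups))
  out
}

#' Fuzzy c-means clustering
#'
#' Standard alternating optimisation of the fuzzy c-means objective
#' `J = sum_ij u_ij^m d(x_i, v_j)^2` with Euclidean geometry: membership
#' update `u_ij = 1 / sum_k (d_ij/d_ik)^(2/(m-1))`, centroid update
#' `v_j = sum_i u_ij^m x_i / sum_i u_ij^m`. Rows of the membership matrix sum
#' to 1 at every iteration. A record coincident with a centroid gets crisp
#' membership 1 there. Initialisation draws a random row-stochastic membership
#' matrix from `seed` (initialising centroids at data records instead locks
#' their crisp memberships in place at high fuzziness); the run is fully
#' deterministic given the seed.
#'
#' @param mat Records x features matrix.
#' @param k Number of clusters (>= 2).
#' @param m Fuzziness factor, > 1 (default 2). As `m` grows, memberships
#'   approach the uniform `1/k`.
#' @param seed Integer seed (default 0).
#' @param max_iter Iteration cap (default 300).
#' @param tol Convergence tolerance on the max membership change
#'   (default 1e-6).
#' @return A [fuzzy_membership()] with default threshold `1/k`. The per-
#'   iteration objective values and max row-sum errors are kept in the
#'   `objective_trace` and `rowsum_error_trace` attributes.
#' @export
run_fuzzy_cmeans <- function(mat, k, m = 2, seed = 0L, max_iter = 300L,
                             tol = 1e-6) {
  mat <- as_data_matrix(mat)
  n <- nrow(mat)
  if (!is.numeric(k) || k < 2L || k > n) stop_param("k must satisfy 2 <= k <= n")
  if (m <= 1) stop_param("fuzziness m must be > 1")
  k <- as.integer(k)
  U <- with_seed(seed, {
    u <- matrix(stats::runif(n * k), n, k)
    u / rowSums(u)
  })
  obj_trace <- numeric(0); rs_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    Um <- U^m
    centers <- (t(Um) %*% mat) / colSums(Um)
    Unew <- .fcm_memberships(mat, centers, m)
    D2 <- .sqdist_to_centers(mat, centers)
    obj_trace <- c(obj_trace, sum(Unew^m * D2))
    rs_trace <- c(rs_trace, max(abs(rowSums(Unew) - 1)))
    delta <- max(abs(Unew - U))
    U <- Unew
    if (delta < tol) break
  }
  dimnames(U) <- list(rownames(mat), group_names(k))
  out <- fuzzy_membership(U, threshold = 1 / k)
  attr(out, "objective_trace") <- obj_trace
  attr(out, "rowsum_error_trace") <- rs_trace
  attr(out, "centers") <- centers
  out$provenance <- sprintf("fuzzy_cmeans(k=%d, m=%g, seed=%d)", k, m, as.integer(seed))
  out
}

.sqdist_to_centers <- function(mat, centers) {
  vapply(seq_len(nrow(centers)), function(j)
    rowSums(sweep(mat, 2L, centers[j, ])^2), numeric(nrow(mat)))
}

.fcm_memberships <- function(mat, centers, m) {
  D2 <- .sqdist_to_centers(mat, centers)
  if (nrow(mat) == 1L) D2 <- matrix(D2, nrow = 1L)
  U <- matrix(0, nrow(mat), nrow(centers))
  zero <- D2 == 0
  coincident <- rowSums(zero) > 0L
  # crisp membership at the (first) exactly coincident centroid
  if (any(coincident)) {
    first <- apply(zero[coincident, , drop = FALSE], 1L, which.max)
    U[cbind(which(coincident), first)] <- 1
  }
  reg <- which(!coincident)
  if (length(reg) > 0L) {
    # factor out the row minimum so the power never overflows
    Dn <- D2[reg, , drop = FALSE]
    Dn <- Dn / apply(Dn, 1L, min)
    P <- Dn^(-1 / (m - 1))
    U[reg, ] <- P / rowSums(P)
  }
  U
}
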