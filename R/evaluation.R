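# The two evaluation surfaces: per-record fit to the own-cluster centroid
# (the bar-chart "distance view") and fit to every other cluster's centroid
# (the between-cluster matrix with empty diagonal blocks). Sorting is always
# best-fit-first: ascending for dissimilarity metrics, descending for
# correlations ("long bars" mean high similarity there).

#' Within-cluster fit of every record to its own group's centroid
#'
#' @param mat Records x features matrix.
#' @param strat A [stratification()] covering a subset of the matrix rows.
#' @param metric Metric name or `metric_spec`.
#' @return A `fit_profile`: per-record `fit` values on the metric's own scale,
#'   the per-record `group`, per-group best-fit-first orderings (`order`), and
#'   `global_scale_max`, the largest fit magnitude across the run — the value
#'   all bars are scaled against. Scales are computed per metric orientation;
#'   similarity and dissimilarity views never share one.
#' @export
within_cluster_fit <- function(mat, strat, metric = "euclidean") {
  mat <- as_data_matrix(mat)
  stopifnot(inherits(strat, "stratification"))
  m <- metric_spec(metric)
  .check_known(strat_records(strat), mat)
  fits <- numeric(0)
  ord <- list()
  for (g in names(strat$groups)) {
    ids <- strat$groups[[g]]
    ctr <- centroid(mat[ids, , drop = FALSE])
    f <- fit_to_centroid(mat[ids, , drop = FALSE], ctr, m)
    names(f) <- ids
    fits <- c(fits, f)
    ord[[g]] <- ids[order(to_dissimilarity(f, m), seq_along(f))]
  }
  structure(list(fit = fits, group = strat_labels(strat), metric = m,
                 order = ord,
                 global_scale_max = max(abs(fits))),
            class = "fit_profile")
}

#' @export
print.fit_profile <- function(x, ...) {
  cat("Within-cluster fit (", x$metric$name, ", ", x$metric$orientation,
      "): ", length(x$fit), " record(s), ", length(x$order), " group(s)\n",
      sep = "")
  cat("global scale max:", format(x$global_scale_max, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.fit_profile <- function(object, ...) {
  data.frame(
    group = names(object$order),
    n = lengths(object$order),
    mean_fit = vapply(names(object$order), function(g)
      mean(object$fit[names(object$group)[object$group == g]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Within-cluster fit as a sorted table
#'
#' @param profile A `fit_profile`.
#' @return `data.frame` (record_id, group, fit, rank) with rank 1 = best fit
#'   within its group.
#' @export
fit_table <- function(profile) {
  stopifnot(inherits(profile, "fit_profile"))
  rows <- lapply(names(profile$order), function(g) {
    ids <- profile$order[[g]]
    data.frame(record_id = ids, group = g, fit = unname(profile$fit[ids]),
               rank = seq_along(ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit of every record to every other group's centroid
#'
#' Cells where the column group is the record's own group are masked (`NA`),
#' mirroring the empty diagonal blocks of the between-cluster matrix view.
#'
#' @inheritParams within_cluster_fit
#' @return A `between_fit`: records x groups `fit` matrix with own-group cells
#'   `NA`, plus the per-record `group` vector and the metric.
#' @export
between_cluster_fit <- function(mat, strat, metric = "euclidean") {
  mat <- as_data_matrix(mat)
  stopifnot(inherits(strat, "stratification"))
  if (length(strat$groups) < 2L)
    stop_stratkit("single_cluster_error",
                  "between-cluster fit needs at least two groups")
  m <- metric_spec(metric)
  ids <- strat_records(strat)
  .check_known(ids, mat)
  sub <- mat[ids, , drop = FALSE]
  F <- vapply(names(strat$groups), function(g) {
    ctr <- centroid(mat[strat$groups[[g]], , drop = FALSE])
    fit_to_centroid(sub, ctr, m)
  }, numeric(length(ids)))
  if (length(ids) == 1L) F <- matrix(F, nrow = 1L)
  dimnames(F) <- list(ids, names(strat$groups))
  lab <- strat_labels(strat)
  F[cbind(ids, lab[ids])] <- NA_real_
  structure(list(fit = F, group = lab, metric = m), class = "between_fit")
}

#' @export
print.between_fit <- function(x, ...) {
  cat("Between-cluster fit (", x$metric$name, "): ",
      nrow(x$fit), " record(s) x ", ncol(x$fit),
      " group(s); own-group cells masked\n", sep = "")
  invisible(x)
}

#' Order records by their fit to one column of the between-cluster matrix
#'
#' @param bf A `between_fit`.
#' @param column Group name to sort by.
#' @return Record ids, best fit to that group's centroid first; the record's
#'   own-group (masked) rows sort last.
#' @export
sort_by_column <- function(bf, column) {
  stopifnot(inherits(bf, "between_fit"))
  if (!column %in% colnames(bf$fit)) stop_param(paste0("unknown group: ", column))
  v <- to_dissimilarity(bf$fit[, column], bf$metric)
  rownames(bf$fit)[order(v, na.last = TRUE)]
}

#' Default split thresholds: the second and third quartile of a group's fits
#'
#' Quartiles use linear interpolation between order statistics at positions
#' `(n - 1) * q` (the common default convention, [stats::quantile()] type 7).
#' For similarity metrics the distribution is mirrored: the thresholds are the
#' first and second quartile, so "good" is again the best half and "bad" the
#' worst quarter.
#'
#' @param profile A `fit_profile`.
#' @param group Group name.
#' @return A `split_spec`: thresholds `t1 <= t2` on the metric's fit scale
#'   plus the metric orientation.
#' @export
default_split_thresholds <- function(profile, group) {
  stopifnot(inherits(profile, "fit_profile"))
  if (!group %in% names(profile$order)) stop_param(paste0("unknown group: ", group))
  ids <- profile$order[[group]]
  if (length(ids) < 2L) stop_param("default thresholds need a group with >= 2 records")
  f <- unname(profile$fit[ids])
  if (is_similarity(profile$metric)) {
    q <- stats::quantile(f, c(0.25, 0.5), type = 7, names = FALSE)
    split_spec(q[1L], q[2L], orientation = "similarity")
  } else {
    q <- stats::quantile(f, c(0.5, 0.75), type = 7, names = FALSE)
    split_spec(q[1L], q[2L], orientation = "dissimilarity")
  }
}

#' Construct a split specification
#'
#' Two thresholds on fit values classify a group's records into good /
#' ambiguous / bad regions. For dissimilarity metrics: good `fit <= t1`,
#' ambiguous `t1 < fit <= t2`, bad `fit > t2`. For similarity metrics the
#' inequalities are reversed (good `fit >= t2`, bad `fit < t1`); ties always
#' fall into the better region.
#'
#' @param t1,t2 Thresholds with `t1 <= t2`.
#' @param orientation `"dissimilarity"` or `"similarity"` — the scale the
#'   thresholds live on.
#' @return A `split_spec`.
#' @export
split_spec <- function(t1, t2, orientation = "dissimilarity") {
  if (!is.numeric(t1) || !is.numeric(t2) || t1 > t2)
    stop_param("split thresholds must be numeric with t1 <= t2")
  orientation <- match.arg(orientation, c("dissimilarity", "similarity"))
  structure(list(t1 = t1, t2 = t2, orientation = orientation),
            class = "split_spec")
}

#' Fuzzy membership view under a display threshold
#'
#' A record is displayed as a member of every cluster whose weight reaches the
#' threshold (inclusive: `u >= tau`). Records reaching it in two or more
#' clusters are flagged shared (the purple highlight); single-cluster records
#' are unique (green). A record whose largest weight is below the threshold is
#' assigned to its argmax cluster and flagged low-confidence.
#'
#' @param membership A [fuzzy_membership()].
#' @param tau Display threshold in (0, 1\]; defaults to the membership's own.
#' @return List with `members` (record ids per cluster), `shared` and
#'   `low_confidence` (named logicals per record), and `tau`.
#' @export
membership_view <- function(membership, tau = NULL) {
  stopifnot(inherits(membership, "fuzzy_membership"))
  if (is.null(tau)) tau <- membership$threshold
  if (!is.numeric(tau) || tau <= 0 || tau > 1) stop_param("tau must lie in (0, 1]")
  U <- membership$weights
  hit <- U >= tau
  low <- rowSums(hit) == 0L
  if (any(low)) {
    am <- apply(U[low, , drop = FALSE], 1L, which.max)
    hit[cbind(which(low), am)] <- TRUE
  }
  members <- lapply(seq_len(ncol(U)), function(j) rownames(U)[hit[, j]])
  names(members) <- colnames(U)
  list(members = members,
       shared = stats::setNames(rowSums(hit) >= 2L, rownames(U)),
       low_confidence = stats::setNames(low, rownames(U)),
       tau = tau)
}
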