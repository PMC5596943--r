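# The four refinement operators — split, shift, merge, exclude — as pure
# stratification transformations. Each returns a refinement_result whose
# constructor enforces conservation: the multiset of record ids across the new
# groups plus the excluded pool equals the input's.

refinement_result <- function(strat, excluded, log, before_ids) {
  after <- c(strat_records(strat), excluded)
  if (!identical(sort(after), sort(before_ids)))
    stop_stratkit("conservation_error",
                  "internal error: refinement lost or duplicated records")
  structure(list(stratification = strat, excluded = excluded, log = log),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("Refinement:", x$log$op, "\n")
  print(x$stratification)
  if (length(x$excluded) > 0L)
    cat("Excluded pool:", length(x$excluded), "record(s)\n")
  invisible(x)
}

#' Stratification held by a refinement result
#' @param result A `refinement_result`.
#' @return The contained [stratification()].
#' @export
result_strat <- function(result) {
  stopifnot(inherits(result, "refinement_result"))
  result$stratification
}

.as_strat <- function(x) {
  if (inherits(x, "refinement_result")) x$stratification else x
}
.pool_of <- function(x, pool) {
  if (inherits(x, "refinement_result")) c(x$excluded, pool) else pool
}

#' Split a group into good / ambiguous / bad regions by fit thresholds
#'
#' The group's records are classified by their within-cluster fit against the
#' two thresholds of a [split_spec()] (good: `fit <= t1`; ambiguous:
#' `t1 < fit <= t2`; bad: `fit > t2`; inequalities reversed for similarity
#' metrics). Empty regions are dropped. The new groups are first-class: any
#' subsequent fit view uses their own centroids.
#'
#' @param mat Records x features matrix.
#' @param strat A [stratification()] or `refinement_result`.
#' @param group Name of the group to split.
#' @param spec A [split_spec()]; `NULL` uses [default_split_thresholds()].
#' @param metric Metric name or `metric_spec`.
#' @param pool Excluded-record pool carried alongside the stratification.
#' @return A `refinement_result`.
#' @export
split_cluster <- function(mat, strat, group, spec = NULL, metric = "euclidean",
                          pool = character()) {
  pool <- .pool_of(strat, pool); strat <- .as_strat(strat)
  if (!group %in% names(strat$groups))
    stop_stratkit("unknown_record_error", paste0("unknown group: ", group))
  profile <- within_cluster_fit(mat, strat, metric)
  if (is.null(spec)) spec <- default_split_thresholds(profile, group)
  ids <- strat$groups[[group]]
  fits <- profile$fit[ids]
  split_by_values(strat, group, fits, spec, pool = pool,
                  op = sprintf("split(%s, metric=%s)", group,
                               metric_spec(metric)$name))
}

#' Split a group by arbitrary per-record values (e.g. fuzzy memberships)
#'
#' The core region rule behind [split_cluster()]. For fuzzy clusterings pass
#' the group's membership weights with a similarity-oriented spec: high
#' weights are good.
#'
#' @param strat A [stratification()].
#' @param group Group to split.
#' @param values Named numeric vector, one value per record of the group.
#' @param spec A [split_spec()].
#' @param pool Excluded pool to carry through.
#' @param op Log label.
#' @return A `refinement_result`.
#' @export
split_by_values <- function(strat, group, values, spec, pool = character(),
                            op = paste0("split(", group, ")")) {
  stopifnot(inherits(strat, "stratification"), inherits(spec, "split_spec"))
  if (!group %in% names(strat$groups))
    stop_stratkit("unknown_record_error", paste0("unknown group: ", group))
  ids <- strat$groups[[group]]
  if (!all(ids %in% names(values)))
    stop_param("'values' must cover every record of the group")
  v <- values[ids]
  if (spec$orientation == "similarity") {
    region <- ifelse(v >= spec$t2, "good", ifelse(v >= spec$t1, "ambiguous", "bad"))
  } else {
    region <- ifelse(v <= spec$t1, "good", ifelse(v <= spec$t2, "ambiguous", "bad"))
  }
  before <- c(strat_records(strat), pool)
  pieces <- lapply(c("good", "ambiguous", "bad"), function(r) ids[region == r])
  names(pieces) <- paste0(group, " (", c("good", "ambiguous", "bad"), ")")
  pieces <- pieces[lengths(pieces) > 0L]
  groups <- strat$groups
  at <- match(group, names(groups))
  groups <- append(groups[-at], pieces, after = at - 1L)
  new_strat <- stratification(groups, provenance = strat$provenance)
  refinement_result(new_strat, pool,
                    list(op = op, params = list(t1 = spec$t1, t2 = spec$t2,
                                                orientation = spec$orientation),
                         groups = names(pieces)),
                    before)
}

#' Shift records to their nearest cluster centroid
#'
#' Iterates k-means-style: recompute every group's centroid, then reassign
#' each record in scope to the group whose centroid is nearest under the
#' metric's dissimilarity scale, until no record moves or `max_iter` is
#' reached. Shifting uses the same metric that produced the stratification.
#' Groups emptied by the moves are dropped and logged. The returned assignment
#' is a nearest-centroid fixed point. Monotone decrease of the total
#' within-cluster dissimilarity across iterations is guaranteed under
#' `sq_euclidean` (the Lloyd objective this iteration minimizes); under other
#' metrics the arithmetic-mean centroid update can let the total wobble
#' transiently, and the iteration is capped by `max_iter`.
#'
#' @param mat Records x features matrix.
#' @param strat A [stratification()] or `refinement_result`.
#' @param metric Metric name or `metric_spec`.
#' @param scope Character vector of group names whose records may move;
#'   `NULL` (default) means all records. Records outside scope keep their
#'   group but still contribute to centroids.
#' @param max_iter Iteration cap, default 100.
#' @param pool Excluded pool to carry through.
#' @return A `refinement_result`; the per-iteration objective is in
#'   `log$objective_trace` and the move count in `log$moves`.
#' @export
shift_records <- function(mat, strat, metric = "euclidean", scope = NULL,
                          max_iter = 100L, pool = character()) {
  pool <- .pool_of(strat, pool); strat <- .as_strat(strat)
  mat <- as_data_matrix(mat)
  if (length(strat$groups) < 2L)
    stop_stratkit("single_cluster_error", "shifting needs at least two groups")
  if (is.null(scope)) scope <- names(strat$groups)
  if (!all(scope %in% names(strat$groups)))
    stop_param("scope names unknown groups")
  gnames <- names(strat$groups)
  lab <- strat_labels(strat)
  ids <- names(lab)
  movable <- lab %in% scope
  sub <- mat[ids, , drop = FALSE]
  assign <- match(lab, gnames)
  before <- c(ids, pool)
  obj_trace <- numeric(0)
  moves <- 0L
  dropped <- character(0)
  for (iter in seq_len(max_iter)) {
    centers <- lapply(seq_along(gnames), function(j) {
      if (any(assign == j)) centroid(sub[assign == j, , drop = FALSE]) else NULL
    })
    live <- which(!vapply(centers, is.null, logical(1)))
    D <- vapply(live, function(j)
      dissim_to_centroid(sub, centers[[j]], metric), numeric(length(ids)))
    if (length(ids) == 1L) D <- matrix(D, nrow = 1L)
    nearest <- live[max.col(-D, ties.method = "first")]
    new_assign <- assign
    new_assign[movable] <- nearest[movable]
    obj_trace <- c(obj_trace,
                   sum(D[cbind(seq_along(ids), match(new_assign, live))]))
    changed <- sum(new_assign != assign)
    moves <- moves + changed
    assign <- new_assign
    if (changed == 0L) break
  }
  kept <- gnames[gnames %in% gnames[unique(assign)]]
  dropped <- setdiff(gnames, kept)
  groups <- lapply(kept, function(g) ids[assign == match(g, gnames)])
  names(groups) <- kept
  new_strat <- stratification(groups, provenance = strat$provenance)
  refinement_result(new_strat, pool,
                    list(op = sprintf("shift(metric=%s)", metric_spec(metric)$name),
                         params = list(scope = scope, max_iter = max_iter),
                         groups = kept, dropped = dropped, moves = moves,
                         objective_trace = obj_trace),
                    before)
}

#' Merge two or more groups into one
#'
#' Membership is concatenated in group order, then original record order.
#' Merging is associative on record sets.
#'
#' @param strat A [stratification()] or `refinement_result`.
#' @param groups Two or more group names to merge.
#' @param new_name Name of the merged group (default: names joined by " + ").
#' @param pool Excluded pool to carry through.
#' @return A `refinement_result`.
#' @export
merge_clusters <- function(strat, groups, new_name = NULL, pool = character()) {
  pool <- .pool_of(strat, pool); strat <- .as_strat(strat)
  groups <- unique(as.character(groups))
  if (length(groups) < 2L) stop_param("merging needs at least two distinct groups")
  missing <- setdiff(groups, names(strat$groups))
  if (length(missing) > 0L)
    stop_stratkit("unknown_record_error",
                  paste0("unknown group(s): ", paste(missing, collapse = ", ")))
  if (is.null(new_name)) new_name <- paste(groups, collapse = " + ")
  before <- c(strat_records(strat), pool)
  merged <- unlist(strat$groups[groups], use.names = FALSE)
  keep <- strat$groups[setdiff(names(strat$groups), groups)]
  at <- match(groups[1L], names(strat$groups))
  n_before <- sum(match(names(strat$groups), names(strat$groups)) < at &
                  !(names(strat$groups) %in% groups))
  out <- append(keep, stats::setNames(list(merged), new_name), after = n_before)
  new_strat <- stratification(out, provenance = strat$provenance)
  refinement_result(new_strat, pool,
                    list(op = "merge", params = list(groups = groups,
                                                     new_name = new_name),
                         groups = new_name),
                    before)
}

#' Exclude groups or individual records into a recoverable pool
#'
#' Excluded records stop contributing to centroids, fit views and overlap
#' counts, but remain in the pool of the returned result and can be restored
#' with [include_records()].
#'
#' @param strat A [stratification()] or `refinement_result`.
#' @param groups Group names to exclude entirely, or `NULL`.
#' @param records Individual record ids to exclude, or `NULL`.
#' @param pool Existing excluded pool to extend.
#' @return A `refinement_result`.
#' @export
exclude_records <- function(strat, groups = NULL, records = NULL,
                            pool = character()) {
  pool <- .pool_of(strat, pool); strat <- .as_strat(strat)
  if (is.null(groups) && is.null(records))
    stop_param("name groups or records to exclude")
  if (!is.null(groups)) {
    missing <- setdiff(groups, names(strat$groups))
    if (length(missing) > 0L)
      stop_stratkit("unknown_record_error",
                    paste0("unknown group(s): ", paste(missing, collapse = ", ")))
  }
  all_ids <- strat_records(strat)
  if (!is.null(records)) {
    missing <- setdiff(records, all_ids)
    if (length(missing) > 0L)
      stop_stratkit("unknown_record_error",
                    paste0("unknown record(s): ", paste(utils::head(missing, 5L),
                                                        collapse = ", ")))
  }
  drop_ids <- unique(c(unlist(strat$groups[groups], use.names = FALSE),
                       records))
  before <- c(all_ids, pool)
  new_groups <- lapply(strat$groups, function(g) setdiff(g, drop_ids))
  emptied <- names(new_groups)[lengths(new_groups) == 0L]
  new_groups <- new_groups[lengths(new_groups) > 0L]
  if (length(new_groups) == 0L)
    stop_param("exclusion would empty the whole stratification")
  new_strat <- stratification(new_groups, provenance = strat$provenance)
  refinement_result(new_strat, c(pool, drop_ids),
                    list(op = "exclude",
                         params = list(groups = groups, records = records),
                         groups = emptied, n_excluded = length(drop_ids)),
                    before)
}

#' Restore excluded records from the pool into a named group
#'
#' @param result A `refinement_result` with a non-empty pool.
#' @param assignment Named character vector: record id -> group to restore it
#'   into (new group names are created as needed). Default restores every
#'   pooled record into the group named by the `into` argument.
#' @param into Single group name used when `assignment` is `NULL`.
#' @return A `refinement_result` with the records moved back.
#' @export
include_records <- function(result, assignment = NULL, into = NULL) {
  stopifnot(inherits(result, "refinement_result"))
  pool <- result$excluded
  if (length(pool) == 0L) stop_param("the excluded pool is empty")
  strat <- result$stratification
  if (is.null(assignment)) {
    if (is.null(into)) stop_param("give 'assignment' or 'into'")
    assignment <- stats::setNames(rep(into, length(pool)), pool)
  }
  if (!all(names(assignment) %in% pool))
    stop_stratkit("unknown_record_error", "assignment names records not in the pool")
  before <- c(strat_records(strat), pool)
  groups <- strat$groups
  for (g in unique(assignment)) {
    ids <- names(assignment)[assignment == g]
    groups[[g]] <- c(groups[[g]], ids)
  }
  new_strat <- stratification(groups, provenance = strat$provenance)
  refinement_result(new_strat, setdiff(pool, names(assignment)),
                    list(op = "include", params = list(n = length(assignment)),
                         groups = unique(unname(assignment))),
                    before)
}
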