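#' Construct a stratification
#'
#' A stratification is an ordered set of named, pairwise-disjoint groups of
#' record identifiers — a partition of (a subset of) the rows of a data
#' matrix, such as patient clusters or clinical subtypes.
#'
#' @param groups Named list of character vectors of record ids. Group order
#'   and within-group record order are preserved.
#' @param provenance Free-text note on how the stratification was produced
#'   (algorithm and parameters, or `"manual"`).
#' @return An object of class `stratification`.
#' @export
stratification <- function(groups, provenance = "manual") {
  if (!is.list(groups) || length(groups) == 0L)
    stop_param("'groups' must be a non-empty named list of record id vectors")
  nm <- names(groups)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop_param("group names must be unique non-empty strings")
  groups <- lapply(groups, as.character)
  sizes <- lengths(groups)
  if (any(sizes == 0L))
    stop_stratkit("empty_cluster_error",
                  paste0("empty group(s): ", paste(nm[sizes == 0L], collapse = ", ")))
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids))
    stop_stratkit("duplicate_id_error",
                  paste0("record(s) in more than one group: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  structure(list(groups = groups, provenance = provenance),
            class = "stratification")
}

#' Record ids covered by a stratification, in group-then-record order
#' @param strat A `stratification`.
#' @return Character vector of record ids.
#' @export
strat_records <- function(strat) {
  stopifnot(inherits(strat, "stratification"))
  unlist(strat$groups, use.names = FALSE)
}

#' Group labels of a stratification, one per record
#'
#' @param strat A `stratification`.
#' @return Named character vector mapping record id to group name.
#' @export
strat_labels <- function(strat) {
  stopifnot(inherits(strat, "stratification"))
  lab <- rep(names(strat$groups), lengths(strat$groups))
  names(lab) <- strat_records(strat)
  lab
}

#' @export
print.stratification <- function(x, ...) {
  cat("Stratification:", length(x$groups), "group(s),",
      length(strat_records(x)), "record(s)\n")
  cat("Provenance:", x$provenance, "\n")
  for (g in names(x$groups))
    cat(sprintf("  %-12s n=%d\n", g, length(x$groups[[g]])))
  invisible(x)
}

#' @export
summary.stratification <- function(object, ...) {
  data.frame(group = names(object$groups),
             size = lengths(object$groups),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a fuzzy membership
#'
#' Records-by-clusters weight matrix from a fuzzy clustering: each weight is
#' in \[0, 1\] and every row sums to 1 (within 1e-9). `threshold` is the
#' default display threshold above which a record counts as a member of a
#' cluster.
#'
#' @param weights Numeric matrix, rows named by record id, columns by cluster.
#' @param threshold Default display threshold in (0, 1\]; defaults to `1/k`
#'   (chance level for `k` clusters).
#' @return An object of class `fuzzy_membership`.
#' @export
fuzzy_membership <- function(weights, threshold = 1 / ncol(weights)) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop_param("'weights' must be a numeric matrix")
  if (is.null(rownames(weights)) || is.null(colnames(weights)))
    stop_param("'weights' must have record row names and cluster column names")
  if (anyDuplicated(rownames(weights)))
    stop_stratkit("duplicate_id_error", "duplicate record ids in membership")
  if (any(weights < -1e-12 | weights > 1 + 1e-12))
    stop_stratkit("membership_range_error",
                  "membership weights must lie in [0, 1]")
  weights[weights < 0] <- 0
  weights[weights > 1] <- 1
  rs <- rowSums(weights)
  if (any(abs(rs - 1) > 1e-9))
    stop_stratkit("membership_range_error",
                  "membership rows must sum to 1 (within 1e-9)")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop_param("'threshold' must lie in (0, 1]")
  structure(list(weights = weights, threshold = threshold),
            class = "fuzzy_membership")
}

#' @export
print.fuzzy_membership <- function(x, ...) {
  cat("Fuzzy membership:", nrow(x$weights), "record(s) x",
      ncol(x$weights), "cluster(s); display threshold",
      format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Harden a fuzzy membership into a crisp stratification by argmax weight
#'
#' Ties go to the lowest cluster index.
#'
#' @param membership A `fuzzy_membership`.
#' @return A `stratification` with one group per cluster that received at
#'   least one record.
#' @export
harden_membership <- function(membership) {
  stopifnot(inherits(membership, "fuzzy_membership"))
  U <- membership$weights
  idx <- apply(U, 1L, which.max)  # which.max takes the first (lowest) tie
  groups <- lapply(seq_len(ncol(U)), function(j) rownames(U)[idx == j])
  names(groups) <- colnames(U)
  stratification(groups[lengths(groups) > 0L], provenance = "argmax of fuzzy membership")
}
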