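# Stratification-vs-stratification comparison (the ribbon semantics: shared
# record counts between groups of two stratifications) and per-group context
# summaries: Kaplan-Meier survival and categorical composition.

#' Shared-record counts between the groups of two stratifications
#'
#' Cell (i, j) is the number of records in group i of `stratA` and group j of
#' `stratB`, counted over the records present in both stratifications — the
#' width of the ribbon that would connect the two groups. Records present in
#' only one stratification are excluded from the universe.
#'
#' @param stratA,stratB [stratification()] objects sharing >= 1 record. Fuzzy
#'   memberships are rejected: overlap counts are undefined when a record can
#'   sit in several groups at once.
#' @return Integer matrix (groups of A x groups of B) with the shared-record
#'   universe size in attribute `universe_size`.
#' @export
overlap_matrix <- function(stratA, stratB) {
  for (s in list(stratA, stratB))
    if (inherits(s, "fuzzy_membership"))
      stop_param(paste("fuzzy clusterings cannot be compared by overlap counts;",
                       "harden the membership first (harden_membership)"))
  stopifnot(inherits(stratA, "stratification"), inherits(stratB, "stratification"))
  universe <- intersect(strat_records(stratA), strat_records(stratB))
  if (length(universe) == 0L)
    stop_stratkit("empty_universe_error",
                  "the stratifications share no records")
  labA <- strat_labels(stratA)[universe]
  labB <- strat_labels(stratB)[universe]
  M <- table(factor(labA, levels = names(stratA$groups)),
             factor(labB, levels = names(stratB$groups)))
  M <- matrix(as.integer(M), nrow = nrow(M),
              dimnames = list(names(stratA$groups), names(stratB$groups)))
  attr(M, "universe_size") <- length(universe)
  M
}

#' Adjusted Rand index between two stratifications
#'
#' Chance-corrected agreement of two partitions over their shared records:
#' 1 for identical partitions, ~0 for independent ones. Computed from the
#' contingency table with the usual pair-counting correction.
#'
#' @param stratA,stratB [stratification()] objects sharing >= 1 record.
#' @return Scalar in \[-1, 1\].
#' @export
adjusted_rand <- function(stratA, stratB) {
  M <- overlap_matrix(stratA, stratB)
  n <- sum(M)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(M))
  sum_a <- sum(choose2(rowSums(M)))
  sum_b <- sum(choose2(colSums(M)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Kaplan-Meier product-limit survival curve
#'
#' At each distinct event time t the estimate multiplies by `1 - d_t / n_t`
#' (d_t events among n_t at risk); censored records leave the risk set after
#' their time, and ties between events and censorings at the same time count
#' the events first. Backed by [survival::survfit()].
#'
#' @param survival_table `data.frame` with record_id, time, event columns
#'   (see [read_survival()]), already subset to the group of interest.
#' @return A `km_curve`: event `time`s in ascending order, the survival
#'   probability `surv` after each, numbers at risk / events / censored, and
#'   the `median` survival (smallest time with S <= 0.5, `NA` if never
#'   reached). The curve starts at 1 and is non-increasing.
#' @export
km_curve <- function(survival_table) {
  df <- as_survival_table(survival_table)
  if (nrow(df) == 0L) stop_param("empty survival subset")
  if (all(df$event == 0L))
    warn_stratkit("all_censored_warning",
                  "no events observed; survival curve is flat at 1")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                          conf.type = "none")
  keep <- sf$n.event > 0
  time <- sf$time[keep]
  surv <- sf$surv[keep]
  med <- if (any(surv <= 0.5)) time[which(surv <= 0.5)[1L]] else NA_real_
  structure(list(time = time, surv = surv,
                 n_risk = sf$n.risk[keep], n_event = sf$n.event[keep],
                 n_censor = sum(df$event == 0L), n = nrow(df), median = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, "(", sum(x$n_event), "events,",
      x$n_censor, "censored )\n")
  cat("median survival:",
      if (is.na(x$median)) "not reached" else format(x$median, digits = 6), "\n")
  invisible(x)
}

#' Survival probability at given times (right-continuous step function)
#'
#' @param curve A `km_curve`.
#' @param t Time(s) at which to evaluate S(t).
#' @return Survival probabilities; 1 before the first event.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(tt) {
    i <- findInterval(tt, curve$time)
    if (i == 0L) 1 else curve$surv[i]
  }, numeric(1))
}

#' @export
plot.km_curve <- function(x, ..., xlab = "time", ylab = "S(t)") {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[seq_len(2 * length(x$surv) - 1)])
  graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Per-group Kaplan-Meier curves and median survival
#'
#' @param strat A [stratification()].
#' @param survival_table Survival `data.frame` (record_id, time, event). Only
#'   records shared with the stratification contribute.
#' @return List with `curves` (named list of `km_curve`) and `summary`
#'   (`data.frame`: group, n, events, median).
#' @export
survival_by_group <- function(strat, survival_table) {
  stopifnot(inherits(strat, "stratification"))
  df <- as_survival_table(survival_table)
  curves <- list()
  rows <- list()
  for (g in names(strat$groups)) {
    sub <- df[df$record_id %in% strat$groups[[g]], , drop = FALSE]
    if (nrow(sub) == 0L) next
    cv <- suppressWarnings(km_curve(sub))
    curves[[g]] <- cv
    rows[[g]] <- data.frame(group = g, n = cv$n, events = sum(cv$n_event),
                            median = cv$median, stringsAsFactors = FALSE)
  }
  list(curves = curves, summary = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Per-group composition of a categorical attribute
#'
#' @param strat A [stratification()].
#' @param cats Categorical `data.frame` from [read_categorical()].
#' @param attribute Column name to summarise.
#' @return Integer contingency matrix group x category over the shared
#'   records; records lacking the attribute are counted as `"unknown"`.
#' @export
categorical_composition <- function(strat, cats, attribute) {
  stopifnot(inherits(strat, "stratification"))
  if (!attribute %in% names(cats))
    stop_param(paste0("unknown attribute: ", attribute))
  lab <- strat_labels(strat)
  val <- stats::setNames(as.character(cats[[attribute]]), cats$record_id)
  v <- val[names(lab)]
  v[is.na(v) | !nzchar(v)] <- "unknown"
  M <- table(factor(lab, levels = names(strat$groups)), v)
  matrix(as.integer(M), nrow = nrow(M),
         dimnames = list(names(strat$groups), colnames(M)))
}
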