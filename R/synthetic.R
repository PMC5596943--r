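# Seeded generators with known ground truth: Gaussian blob matrices (with
# optional uniform outliers), overlapping mixtures with posterior membership
# truth, and exponential survival tables. All generators are pure functions of
# their parameters and seed, so every other module is testable offline.

# Centroid layout: centroid 1 at the origin, centroid j at separation*sd along
# coordinate axis ((j-2) mod d) + 1, so any two centroids are at least
# separation*sd apart (adjacent pairs exactly, non-adjacent sqrt(2) times).
blob_centers <- function(k, d, separation, sd) {
  C <- matrix(0, k, d)
  for (j in seq_len(k)[-1L]) C[j, ((j - 2L) %% d) + 1L] <- separation * sd
  C
}

#' Generate Gaussian blobs with known cluster truth
#'
#' Records are drawn from isotropic Gaussians (sd `sd`) at centroids spaced
#' `separation * sd` apart; a fraction of records is replaced by outliers
#' drawn uniformly from a box around the centroids but rejected within 5 sd of
#' any centroid. Outliers are not part of any truth group: they sit in the
#' returned `outliers` pool, mirroring the exclusion operator's semantics.
#'
#' @param k Number of clusters.
#' @param per_cluster Records per cluster.
#' @param d Dimensionality (features).
#' @param separation Centroid spacing in units of within-cluster sd.
#' @param sd Within-cluster standard deviation (default 1).
#' @param outlier_frac Fraction of the `k * per_cluster` records replaced by
#'   outliers, in \[0, 0.5).
#' @param seed Integer seed.
#' @return List with `matrix` (records x features, ids `R001`, ... and
#'   `F1`, ...), `truth` (a [stratification()] of the non-outliers), and
#'   `outliers` (character vector of outlier record ids).
#' @export
make_blobs <- function(k, per_cluster, d, separation, sd = 1,
                       outlier_frac = 0, seed = 0L) {
  if (separation < 0) stop_param("separation must be >= 0")
  if (outlier_frac < 0 || outlier_frac >= 0.5)
    stop_param("outlier_frac must lie in [0, 0.5)")
  n <- k * per_cluster
  n_out <- round(outlier_frac * n)
  centers <- blob_centers(k, d, separation, sd)
  with_seed(seed, {
    lab <- rep(seq_len(k), each = per_cluster)
    X <- centers[lab, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = sd), n, d)
    out_idx <- if (n_out > 0L) sample.int(n, n_out) else integer(0)
    if (n_out > 0L) {
      # outliers live outside 5 sd of every centroid but at the data's own
      # scale (centroid bounding box padded by 10 sd): gross-but-plausible
      # anomalies, not points so remote they dominate any clustering objective
      lo <- apply(centers, 2L, min) - 10 * sd
      hi <- apply(centers, 2L, max) + 10 * sd
      for (i in out_idx) {
        repeat {
          p <- stats::runif(d, lo, hi)
          dmin <- min(sqrt(rowSums(sweep(centers, 2L, p)^2)))
          if (dmin > 5 * sd) break
        }
        X[i, ] <- p
      }
    }
    ids <- sprintf("R%03d", seq_len(n))
    dimnames(X) <- list(ids, paste0("F", seq_len(d)))
    truth_groups <- lapply(seq_len(k), function(j)
      ids[lab == j & !(seq_len(n) %in% out_idx)])
    names(truth_groups) <- group_names(k)
    list(matrix = as_data_matrix(X),
         truth = stratification(truth_groups[lengths(truth_groups) > 0L],
                                provenance = sprintf(
                                  "make_blobs(k=%d, per_cluster=%d, d=%d, sep=%g, sd=%g, outlier_frac=%g, seed=%d)",
                                  k, per_cluster, d, separation, sd,
                                  outlier_frac, as.integer(seed))),
         outliers = ids[sort(out_idx)])
  })
}

#' Generate an overlapping Gaussian mixture with posterior membership truth
#'
#' For small separations (< 3 sd) the components overlap and crisp truth is
#' meaningless; the ground truth is instead the posterior responsibility of
#' each equal-weight isotropic component, whose rows sum to 1 by construction.
#'
#' @inheritParams make_blobs
#' @param separation Centroid spacing in sd units; must be < 3.
#' @return List with `matrix` and `truth` (a [fuzzy_membership()] of the
#'   mixture responsibilities).
#' @export
make_overlapping <- function(k, per_cluster, d, separation, sd = 1, seed = 0L) {
  if (separation >= 3)
    stop_param("make_overlapping is for overlapping mixtures: separation < 3")
  n <- k * per_cluster
  centers <- blob_centers(k, d, separation, sd)
  with_seed(seed, {
    lab <- rep(seq_len(k), each = per_cluster)
    X <- centers[lab, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = sd), n, d)
    ids <- sprintf("R%03d", seq_len(n))
    dimnames(X) <- list(ids, paste0("F", seq_len(d)))
    U <- mixture_responsibilities(X, centers, sd)
    dimnames(U) <- list(ids, group_names(k))
    list(matrix = as_data_matrix(X), truth = fuzzy_membership(U))
  })
}

#' Posterior responsibilities of an equal-weight isotropic Gaussian mixture
#'
#' `r_ij` is proportional to `exp(-||x_i - c_j||^2 / (2 sd^2))`, computed with
#' the log-sum-exp trick; rows sum to 1 exactly.
#'
#' @param X Records x features matrix.
#' @param centers Components x features centroid matrix.
#' @param sd Common isotropic standard deviation.
#' @return Records x components responsibility matrix.
#' @export
mixture_responsibilities <- function(X, centers, sd) {
  L <- -.sqdist_to_centers(X, centers) / (2 * sd^2)
  if (nrow(X) == 1L) L <- matrix(L, nrow = 1L)
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Generate an exponential survival table matched to a stratification
#'
#' Event times are exponential with the group's hazard. Censoring is
#' independent exponential, with its rate chosen per group as
#' `censor_rate / (1 - censor_rate) * hazard`, so the probability that a
#' record is censored equals `censor_rate` exactly; `censor_rate = 0` means
#' every event is observed. The observed time is the minimum of the two and
#' the event flag marks whether the event came first.
#'
#' @param truth A [stratification()] defining the groups.
#' @param hazards Named numeric vector of per-group hazards (> 0); names must
#'   cover the groups. A single unnamed value is recycled.
#' @param censor_rate Target censoring probability in \[0, 1).
#' @param seed Integer seed.
#' @return Survival `data.frame` (record_id, time, event) covering every
#'   record of `truth`, in stratification order.
#' @export
make_survival <- function(truth, hazards, censor_rate = 0, seed = 0L) {
  stopifnot(inherits(truth, "stratification"))
  gn <- names(truth$groups)
  if (length(hazards) == 1L && is.null(names(hazards)))
    hazards <- stats::setNames(rep(hazards, length(gn)), gn)
  if (!all(gn %in% names(hazards)))
    stop_param("hazards must name every group")
  if (any(hazards <= 0)) stop_param("hazards must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop_param("censor_rate must lie in [0, 1)")
  with_seed(seed, {
    rows <- lapply(gn, function(g) {
      ids <- truth$groups[[g]]
      ev <- stats::rexp(length(ids), rate = hazards[[g]])
      if (censor_rate > 0) {
        cr <- censor_rate / (1 - censor_rate) * hazards[[g]]
        cs <- stats::rexp(length(ids), rate = cr)
      } else cs <- rep(Inf, length(ids))
      data.frame(record_id = ids, time = pmin(ev, cs),
                 event = as.integer(ev <= cs), stringsAsFactors = FALSE)
    })
    as_survival_table(do.call(rbind, rows))
  })
}
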