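# Metric registry. Every comparison that needs "closest" goes through
# to_dissimilarity(), which makes correlation and distance metrics
# interchangeable in the clustering, evaluation and refinement code.

.metric_table <- data.frame(
  name = c("euclidean", "sq_euclidean", "manhattan", "chebyshev",
           "canberra", "pearson", "spearman"),
  orientation = c("dissimilarity", "dissimilarity", "dissimilarity",
                  "dissimilarity", "dissimilarity", "similarity", "similarity"),
  stringsAsFactors = FALSE
)

#' Available metric names
#' @return Character vector of the registered metric names.
#' @export
metric_names <- function() .metric_table$name

#' Resolve a metric by name
#'
#' The registry carries geometric distances (Euclidean, squared Euclidean,
#' Manhattan, Chebyshev, Canberra) and rank/linear correlation coefficients
#' (Spearman, Pearson). Distances are dissimilarities (0 = identical);
#' correlations are similarities in \[-1, 1\] (1 = identical profile).
#'
#' @param name One of [metric_names()], or an existing `metric_spec`.
#' @return A `metric_spec` with fields `name` and `orientation`.
#' @export
metric_spec <- function(name) {
  if (inherits(name, "metric_spec")) return(name)
  if (!is.character(name) || length(name) != 1L || !(name %in% .metric_table$name))
    stop_param(paste0("unknown metric '", paste(name, collapse = ","),
                      "'; valid metrics: ",
                      paste(.metric_table$name, collapse = ", ")))
  i <- match(name, .metric_table$name)
  structure(list(name = name, orientation = .metric_table$orientation[i]),
            class = "metric_spec")
}

#' @export
print.metric_spec <- function(x, ...) {
  cat("Metric:", x$name, sprintf("(%s)\n", x$orientation))
  invisible(x)
}

is_similarity <- function(metric) metric_spec(metric)$orientation == "similarity"

#' Distance or correlation between two feature vectors
#'
#' @param a,b Numeric vectors of equal length (>= 2 for the correlation
#'   metrics).
#' @param metric Metric name or `metric_spec`.
#' @return A scalar: >= 0 for dissimilarity metrics, in \[-1, 1\] for
#'   correlations. Correlation with a zero-variance vector is undefined; it is
#'   returned as 0 with a warning so fit views always produce a value.
#' @examples
#' record_distance(c(0, 0), c(3, 4), "euclidean")   # 5
#' record_distance(c(1, 3), c(2, 3), "canberra")    # 1/3
#' record_distance(1:3, c(2, 4, 6), "pearson")      # 1
#' @export
record_distance <- function(a, b, metric) {
  m <- metric_spec(metric)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) == 0L)
    stop_stratkit("dimension_error",
                  sprintf("vector lengths differ or are zero (%d vs %d)",
                          length(a), length(b)))
  switch(m$name,
    euclidean    = sqrt(sum((a - b)^2)),
    sq_euclidean = sum((a - b)^2),
    manhattan    = sum(abs(a - b)),
    chebyshev    = max(abs(a - b)),
    canberra     = {
      num <- abs(a - b); den <- abs(a) + abs(b)
      keep <- den > 0
      sum(num[keep] / den[keep])
    },
    pearson      = .safe_cor(a, b, method = "pearson"),
    spearman     = .safe_cor(a, b, method = "spearman")
  )
}

.safe_cor <- function(a, b, method) {
  if (length(a) < 2L)
    stop_stratkit("dimension_error", "correlation metrics need length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warn_stratkit("constant_vector_warning",
                  "correlation with a zero-variance vector is undefined; returning 0")
    return(0)
  }
  # stats::cor: Spearman ranks ties by average rank
  stats::cor(a, b, method = method)
}

#' Centroid (arithmetic mean) of a set of record rows
#'
#' @param rows Numeric matrix with one row per record (a single vector is
#'   accepted as one record).
#' @return Numeric vector of per-feature means.
#' @export
centroid <- function(rows) {
  if (is.vector(rows)) rows <- matrix(rows, nrow = 1L)
  if (!is.matrix(rows) || nrow(rows) == 0L)
    stop_stratkit("empty_cluster_error", "cannot compute the centroid of an empty group")
  colMeans(rows)
}

#' Map a metric value onto the dissimilarity scale
#'
#' Dissimilarity metrics pass through unchanged; correlation (similarity)
#' values `r` map to `1 - r`, so 0 always means a perfect fit and larger
#' always means worse. Nearest-centroid logic, sorting and the split regions
#' all operate on this scale.
#'
#' @param value Metric value(s).
#' @param metric Metric name or `metric_spec`.
#' @return Value(s) on the dissimilarity scale (`[0, 2]` for correlations).
#' @export
to_dissimilarity <- function(value, metric) {
  if (is_similarity(metric)) 1 - value else value
}

# Fit (raw metric value) from every row of `mat` to a single centroid vector.
fit_to_centroid <- function(mat, ctr, metric) {
  m <- metric_spec(metric)
  switch(m$name,
    euclidean    = sqrt(rowSums(sweep(mat, 2L, ctr)^2)),
    sq_euclidean = rowSums(sweep(mat, 2L, ctr)^2),
    manhattan    = rowSums(abs(sweep(mat, 2L, ctr))),
    chebyshev    = apply(abs(sweep(mat, 2L, ctr)), 1L, max),
    vapply(seq_len(nrow(mat)),
           function(i) record_distance(mat[i, ], ctr, m), numeric(1))
  )
}

# Same, but mapped onto the dissimilarity scale (0 = perfect fit).
dissim_to_centroid <- function(mat, ctr, metric) {
  to_dissimilarity(fit_to_centroid(mat, ctr, metric), metric)
}

# Full pairwise dissimilarity matrix between rows of `mat`.
pairwise_dissimilarity <- function(mat, metric) {
  m <- metric_spec(metric)
  n <- nrow(mat)
  D <- switch(m$name,
    euclidean    = as.matrix(stats::dist(mat, method = "euclidean")),
    sq_euclidean = as.matrix(stats::dist(mat, method = "euclidean"))^2,
    manhattan    = as.matrix(stats::dist(mat, method = "manhattan")),
    chebyshev    = as.matrix(stats::dist(mat, method = "maximum")),
    {
      D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
      for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
        D[i, j] <- D[j, i] <- to_dissimilarity(
          record_distance(mat[i, ], mat[j, ], m), m)
      }
      D
    }
  )
  D
}
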