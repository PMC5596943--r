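# Static HTML/SVG report: per group a row-aligned expression heatmap, the
# within-cluster fit bars sorted best to worst, and the between-cluster fit
# matrix as a grayscale heat map; threshold markers at the split positions.
# Output is plain string-built markup with no timestamps, so regeneration from
# identical inputs is byte-identical.

svg_rect <- function(x, y, w, h, fill, class = NULL) {
  sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s"%s/>',
          x, y, w, h, fill,
          if (is.null(class)) "" else sprintf(' class="%s"', class))
}

# blue-white-red diverging ramp over the matrix value range
heat_color <- function(v, lo, hi) {
  if (hi <= lo) return(rep("#ffffff", length(v)))
  t <- (v - lo) / (hi - lo)
  r <- ifelse(t < 0.5, 2 * t, 1)
  b <- ifelse(t < 0.5, 1, 2 * (1 - t))
  g <- 1 - abs(2 * t - 1) * 0.6
  grDevices::rgb(r, g, b)
}

gray_color <- function(v, lo, hi) {
  if (hi <= lo) return(rep("#808080", length(v)))
  t <- pmin(pmax((v - lo) / (hi - lo), 0), 1)
  grDevices::gray(1 - t)   # darker = larger fit value
}

#' Render a static evaluation report
#'
#' One HTML page per stratification: for each group a heatmap block of the
#' group's records, the within-cluster fit bars (sorted best to worst and
#' scaled against the run's global maximum), and the grayscale between-cluster
#' fit matrix with the own-group cells empty. When a fuzzy membership is
#' supplied, records above the display threshold in several clusters are
#' rendered with the `shared` style class (purple) and unique records in
#' green. Threshold markers are drawn at the split-spec positions.
#'
#' @param mat Records x features matrix.
#' @param strat A [stratification()].
#' @param metric Metric name or `metric_spec`.
#' @param file Output HTML path.
#' @param membership Optional [fuzzy_membership()] for the shared/unique
#'   highlighting.
#' @param spec Optional [split_spec()] whose thresholds are drawn on the fit
#'   bars.
#' @return The output path, invisibly.
#' @export
render_report <- function(mat, strat, metric = "euclidean", file,
                          membership = NULL, spec = NULL) {
  mat <- as_data_matrix(mat)
  stopifnot(inherits(strat, "stratification"))
  prof <- within_cluster_fit(mat, strat, metric)
  bf <- if (length(strat$groups) >= 2L) between_cluster_fit(mat, strat, metric) else NULL
  shared <- if (!is.null(membership)) membership_view(membership)$shared else NULL

  cell <- 8; bar_w <- 120; gap <- 20
  ids_all <- strat_records(strat)
  sub <- mat[ids_all, , drop = FALSE]
  lo <- min(sub); hi <- max(sub)
  gmax <- prof$global_scale_max
  dmax <- if (!is.null(bf)) max(bf$fit, na.rm = TRUE) else 1
  dmin <- if (!is.null(bf)) min(bf$fit, na.rm = TRUE) else 0
  k <- length(strat$groups)
  blocks <- character(0)
  for (g in names(strat$groups)) {
    ids <- prof$order[[g]]           # best fit first
    nr <- length(ids)
    h <- nr * cell
    w_heat <- ncol(sub) * cell
    x_bar <- w_heat + gap
    x_mat <- x_bar + bar_w + gap
    svg <- c(sprintf('<svg width="%d" height="%d" role="img">',
                     ceiling(x_mat + k * 16 + 10), h + 20))
    for (i in seq_along(ids)) {
      vals <- sub[ids[i], ]
      cols <- heat_color(vals, lo, hi)
      svg <- c(svg, vapply(seq_along(vals), function(j)
        svg_rect((j - 1) * cell, (i - 1) * cell, cell, cell, cols[j]),
        character(1)))
      # fit bar, globally scaled
      f <- abs(prof$fit[ids[i]])
      wbar <- if (gmax > 0) f / gmax * bar_w else 0
      cls <- if (!is.null(shared) && isTRUE(shared[ids[i]])) "shared" else "unique"
      svg <- c(svg, svg_rect(x_bar, (i - 1) * cell + 1, wbar, cell - 2,
                             if (cls == "shared") "#8e44ad" else "#27ae60",
                             class = cls))
      if (!is.null(bf)) {
        bvals <- bf$fit[ids[i], ]
        for (j in seq_along(bvals)) {
          fill <- if (is.na(bvals[j])) "#ffffff"
                  else gray_color(bvals[j], dmin, dmax)
          svg <- c(svg, svg_rect(x_mat + (j - 1) * 16, (i - 1) * cell,
                                 15, cell, fill))
        }
      }
    }
    if (!is.null(spec) && gmax > 0) {
      for (tt in c(spec$t1, spec$t2)) {
        xt <- x_bar + abs(tt) / gmax * bar_w
        svg <- c(svg, sprintf(
          '<line x1="%.2f" y1="0" x2="%.2f" y2="%d" stroke="#c0392b" stroke-dasharray="3,2" class="threshold"/>',
          xt, xt, h))
      }
    }
    svg <- c(svg, "</svg>")
    blocks <- c(blocks, sprintf(
      '<section class="cluster"><h2>%s (n=%d)</h2><div class="heatmap">%s</div></section>',
      g, nr, paste(svg, collapse = "")))
  }
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>Cluster evaluation report (%s)</title>", prof$metric$name),
    "<style>body{font-family:sans-serif} .cluster{margin-bottom:1em}</style>",
    "</head><body>",
    sprintf("<h1>Cluster evaluation — %d groups, %d records, metric %s (%s)</h1>",
            k, length(ids_all), prof$metric$name, prof$metric$orientation),
    sprintf("<p>Bars show the fit of each record to its own cluster centroid, sorted best to worst and scaled against the global maximum %.6g. The grayscale matrix shows the fit to every other cluster; own-cluster cells are empty.</p>",
            gmax),
    blocks,
    "</body></html>")
  writeLines(html, file, useBytes = TRUE)
  invisible(file)
}
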