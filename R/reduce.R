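# Min-max trace reduction for display: per pixel column, the many
# sample-to-sample line drawings are replaced by one vertical min-max
# segment plus one connector into the next column, preserving exactly the
# set of pixels the naive polyline would cover.

#' Per-column extrema of a sample vector
#'
#' Partitions `samples` into `width_px` contiguous columns (column `k` gets
#' samples `floor((k-1) n / w) + 1` through `floor(k n / w)`, sizes
#' differing by at most one) and returns the exact min and max of each.
#'
#' @param samples Numeric vector (or a [trace()]), n >= 2.
#' @param width_px Number of pixel columns (>= 1).
#' @return Tibble with one row per column: `column`, `first`, `last`
#'   (sample indices), `min`, `max`.
#' @export
column_extrema <- function(samples, width_px) {
  if (is_trace(samples)) samples <- samples$samples
  n <- length(samples)
  if (n < 2L) {
    rlang::abort("Need at least two samples.", class = "sweepkit_error_argument")
  }
  if (width_px < 1L) {
    rlang::abort("`width_px` must be >= 1.", class = "sweepkit_error_argument")
  }
  w <- as.integer(width_px)
  bounds <- floor((0:w) * n / w)      # 0-based exclusive cuts
  tibble::tibble(
    column = seq_len(w),
    first = bounds[-(w + 1L)] + 1L,
    last = bounds[-1L],
    min = purrr::map2_dbl(bounds[-(w + 1L)] + 1L, bounds[-1L],
                          function(a, b) min(samples[a:b])),
    max = purrr::map2_dbl(bounds[-(w + 1L)] + 1L, bounds[-1L],
                          function(a, b) max(samples[a:b]))
  )
}

#' Min-max reduction of a trace to a drawable segment list
#'
#' If `n <= 2 * width_px + 2` the reduction saves nothing and the unreduced
#' polyline (`n - 1` segments) is returned. Otherwise each pixel column
#' contributes one vertical segment spanning its min-max range plus one
#' connector from its last sample to the first sample of the next column:
#' exactly `2 * width_px - 1` segments, independent of `n`, covering the
#' same vertical pixel span per column as the naive drawing. The vertical
#' segment is oriented toward whichever extremum occurs first in the
#' column.
#'
#' @param samples Numeric vector or [trace()] (x taken as sample index, or
#'   time for traces).
#' @param width_px Horizontal resolution in pixel columns.
#' @return Tibble of segments (`x1`, `y1`, `x2`, `y2`, `kind` =
#'   `"vertical"`/`"connector"`/`"polyline"`) with attributes `reduced`
#'   (logical) and `width` (pixel columns).
#' @examples
#' seg <- reduce_trace(rnorm(16000), width_px = 800)
#' nrow(seg)  # 1599 = 2 * 800 - 1
#' @export
reduce_trace <- function(samples, width_px) {
  x <- NULL
  if (is_trace(samples)) {
    x <- trace_times(samples)
    samples <- samples$samples
  }
  n <- length(samples)
  if (n < 2L) {
    rlang::abort("Need at least two samples.", class = "sweepkit_error_argument")
  }
  if (width_px < 1L) {
    rlang::abort("`width_px` must be >= 1.", class = "sweepkit_error_argument")
  }
  if (is.null(x)) x <- seq_len(n)
  w <- as.integer(width_px)
  if (n <= 2L * w + 2L) {
    out <- tibble::tibble(x1 = x[-n], y1 = samples[-n],
                          x2 = x[-1], y2 = samples[-1],
                          kind = "polyline")
    attr(out, "reduced") <- FALSE
    attr(out, "width") <- w
    return(out)
  }
  ext <- column_extrema(samples, w)
  xmid <- x[ext$first]   # draw the column's vertical at its first sample
  # vertical min->max when the min occurs first, else max->min
  imin <- purrr::map2_int(ext$first, ext$last,
                          function(a, b) a + which.min(samples[a:b]) - 1L)
  imax <- purrr::map2_int(ext$first, ext$last,
                          function(a, b) a + which.max(samples[a:b]) - 1L)
  min_first <- imin <= imax
  vert <- tibble::tibble(
    x1 = xmid, y1 = ifelse(min_first, ext$min, ext$max),
    x2 = xmid, y2 = ifelse(min_first, ext$max, ext$min),
    kind = "vertical")
  conn <- tibble::tibble(
    x1 = x[ext$last[-w]], y1 = samples[ext$last[-w]],
    x2 = x[ext$first[-1]], y2 = samples[ext$first[-1]],
    kind = "connector")
  out <- dplyr::arrange(dplyr::bind_rows(vert, conn), x1, dplyr::desc(kind))
  attr(out, "reduced") <- TRUE
  attr(out, "width") <- w
  out
}
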