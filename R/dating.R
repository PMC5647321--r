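# 4dTv distribution, peak detection, and molecular-clock dating: turn
# block-level (or pair-level) 4dTv values into divergence-time estimates.

#' Kernel density of a 4dTv distribution
#'
#' Gaussian kernel density estimate on a fixed grid of 512 points over
#' `[0, max(values) + 3*bandwidth]`. `bandwidth = "auto"` uses Silverman's
#' rule of thumb (`stats::bw.nrd0`).
#'
#' @param values Numeric vector of defined 4dTv values (NAs dropped); at
#'   least 2 required.
#' @param bandwidth Kernel bandwidth, or `"auto"`.
#' @return Object of class `dtv_density`: list with `values`, `bandwidth`,
#'   `grid`, `density`.
#' @export
build_density <- function(values, bandwidth = "auto") {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("need at least 2 defined 4dTv values", call. = FALSE)
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(values)
        else .check_number(bandwidth, "bandwidth", lower = 0, strict = TRUE)
  d <- stats::density(values, bw = bw, kernel = "gaussian",
                      from = 0, to = max(values) + 3 * bw, n = 512L)
  structure(list(values = values, bandwidth = bw, grid = d$x,
                 density = d$y),
            class = "dtv_density")
}

#' @export
print.dtv_density <- function(x, ...) {
  cat(sprintf("4dTv density: n = %d, bandwidth = %.4g, grid [0, %.4g]\n",
              length(x$values), x$bandwidth, max(x$grid)))
  invisible(x)
}

#' Detect peaks of a 4dTv density
#'
#' Interior local maxima of the density whose prominence -- height minus the
#' higher of the two flanking minima, where each flanking minimum is the
#' lowest density between the peak and the neighbouring local maximum (or
#' grid end) on that side -- reaches `min_prominence` times the maximum
#' density. Taking the higher flank means a mode rising only slightly above
#' an adjacent shoulder is discarded, so a near-flat density yields no peaks.
#' Grid endpoints are never peaks. Peaks are returned in descending height,
#' ties broken toward the lower position; positions are reported at grid
#' resolution.
#'
#' @param dist A [build_density()] result.
#' @param min_prominence Prominence threshold as a fraction of the maximum
#'   density.
#' @return Data frame with columns `position`, `height`, `prominence`
#'   (possibly 0 rows).
#' @export
detect_peaks <- function(dist, min_prominence = 0.05) {
  stopifnot(inherits(dist, "dtv_density"))
  y <- dist$density
  x <- dist$grid
  n <- length(y)
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                  y[2:(n - 1L)] >= y[3:n]) + 1L
  if (length(cand) == 0L)
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(seq_along(cand), function(ci) {
    m <- cand[ci]
    lo <- if (ci > 1L) cand[ci - 1L] else 1L
    hi <- if (ci < length(cand)) cand[ci + 1L] else n
    y[m] - max(min(y[lo:m]), min(y[m:hi]))
  }, numeric(1))
  keep <- prom >= min_prominence * max(y)
  out <- data.frame(position = x[cand[keep]], height = y[cand[keep]],
                    prominence = prom[keep])
  out <- out[order(-out$height, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate a two-lineage molecular clock from an anchor
#'
#' Two diverging lineages accumulate 4dTv jointly, so a pair whose divergence
#' is `anchor_mya` million years old and whose 4dTv is `anchor_4dtv` implies a
#' per-lineage accumulation rate of `anchor_4dtv / (2 * anchor_mya)` 4dTv per
#' million years.
#'
#' @param anchor_4dtv 4dTv value of a peak with known age (> 0).
#' @param anchor_mya Age of that divergence in million years (> 0).
#' @return Object of class `dtv_clock`: list with `rate` (4dTv/My per
#'   lineage) and `anchor`.
#' @export
calibrate_rate <- function(anchor_4dtv, anchor_mya) {
  .check_number(anchor_4dtv, "anchor_4dtv", lower = 0, strict = TRUE)
  .check_number(anchor_mya, "anchor_mya", lower = 0, strict = TRUE)
  structure(list(rate = anchor_4dtv / (2 * anchor_mya),
                 anchor = c(fourdtv = anchor_4dtv, mya = anchor_mya)),
            class = "dtv_clock")
}

#' @export
print.dtv_clock <- function(x, ...) {
  cat(sprintf("4dTv clock: %.4g 4dTv/My per lineage (anchor 4dTv %.3g at %.3g Mya)\n",
              x$rate, x$anchor["fourdtv"], x$anchor["mya"]))
  invisible(x)
}

#' Date a 4dTv peak with a calibrated clock
#'
#' @param peak_4dtv Peak position(s) in 4dTv units (>= 0).
#' @param clock A [calibrate_rate()] object.
#' @return Divergence time(s) in million years: `peak_4dtv / (2 * rate)`.
#' @export
date_peak <- function(peak_4dtv, clock) {
  stopifnot(inherits(clock, "dtv_clock"))
  if (any(is.na(peak_4dtv)) || any(peak_4dtv < 0))
    stop("peak 4dTv must be non-negative", call. = FALSE)
  if (clock$rate <= 0) stop("clock rate must be positive", call. = FALSE)
  peak_4dtv / (2 * clock$rate)
}

#' Fit a WGD/speciation dating model to 4dTv values
#'
#' The central fit of the package: estimates the 4dTv distribution of a set
#' of gene pairs or syntenic blocks by Gaussian KDE, locates its modes by
#' prominence-filtered peak detection, and (given a calibration anchor)
#' converts each mode to a divergence time under a two-lineage molecular
#' clock. Peaks of the paralog distribution date polyploidization events;
#' ortholog peaks date speciations.
#'
#' @param values Numeric vector of 4dTv values (block-level medians from
#'   [block_4dtv()] by default usage, or per-pair values), or a
#'   `fourdtv_values`-bearing data frame column extracted by the caller.
#' @param bandwidth Passed to [build_density()].
#' @param min_prominence Passed to [detect_peaks()].
#' @param anchor_4dtv,anchor_mya Optional clock anchor passed to
#'   [calibrate_rate()]; when given, peaks gain a `date_mya` column.
#' @return Object of class `wgd_dating` with elements `density`
#'   (`dtv_density`), `peaks` (data frame: position, height, prominence
#'   [, date_mya]), `clock` (`dtv_clock` or `NULL`), `n`, `call`. Methods:
#'   `print`, `summary`, `plot`, `coef` (peak positions).
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 0.05, 0.01), rnorm(150, 0.30, 0.02))
#' fit <- wgd_dating(x, anchor_4dtv = 0.27, anchor_mya = 46.7)
#' fit
#' coef(fit)
#' @export
wgd_dating <- function(values, bandwidth = "auto", min_prominence = 0.05,
                       anchor_4dtv = NULL, anchor_mya = NULL) {
  dens <- build_density(values, bandwidth = bandwidth)
  peaks <- detect_peaks(dens, min_prominence = min_prominence)
  clock <- NULL
  if (!is.null(anchor_4dtv) || !is.null(anchor_mya)) {
    if (is.null(anchor_4dtv) || is.null(anchor_mya))
      stop("supply both `anchor_4dtv` and `anchor_mya`, or neither",
           call. = FALSE)
    clock <- calibrate_rate(anchor_4dtv, anchor_mya)
    peaks$date_mya <- if (nrow(peaks)) date_peak(peaks$position, clock)
                      else numeric(0)
  }
  structure(list(density = dens, peaks = peaks, clock = clock,
                 n = length(dens$values), call = match.call()),
            class = "wgd_dating")
}

#' @export
print.wgd_dating <- function(x, digits = 4, ...) {
  cat("4dTv peak dating\n")
  cat(sprintf("  %d values, bandwidth %.4g, %d peak(s)\n",
              x$n, x$density$bandwidth, nrow(x$peaks)))
  if (nrow(x$peaks)) {
    print(format(x$peaks, digits = digits), row.names = TRUE)
  } else {
    cat("  no peak above the prominence threshold\n")
  }
  invisible(x)
}

#' @export
summary.wgd_dating <- function(object, ...) {
  structure(list(fit = object), class = "summary.wgd_dating")
}

#' @export
print.summary.wgd_dating <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  value range: [%.4g, %.4g], median %.4g\n",
              min(f$density$values), max(f$density$values),
              stats::median(f$density$values)))
  if (!is.null(f$clock)) print(f$clock)
  invisible(x)
}

#' @export
coef.wgd_dating <- function(object, ...) {
  if (!nrow(object$peaks)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(object$peaks$position,
                  paste0("peak", seq_len(nrow(object$peaks))))
}

#' @export
plot.wgd_dating <- function(x, main = "4dTv distribution",
                            xlab = "4dTv", ylab = "density", ...) {
  graphics::plot(x$density$grid, x$density$density, type = "l",
                 main = main, xlab = xlab, ylab = ylab, ...)
  if (nrow(x$peaks)) {
    graphics::abline(v = x$peaks$position, lty = 2, col = "grey40")
    lab <- if (!is.null(x$peaks$date_mya))
      sprintf("%.3g (%.1f Mya)", x$peaks$position, x$peaks$date_mya)
    else sprintf("%.3g", x$peaks$position)
    graphics::text(x$peaks$position, x$peaks$height, lab, pos = 4, cex = 0.8)
  }
  invisible(x)
}
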