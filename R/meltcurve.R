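# Melting-temperature estimation from thermal denaturation curves.

#' Estimate the melting temperature from a melt curve
#'
#' Smooths the fluorescence with a centered moving average of
#' \code{smoothWindow} points, takes the central-difference first derivative
#' dF/dT on the uniform temperature grid, and reports Tm as the temperature
#' at the maximum of the derivative over the rising phase of the transition.
#' Constant vertical offsets of the curve do not change the estimate.
#'
#' @param curve data.frame with columns \code{temperature} (strictly
#'   increasing, uniform step) and \code{fluorescence}.
#' @param smoothWindow odd number of points of the moving average
#'   (default 5; 1 disables smoothing).
#' @return list (class \code{TmEstimate}) with \code{tm} (degrees C),
#'   \code{derivative} (data.frame temperature, dFdT over the interior grid)
#'   and \code{smoothWindow}.
#' @export
meltCurveTm <- function(curve, smoothWindow = 5L) {
  stopIfNot(all(c("temperature", "fluorescence") %in% names(curve)),
            "curve needs temperature and fluorescence columns")
  tC <- curve$temperature
  fl <- curve$fluorescence
  stopIfNot(length(tC) >= 5, "need at least 5 points")
  dt <- diff(tC)
  stopIfNot(all(dt > 0), "temperature must be strictly increasing")
  stopIfNot(diff(range(dt)) <= 1e-6 * mean(dt) + 1e-9,
            "temperature grid must be uniform")
  stopIfNot(smoothWindow >= 1 && smoothWindow %% 2 == 1,
            "smoothWindow must be odd")
  h <- mean(dt)
  if (smoothWindow > 1) {
    half <- (smoothWindow - 1) / 2
    padded <- c(rep(fl[1], half), fl, rep(fl[length(fl)], half))
    fl <- as.numeric(stats::filter(padded, rep(1 / smoothWindow, smoothWindow),
                                   sides = 2))[(half + 1):(half + length(tC))]
  }
  n <- length(fl)
  dFdT <- (fl[3:n] - fl[1:(n - 2)]) / (2 * h)
  tMid <- tC[2:(n - 1)]
  if (max(dFdT) <= 0)
    stop("no melting transition: the curve has no rising phase")
  peak <- which.max(dFdT)
  structure(list(tm = tMid[peak],
                 derivative = data.frame(temperature = tMid, dFdT = dFdT),
                 smoothWindow = as.integer(smoothWindow)),
            class = "TmEstimate")
}

#' @export
print.TmEstimate <- function(x, ...) {
  cat(sprintf("Tm estimate: %.1f C (window %d, %d derivative points)\n",
              x$tm, x$smoothWindow, nrow(x$derivative)))
  invisible(x)
}
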