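#' Plot microstate topographies
#'
#' Quick-look topographic rendering of a map set: each map is interpolated
#' onto a disc in the flat layout projection with inverse-distance
#' weighting and drawn as a filled image (red positive, blue negative)
#' with the electrode positions overlaid.
#'
#' @param x a [MicrostateMaps-class].
#' @param layout a [SensorLayout-class] matching the maps' channels.
#' @param gridN interpolation grid resolution per axis.
#' @param ... ignored.
#' @importFrom graphics image par points text title
#' @importFrom grDevices colorRampPalette
#' @export
setMethod("plot", signature(x = "MicrostateMaps", y = "missing"),
  function(x, layout = makeLayout(), gridN = 60L, ...) {
    stopifnot(identical(layout@channels, x@channels))
    K <- nMaps(x)
    old <- par(mfrow = c(1, K), mar = c(0.5, 0.5, 2, 0.5))
    on.exit(par(old))
    p2 <- layout@pos2
    rmax <- max(sqrt(rowSums(p2^2))) * 1.05
    g <- seq(-rmax, rmax, length.out = gridN)
    gx <- matrix(g, gridN, gridN)
    gy <- t(gx)
    inside <- sqrt(gx^2 + gy^2) <= rmax
    pal <- colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
    for (k in seq_len(K)) {
      v <- x@maps[k, ]
      z <- matrix(NA_real_, gridN, gridN)
      d2 <- outer(as.numeric(gx), p2[, 1], `-`)^2 +
        outer(as.numeric(gy), p2[, 2], `-`)^2
      w <- 1 / pmax(d2, 1e-6)
      z[] <- (w %*% v) / rowSums(w)
      z[!inside] <- NA
      lim <- max(abs(z), na.rm = TRUE)
      image(g, g, z, zlim = c(-lim, lim), col = pal, axes = FALSE,
            xlab = "", ylab = "", asp = 1)
      points(p2[, 1], p2[, 2], pch = 20, cex = 0.6)
      lab <- x@classLabels[k]
      title(if (is.na(lab)) paste("map", k) else paste("class", lab))
    }
    invisible(NULL)
  })
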