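#' Canonical 19-channel 10-20 sensor layout
#'
#' Builds the standard 19-electrode international 10-20 montage used by
#' routine clinical EEG (Fp1, Fp2, F7, F3, Fz, F4, F8, T3, C3, Cz, C4, T4,
#' T5, P3, Pz, P4, T6, O1, O2) with unit-sphere electrode coordinates
#' (x = right, y = anterior, z = vertex) and a flat azimuthal-equidistant
#' projection for plotting.
#'
#' @return a [SensorLayout-class] with 19 channels.
#' @examples
#' lay <- makeLayout()
#' nChannels(lay)
#' @export
makeLayout <- function() {
  # standard unit-sphere coordinates for the 10-20 positions
  tab <- rbind(
    Fp1 = c(-0.3090,  0.9511, 0.0000),
    Fp2 = c( 0.3090,  0.9511, 0.0000),
    F7  = c(-0.8090,  0.5878, 0.0000),
    F3  = c(-0.5450,  0.6730, 0.5000),
    Fz  = c( 0.0000,  0.7071, 0.7071),
    F4  = c( 0.5450,  0.6730, 0.5000),
    F8  = c( 0.8090,  0.5878, 0.0000),
    T3  = c(-1.0000,  0.0000, 0.0000),
    C3  = c(-0.7071,  0.0000, 0.7071),
    Cz  = c( 0.0000,  0.0000, 1.0000),
    C4  = c( 0.7071,  0.0000, 0.7071),
    T4  = c( 1.0000,  0.0000, 0.0000),
    T5  = c(-0.8090, -0.5878, 0.0000),
    P3  = c(-0.5450, -0.6730, 0.5000),
    Pz  = c( 0.0000, -0.7071, 0.7071),
    P4  = c( 0.5450, -0.6730, 0.5000),
    T6  = c( 0.8090, -0.5878, 0.0000),
    O1  = c(-0.3090, -0.9511, 0.0000),
    O2  = c( 0.3090, -0.9511, 0.0000))
  tab <- tab / sqrt(rowSums(tab^2))
  # azimuthal equidistant: radius = inclination from vertex, direction kept
  incl <- acos(pmin(1, pmax(-1, tab[, 3])))
  az <- atan2(tab[, 2], tab[, 1])
  pos2 <- cbind(incl * cos(az), incl * sin(az))
  dimnames(pos2) <- list(rownames(tab), c("u", "v"))
  new("SensorLayout", channels = rownames(tab), pos3 = tab, pos2 = pos2)
}

# Common synonyms between the older 10-20 names and the modified
# combinatorial nomenclature, normalized to the layout's own names.
channelSynonyms <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Normalize 10-20 channel names
#'
#' Maps modern modified-nomenclature names (T7, T8, P7, P8) onto the older
#' equivalents used by this layout (T3, T4, T5, T6) and trims whitespace.
#'
#' @param names character vector of channel names.
#' @return normalized character vector.
#' @export
normalizeChannelNames <- function(names) {
  nm <- trimws(names)
  hit <- nm %in% names(channelSynonyms)
  nm[hit] <- channelSynonyms[nm[hit]]
  nm
}

# great-circle (angular) distance matrix between layout channels
greatCircleDist <- function(layout) {
  g <- tcrossprod(layout@pos3)
  acos(pmin(pmax(g, -1), 1))
}
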