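#' Standard 32-channel 10-20 montage
#'
#' Schematic 2-D electrode layout (unit head radius, nose up) for a
#' 32-channel cap with midline and lateral rows from frontopolar to
#' occipital sites, including the centroparietal electrode CPz at which the
#' P3 and Pe components peak.
#'
#' @return A data.frame with columns `channel`, `x`, `y`.
#' @examples
#' m <- standardMontage32()
#' subset(m, channel == "CPz")
#' @export
standardMontage32 <- function() {
  ch <- c("Fp1", "Fpz", "Fp2",
          "F7",  "F3",  "Fz",  "F4",  "F8",
          "FT7", "FC3", "FCz", "FC4", "FT8",
          "T7",  "C3",  "Cz",  "C4",  "T8",
          "TP7", "CP3", "CPz", "CP4", "TP8",
          "P7",  "P3",  "Pz",  "P4",  "P8",
          "O1",  "Oz",  "O2",  "POz")
  x <- c(-0.30, 0.00, 0.30,
         -0.65, -0.35, 0.00, 0.35, 0.65,
         -0.70, -0.35, 0.00, 0.35, 0.70,
         -0.80, -0.40, 0.00, 0.40, 0.80,
         -0.70, -0.35, 0.00, 0.35, 0.70,
         -0.65, -0.35, 0.00, 0.35, 0.65,
         -0.30, 0.00, 0.30, 0.00)
  y <- c(0.80, 0.85, 0.80,
         0.50, 0.50, 0.50, 0.50, 0.50,
         0.25, 0.25, 0.25, 0.25, 0.25,
         0.00, 0.00, 0.00, 0.00, 0.00,
         -0.25, -0.25, -0.25, -0.25, -0.25,
         -0.50, -0.50, -0.50, -0.50, -0.50,
         -0.80, -0.85, -0.80, -0.65)
  data.frame(channel = ch, x = x, y = y, stringsAsFactors = FALSE)
}

#' Gaussian scalp topography centred on an electrode
#'
#' Builds a unit-norm (L2) channel-weight vector as a Gaussian bump over
#' the 2-D montage coordinates, centred on `center` (default CPz, the site
#' of the centroparietal P3/Pe positivities).
#'
#' @param montage Montage data.frame as from [standardMontage32()].
#' @param center Channel label at the bump centre.
#' @param width Spatial standard deviation of the bump (head-radius units).
#' @return Named numeric vector of channel weights with unit L2 norm.
#' @export
gaussianTopography <- function(montage = standardMontage32(), center = "CPz",
                               width = 0.35) {
  i <- match(center, montage$channel)
  stopIfNot(!is.na(i), sprintf("channel '%s' not in montage", center))
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  w <- exp(-d2 / (2 * width^2))
  w <- w / sqrt(sum(w^2))
  names(w) <- montage$channel
  w
}
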