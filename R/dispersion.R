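#' Construct a dispersion model for a supported material
#'
#' Sellmeier coefficients are taken from published fits:
#' \itemize{
#'   \item \code{"fused_silica"}: Malitson, J. Opt. Soc. Am. 55, 1205 (1965);
#'     valid 210--3710 nm.
#'   \item \code{"water"}: Daimon & Masumura, Appl. Opt. 46, 3811 (2007),
#'     20 degrees C fit; valid 182--1129 nm.
#'   \item \code{"vacuum"}: n = 1 at all wavelengths.
#' }
#'
#' @param name one of "vacuum", "fused_silica", "water"
#' @return a \linkS4class{DispersionModel}
#' @examples
#' refractiveIndex(dispersionModel("fused_silica"), 532)
#' @export
dispersionModel <- function(name = c("vacuum", "fused_silica", "water")) {
  name <- match.arg(name)
  switch(name,
    vacuum = new("DispersionModel", name = "vacuum",
      coefA = numeric(0), coefL = numeric(0),
      validRange = c(1, Inf), source = "definition"),
    fused_silica = new("DispersionModel", name = "fused_silica",
      coefA = c(0.6961663, 0.4079426, 0.8974794),
      coefL = c(0.0684043, 0.1162414, 9.896161)^2,
      validRange = c(210, 3710),
      source = "Malitson (1965), J. Opt. Soc. Am. 55, 1205"),
    water = new("DispersionModel", name = "water",
      coefA = c(5.684027565e-1, 1.726177391e-1, 2.086189578e-2, 1.130748688e-1),
      coefL = c(5.101829712e-3, 1.821153936e-2, 2.620722293e-2, 1.069792721e1),
      validRange = c(182, 1129),
      source = "Daimon & Masumura (2007), Appl. Opt. 46, 3811 (20 C)"))
}

#' Refractive index from a Sellmeier dispersion model
#'
#' @param model a \linkS4class{DispersionModel}
#' @param wavelength vacuum wavelength(s) in nm
#' @return dimensionless refractive index n(lambda), vectorized over wavelength
#' @examples
#' refractiveIndex(dispersionModel("water"), 780)
#' @export
refractiveIndex <- function(model, wavelength) {
  stopifnot(is(model, "DispersionModel"))
  if (any(wavelength < model@validRange[1] | wavelength > model@validRange[2]))
    stop(sprintf("wavelength outside the validity range [%g, %g] nm of the %s model",
                 model@validRange[1], model@validRange[2], model@name))
  if (model@name == "vacuum") return(rep(1, length(wavelength)))
  l2 <- (wavelength / 1000)^2  # Sellmeier forms use lambda in um
  s <- rep(0, length(wavelength))
  for (i in seq_along(model@coefA))
    s <- s + model@coefA[i] * l2 / (l2 - model@coefL[i])
  sqrt(1 + s)
}

# Largest wavelength band (nm) on which every model in `models` is valid.
.jointValidRange <- function(models) {
  lo <- max(vapply(models, function(m) m@validRange[1], numeric(1)))
  hi <- min(vapply(models, function(m) m@validRange[2], numeric(1)))
  c(lo, hi)
}
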