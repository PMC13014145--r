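# Faddeeva function w(z) = exp(-z^2) erfc(-iz) for Im(z) >= 0.
# Moderate |z|: direct evaluation through the complex error function
# (pracma::erfz); large |z|: Laplace continued fraction (backward recursion),
# which is accurate to ~1e-13 for |z| >= 6 and avoids the exp(-z^2)*erf
# overflow/underflow pair in the far wings.
faddeeva <- function(z) {
  w <- complex(length.out = length(z))
  big <- Mod(z) >= 6
  if (any(!big)) {
    zs <- z[!big]
    w[!big] <- exp(-zs^2) * (1 - pracma::erfz(-1i * zs))
  }
  if (any(big)) {
    zb <- z[big]
    r <- complex(length.out = length(zb))
    for (k in 30:1) r <- (k / 2) / (zb - r)
    w[big] <- (1i / sqrt(pi)) / (zb - r)
  }
  w
}

#' Peak-normalised Voigt line profile
#'
#' Convolution of a Gaussian (standard deviation `sigma`) and a Lorentzian
#' (half-width at half-maximum `gamma`), scaled so that the value at `center`
#' equals `amplitude`. This peak-height convention is used throughout the
#' package: synthetic band amplitudes and perturbation bumps are read off as
#' peak intensities. Limiting cases (`gamma = 0` Gaussian, `sigma = 0`
#' Lorentzian) are computed in closed form.
#'
#' @param x wavenumbers (cm^-1) at which to evaluate.
#' @param center line center (cm^-1).
#' @param sigma Gaussian standard deviation (cm^-1), `>= 0`.
#' @param gamma Lorentzian HWHM (cm^-1), `>= 0`. `sigma` and `gamma` must not
#'   both be zero.
#' @param amplitude peak height (arbitrary units).
#' @return numeric vector of intensities, same length as `x`.
#' @examples
#' g <- wavenumber_grid()
#' y <- voigt_profile(as.numeric(g), 1003, sigma = 4, gamma = 2)
#' @export
voigt_profile <- function(x, center, sigma, gamma, amplitude = 1) {
  stop_if_not_scalar_number(center, "center")
  stop_if_not_scalar_number(sigma, "sigma")
  stop_if_not_scalar_number(gamma, "gamma")
  if (sigma < 0 || gamma < 0) stop("'sigma' and 'gamma' must be non-negative")
  if (sigma == 0 && gamma == 0) {
    stop("'sigma' and 'gamma' must not both be zero (degenerate line shape)")
  }
  x <- as.numeric(x)
  if (gamma == 0) {
    return(amplitude * exp(-((x - center)^2) / (2 * sigma^2)))
  }
  if (sigma == 0) {
    return(amplitude * gamma^2 / ((x - center)^2 + gamma^2))
  }
  z <- ((x - center) + 1i * gamma) / (sigma * sqrt(2))
  z0 <- complex(real = 0, imaginary = gamma / (sigma * sqrt(2)))
  val <- Re(faddeeva(z))
  peak <- Re(faddeeva(z0))
  amplitude * val / peak
}

# split a target Voigt FWHM into (sigma, gamma) given the Lorentzian fraction
# eta of the total width, inverting the Olivero-Longbothum approximation
# f_V ~ 0.5346 f_L + sqrt(0.2166 f_L^2 + f_G^2)
voigt_params_from_fwhm <- function(fwhm, eta = 0.3) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  f_l <- eta * fwhm
  f_g2 <- (fwhm - 0.5346 * f_l)^2 - 0.2166 * f_l^2
  f_g <- sqrt(max(f_g2, 0))
  list(sigma = f_g / (2 * sqrt(2 * log(2))), gamma = f_l / 2)
}

# evaluate a band's peak-normalised shape on a grid
band_shape <- function(band, x) {
  shape <- band$shape %||% "voigt"
  switch(shape,
    gaussian = voigt_profile(x, band$center,
      sigma = band$fwhm / (2 * sqrt(2 * log(2))), gamma = 0),
    lorentzian = voigt_profile(x, band$center, sigma = 0, gamma = band$fwhm / 2),
    voigt = {
      p <- voigt_params_from_fwhm(band$fwhm, eta = band$eta %||% 0.3)
      voigt_profile(x, band$center, sigma = p$sigma, gamma = p$gamma)
    },
    stop("unknown band shape: ", shape)
  )
}
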