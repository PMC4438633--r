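# von Mises sampling (Best & Fisher rejection method). Used on the
# doubled-angle circle to draw axial fiber orientations; kappa = 0 falls back
# to the uniform circular distribution.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(runif(1) - 0.5) * acos(max(-1, min(1, f)))) %% (2 * pi)
    }
  }
  out
}

# Draw n axial orientations in degrees on [0, 180) concentrated around
# mean_angle_deg with concentration kappa (von Mises on doubled angles).
raxial_deg <- function(n, mean_angle_deg, kappa) {
  phi <- rvonmises(n, 2 * mean_angle_deg * pi / 180, kappa)
  (phi / 2 * 180 / pi) %% 180
}

#' Circular variance of axial angles
#'
#' Variance of the doubled angles on the circle: `1 - |mean(exp(2i * theta))|`.
#' 0 for perfectly co-oriented axes, approaching 1 for uniform orientations.
#'
#' @param angles_deg Axial angles in degrees (interpreted mod 180).
#' @return Circular variance in `[0, 1]`.
#' @export
axial_circular_variance <- function(angles_deg) {
  z <- exp(2i * angles_deg * pi / 180)
  1 - Mod(mean(z))
}
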