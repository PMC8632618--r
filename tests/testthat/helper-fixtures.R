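# Shared fixtures: small grids and bases keep unit tests fast; the
# full-size 465-point band is reserved for the acceptance suite.

tiny_grid <- function(n = 60) analysis_grid(490, 620, n)

tiny_basis <- function(grid = tiny_grid(), seed = 1) {
  make_synthetic_basis(grid, seed = seed)
}

# Variable-projection oracle for the chromophore + scattering fit: brute
# 1-D grid over the scattering power beta with a non-negative linear solve
# for the four amplitudes at each grid value. Independent of the package's
# Levenberg-Marquardt path; exact when the true beta lies on the grid.
vp_oracle <- function(mu_t, basis, beta_grid = seq(0, 10, by = 0.01)) {
  A <- as.matrix(as.data.frame(basis)[, c("Hb", "HbO2", "metHb")])
  wl <- basis$wavelength_nm
  y <- mu_t$value
  best <- NULL
  for (b in beta_grid) {
    M <- cbind(A, (wl / 550)^(-b))
    amp <- pracma::lsqnonneg(M, y)$x
    sse <- sum((y - M %*% amp)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(theta = c(amp, b), sse = sse)
    }
  }
  best
}

# Closed-form simple linear regression via normal equations, for checking
# the attenuation estimator against an independent route.
ols_by_hand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}
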