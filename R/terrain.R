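# Synthetic terrain: spectrally filtered white noise rescaled to the
# configured relief. Gives a smooth, seeded, mountainous elevation field
# with correlation length about 1/20 of the district side.

#' Generate a synthetic elevation grid
#'
#' White noise smoothed with a (circular) Gaussian filter in the Fourier
#' domain, then linearly rescaled so that `max - min` equals
#' `cfg$terrain_relief` exactly, sitting on a 300 m base elevation. A relief
#' of 0 yields a constant grid.
#'
#' @param cfg a [district_config()].
#' @return a `terrain_grid`.
#' @export
generate_terrain <- function(cfg) {
  if (!inherits(cfg, "district_config")) wa_stop("`cfg` must be a district_config")
  n <- cfg$grid_size
  base_elev <- 300
  vals <- with_seed(cfg$seed + 101L, {
    noise <- matrix(stats::rnorm(n * n), n, n)
    smooth <- gaussian_smooth(noise, sigma = max(2, n / 20))
    rng <- range(smooth)
    if (cfg$terrain_relief == 0 || rng[2] == rng[1]) {
      matrix(base_elev, n, n)
    } else {
      base_elev + (smooth - rng[1]) / (rng[2] - rng[1]) * cfg$terrain_relief
    }
  })
  spatial_grid(vals, origin = c(0, 0), cell_size = cfg$cell_size)
}

# circular Gaussian smoothing via 2-D FFT; sigma in cells
gaussian_smooth <- function(m, sigma) {
  n <- nrow(m); p <- ncol(m)
  # wrapped distance to (1,1) along each axis
  dx <- pmin(0:(p - 1), p - (0:(p - 1)))
  dy <- pmin(0:(n - 1), n - (0:(n - 1)))
  kern <- exp(-outer(dy^2, dx^2, "+") / (2 * sigma^2))
  kern <- kern / sum(kern)
  out <- Re(stats::fft(stats::fft(m) * stats::fft(kern), inverse = TRUE)) / (n * p)
  out
}
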