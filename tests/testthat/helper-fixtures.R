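# Shared fixtures built in code at test time.

# Published construct parameterisations used throughout the tests
dsdna_model <- function() polymer_model("ewlc", L = 530, p = 50, K = 1000)
bundle_model <- function() polymer_model("efjc", L = 485, K = 10000,
                                         n_segments = 2)
ssdna_model <- function() polymer_model("wlc", L = 15, p = 1)

# Analytic two-Gaussian density on the histogram grid convention
mixture_histogram <- function(sep, mode_sd, bin_width = 0.25,
                              pad = 5, w = c(0.5, 0.5)) {
  grid <- seq(-pad, sep + pad, by = bin_width)
  d <- w[1] * dnorm(grid, 0, mode_sd) + w[2] * dnorm(grid, sep, mode_sd)
  d <- d / (sum(d) * bin_width)
  structure(data.frame(bin_center = grid, count = NA_integer_, density = d),
            bin_width = bin_width,
            class = c("defl_histogram", "data.frame"))
}

# Evaluate a histogram's density at given bin centers (0 outside support)
density_on <- function(h, centers) {
  bw <- attr(h, "bin_width")
  idx <- match(round((centers - h$bin_center[1]) / bw),
               round((h$bin_center - h$bin_center[1]) / bw))
  out <- h$density[idx]
  out[is.na(out)] <- 0
  out
}

# L2 error of a deconvolved density against the truth, over the union grid
l2_error <- function(dec, truth) {
  centers <- sort(union(round(dec$bin_center, 9), round(truth$bin_center, 9)))
  d <- density_on(dec, centers)
  p <- density_on(truth, centers)
  sqrt(sum((d - p)^2) / sum(p^2))
}

# Histogram-mode positions above a fraction of the peak
mode_positions <- function(h, frac = 0.2) {
  d <- h$density
  n <- length(d)
  idx <- which(d[2:(n - 1)] >= d[1:(n - 2)] & d[2:(n - 1)] > d[3:n]) + 1L
  idx <- idx[d[idx] >= frac * max(d)]
  h$bin_center[idx]
}

# Constant-distance simulation settings used for kinetics/landscape work:
# large Metropolis steps decorrelate the bead modes and a high MC rate
# emulates the finite measurement bandwidth (many MC samples averaged per
# output sample).
cd_config <- function(preset, seed, mc_rate = 1e6, step = 3) {
  cfg <- preset_config(preset, seed = seed)
  cfg$mc_rate <- mc_rate
  cfg$step_size <- step
  cfg
}
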