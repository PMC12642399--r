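# Shared fixtures and independent oracles, built in code at test time.

# Independent bisection oracle for the 1:1 equilibrium: root of
# h(F) = F^2 + (kd + K - C) F - kd C on [0, C], where h(0) <= 0 and
# h(C) = C K >= 0.
bisect_free_cargo <- function(C, K, kd, iter = 200) {
  if (C == 0) return(0)
  h <- function(f) f^2 + (kd + K - C) * f - kd * C
  lo <- 0
  hi <- C
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (h(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Independent fixed-point oracle: damped iteration of
# F <- kd C / (kd + K - C + F), the mass-action/mass-balance rearrangement.
fixed_point_free_cargo <- function(C, K, kd, tol = 1e-12, damp = 0.05) {
  f <- C
  for (i in seq_len(1e6)) {
    f_new <- (1 - damp) * f + damp * kd * C / (kd + K - C + f)
    if (abs(f_new - f) < tol * damp) return(f_new)
    f <- f_new
  }
  stop("fixed-point oracle did not converge")
}

# Log-spaced bin edges over a cartridge window.
log_edges <- function(lo, hi, n = 64) exp(seq(log(lo), log(hi),
                                              length.out = n + 1))

# Replicate set of constant-density distributions.
constant_replicates <- function(value, cartridge, n = 3, n_bins = 64) {
  win <- if (cartridge == "C400") c(70, 400) else c(250, 2000)
  edges <- log_edges(win[1], win[2], n_bins)
  replicate_set(lapply(seq_len(n), function(i)
    size_distribution(edges, rep(value, n_bins), cartridge = cartridge)))
}

# Replicate set of Poisson-noised draws around a lognormal density curve
# (meanlog/sdlog on the diameter in nm), scaled by `scale` counts/ml.
lognormal_replicates <- function(cartridge, meanlog = log(200),
                                 sdlog = 0.8, scale = 1e8, n = 3,
                                 n_bins = 64, volume = 0.005) {
  win <- if (cartridge == "C400") c(70, 400) else c(250, 2000)
  edges <- log_edges(win[1], win[2], n_bins)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- dlnorm(ctr, meanlog, sdlog) * scale
  widths <- diff(edges)
  reps <- lapply(seq_len(n), function(i) {
    counts <- rpois(n_bins, dens * widths * volume)
    size_distribution(edges, counts / (widths * volume),
                      cartridge = cartridge)
  })
  list(set = replicate_set(reps), truth = dens, edges = edges,
       volume = volume)
}

# Probability mass from raw bin masses, through the public API.
pm_from_mass <- function(p, edges = seq(0, length(p))) {
  to_probability(size_distribution(edges, p / diff(edges)), zero_floor = 0)
}

# Default FCS fixtures.
test_geometry <- function() instrument_geometry(r0 = 2e-7, z0 = 1e-6)
test_calibration <- function() fcs_calibration(d_ref = 4.14e-10,
                                               taud_ref = 30e-6)

# Radius whose diffusion time equals `taud` under test_calibration().
radius_for_taud <- function(taud, cal = test_calibration()) {
  taud * 1.380649e-23 * cal$temperature /
    (6 * pi * cal$viscosity * cal$d_ref * cal$taud_ref)
}
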