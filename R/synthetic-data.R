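#' Parameters of the synthetic cluster-size landscape
#'
#' Generative model for the continuum of assembly states of a prion-like
#' RNA-binding protein: monomers (~4 nm), a heavy-tailed spectrum of nano-
#' and mesoscale clusters, an optional flattened ("plateau") regime at
#' ~400--1100 nm, and, above the saturation concentration, a micron-scale
#' condensate mode. The size density is a mixture over diameter d (nm):
#' a lognormal monomer peak, a truncated power-law cluster tail
#' `p(d) ~ d^(-alpha) * exp(-d/lambda)`, a uniform plateau component, and a
#' lognormal condensate mode active only when the free cargo concentration
#' exceeds `csat`.
#'
#' Concentration coupling: mixture weights of the self-assembled components
#' scale with free cargo concentration `c` as `c / (c + weight_half)` (so a
#' cargo-free solution is all monomer), the tail scale grows as
#' `lambda * (c / conc_ref)^(1/3)`, and the total particle concentration is
#' `particles_per_uM * c`. Size distributions therefore depend on the free
#' -- not total -- cargo concentration, the linked-equilibrium structure the
#' analysis is designed to detect.
#'
#' @param monomer_diameter Monomer mode diameter (nm), default 4.
#' @param monomer_sdlog Lognormal width of the monomer peak, default 0.15.
#' @param tail_exponent Power-law exponent alpha, default 2.5.
#' @param tail_scale Exponential cutoff lambda (nm) at the reference
#'   concentration, default 500.
#' @param tail_weight Maximum mixture weight of the cluster tail, default
#'   0.3.
#' @param plateau_range Diameter interval of the flattened regime (nm),
#'   default `c(400, 1100)`.
#' @param plateau_weight Maximum mixture weight of the plateau component,
#'   default 0.02; 0 disables it.
#' @param csat Saturation concentration (uM), default 1; the condensate
#'   mode is active only for free cargo strictly above it.
#' @param condensate_mode_diameter Condensate mode diameter (nm, > 1000),
#'   default 1500.
#' @param condensate_sdlog Lognormal width of the condensate mode, default
#'   0.15.
#' @param condensate_weight Mixture weight of the condensate mode when
#'   active, default 0.05.
#' @param conc_ref Reference concentration for the tail-scale coupling
#'   (uM), default 1.
#' @param particles_per_uM Total particle concentration per uM of free
#'   cargo (particles/ml/uM), default 5e9.
#' @param weight_half Half-saturation concentration of the weight coupling
#'   (uM), default 0.1.
#' @param tail_above_csat_only If `TRUE`, the cluster tail and plateau are
#'   suppressed below `csat`: the style of proteins (e.g. hnRNPA2) that show
#'   minimal subsaturated clustering and heavy tails only above saturation.
#' @return An object of class `landscape_params`.
#' @export
landscape_params <- function(monomer_diameter = 4, monomer_sdlog = 0.15,
                             tail_exponent = 2.5, tail_scale = 500,
                             tail_weight = 0.3,
                             plateau_range = c(400, 1100),
                             plateau_weight = 0.02,
                             csat = 1,
                             condensate_mode_diameter = 1500,
                             condensate_sdlog = 0.15,
                             condensate_weight = 0.05,
                             conc_ref = 1, particles_per_uM = 5e9,
                             weight_half = 0.1,
                             tail_above_csat_only = FALSE) {
  check_scalar(monomer_diameter, "monomer_diameter", min = 0,
               strict_min = TRUE)
  check_scalar(tail_exponent, "tail_exponent")
  check_scalar(tail_scale, "tail_scale", min = 0, strict_min = TRUE)
  check_scalar(csat, "csat", min = 0, strict_min = TRUE)
  check_scalar(condensate_mode_diameter, "condensate_mode_diameter",
               min = 1000, strict_min = TRUE)
  for (w in c(tail_weight, plateau_weight, condensate_weight))
    if (w < 0 || w > 1)
      stop("mixture weights must lie in [0, 1]", call. = FALSE)
  if (tail_weight + plateau_weight + condensate_weight > 1)
    stop("mixture weights must sum to <= 1", call. = FALSE)
  if (length(plateau_range) != 2L || plateau_range[1] >= plateau_range[2] ||
      plateau_range[1] < 70 || plateau_range[2] > 2000)
    stop("plateau_range must be an increasing interval within [70, 2000] nm",
         call. = FALSE)
  structure(
    list(monomer_diameter = monomer_diameter, monomer_sdlog = monomer_sdlog,
         tail_exponent = tail_exponent, tail_scale = tail_scale,
         tail_weight = tail_weight, plateau_range = plateau_range,
         plateau_weight = plateau_weight, csat = csat,
         condensate_mode_diameter = condensate_mode_diameter,
         condensate_sdlog = condensate_sdlog,
         condensate_weight = condensate_weight, conc_ref = conc_ref,
         particles_per_uM = particles_per_uM, weight_half = weight_half,
         tail_above_csat_only = tail_above_csat_only),
    class = "landscape_params"
  )
}

#' Named presets for the landscape generator
#'
#' `"fus"`: high-affinity chaperone binding (Kd 0.05 uM) with subsaturated
#' heavy-tailed clustering. `"fus_p525l"`: the weak-binding disease variant
#' (Kd 0.2 uM), same clustering style. `"hnrnpa2"`: high-affinity binding
#' (Kd 0.05 uM) but heavy tails only above csat (minimal subsaturated
#' clustering), with csat 2 uM.
#'
#' @param preset One of `"fus"`, `"fus_p525l"`, `"hnrnpa2"`.
#' @return List with elements `kd` (uM) and `params`
#'   ([landscape_params()]).
#' @export
landscape_preset <- function(preset = c("fus", "fus_p525l", "hnrnpa2")) {
  preset <- match.arg(preset)
  switch(preset,
    fus = list(kd = 0.05, params = landscape_params()),
    fus_p525l = list(kd = 0.2, params = landscape_params()),
    hnrnpa2 = list(kd = 0.05,
                   params = landscape_params(csat = 2,
                                             tail_above_csat_only = TRUE))
  )
}

# Support of the generated landscape (nm).
.d_min <- 1
.d_max <- 5000

# Unnormalized truncated-power-law tail cdf on a fine log grid; returns a
# function mass(lo, hi) giving normalized per-interval tail mass.
tail_mass_fn <- function(alpha, lambda, d_lo) {
  x <- exp(seq(log(d_lo), log(.d_max), length.out = 4001))
  f <- x^(-alpha) * exp(-x / lambda)
  cum <- cumtrapz(x, f)
  total <- cum[length(cum)]
  cdf <- function(d) {
    d <- pmin(pmax(d, d_lo), .d_max)
    stats::approx(log(x), cum, xout = log(d), rule = 2)$y / total
  }
  function(lo, hi) pmax(cdf(hi) - cdf(lo), 0)
}

#' Generate the cluster-size landscape at a given free cargo concentration
#'
#' Evaluates the mixture weights, effective tail scale and total particle
#' concentration of the landscape model (see [landscape_params()]) at a
#' free cargo concentration, producing a normalized size density over
#' 1--5000 nm.
#'
#' @param cargo_free Free cargo concentration (uM), >= 0.
#' @param params A [landscape_params()].
#' @return An object of class `cluster_landscape` with the evaluated
#'   `weights` (monomer, tail, plateau, condensate), `tail_scale_eff` (nm)
#'   and `total_concentration` (particles/ml); query it with
#'   [landscape_bin_mass()] and [landscape_density()].
#' @export
generate_cluster_landscape <- function(cargo_free, params = landscape_params()) {
  check_scalar(cargo_free, "cargo_free", min = 0)
  if (!inherits(params, "landscape_params"))
    stop("params must be a landscape_params object", call. = FALSE)
  s <- if (cargo_free > 0) cargo_free / (cargo_free + params$weight_half)
       else 0
  suppress <- params$tail_above_csat_only && cargo_free <= params$csat
  w_tail <- if (suppress) 0 else params$tail_weight * s
  w_plat <- if (suppress) 0 else params$plateau_weight * s
  w_cond <- if (cargo_free > params$csat) params$condensate_weight else 0
  w_mono <- 1 - w_tail - w_plat - w_cond
  tail_scale_eff <- params$tail_scale *
    (max(cargo_free, 0) / params$conc_ref)^(1 / 3)
  structure(
    list(cargo_free = cargo_free, params = params,
         weights = c(monomer = w_mono, tail = w_tail, plateau = w_plat,
                     condensate = w_cond),
         tail_scale_eff = tail_scale_eff,
         total_concentration = params$particles_per_uM * cargo_free,
         tail_mass = if (w_tail > 0)
           tail_mass_fn(params$tail_exponent, tail_scale_eff,
                        2 * params$monomer_diameter)
         else function(lo, hi) rep(0, length(lo))),
    class = "cluster_landscape"
  )
}

#' @export
print.cluster_landscape <- function(x, ...) {
  cat(sprintf(
    "cluster_landscape at cargo_free = %.4g uM: weights m/t/p/c = %.3f/%.3f/%.3f/%.3f, tail scale %.4g nm\n",
    x$cargo_free, x$weights[1], x$weights[2], x$weights[3], x$weights[4],
    x$tail_scale_eff))
  invisible(x)
}

#' Per-bin probability mass of a cluster landscape
#'
#' Integrates the landscape density over contiguous diameter bins.
#'
#' @param landscape A [generate_cluster_landscape()] result.
#' @param edges Strictly increasing bin edges (nm), length n + 1.
#' @return Numeric vector of n bin masses.
#' @export
landscape_bin_mass <- function(landscape, edges) {
  p <- landscape$params
  w <- landscape$weights
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  m <- w[["monomer"]] *
    (stats::plnorm(hi, log(p$monomer_diameter), p$monomer_sdlog) -
     stats::plnorm(lo, log(p$monomer_diameter), p$monomer_sdlog))
  if (w[["tail"]] > 0)
    m <- m + w[["tail"]] * landscape$tail_mass(lo, hi)
  if (w[["plateau"]] > 0) {
    pl <- p$plateau_range
    ov <- pmax(pmin(hi, pl[2]) - pmax(lo, pl[1]), 0)
    m <- m + w[["plateau"]] * ov / (pl[2] - pl[1])
  }
  if (w[["condensate"]] > 0)
    m <- m + w[["condensate"]] *
      (stats::plnorm(hi, log(p$condensate_mode_diameter), p$condensate_sdlog) -
       stats::plnorm(lo, log(p$condensate_mode_diameter), p$condensate_sdlog))
  unname(m)
}

#' Probability density of a cluster landscape
#'
#' @param landscape A [generate_cluster_landscape()] result.
#' @param d Diameters (nm).
#' @return Density values (1/nm).
#' @export
landscape_density <- function(landscape, d) {
  p <- landscape$params
  w <- landscape$weights
  out <- w[["monomer"]] * stats::dlnorm(d, log(p$monomer_diameter),
                                        p$monomer_sdlog)
  if (w[["tail"]] > 0) {
    d_lo <- 2 * p$monomer_diameter
    # normalize against the same quadrature the mass function uses
    norm_mass <- landscape$tail_mass(d_lo, .d_max)
    x <- exp(seq(log(d_lo), log(.d_max), length.out = 4001))
    total <- cumtrapz(x, x^(-p$tail_exponent) *
                        exp(-x / landscape$tail_scale_eff))
    total <- total[length(total)]
    f <- ifelse(d >= d_lo & d <= .d_max,
                d^(-p$tail_exponent) * exp(-d / landscape$tail_scale_eff) /
                  total * norm_mass, 0)
    out <- out + w[["tail"]] * f
  }
  if (w[["plateau"]] > 0) {
    pl <- p$plateau_range
    out <- out + w[["plateau"]] *
      ifelse(d >= pl[1] & d <= pl[2], 1 / (pl[2] - pl[1]), 0)
  }
  if (w[["condensate"]] > 0)
    out <- out + w[["condensate"]] *
      stats::dlnorm(d, log(p$condensate_mode_diameter), p$condensate_sdlog)
  out
}

#' Specify an MRPS instrument model
#'
#' A cartridge observes the landscape through its detection window with a
#' log-spaced bin grid; expected per-bin counts are the landscape mass in
#' the bin times the total particle concentration times the sampled volume,
#' and observed counts are Poisson draws around that expectation.
#'
#' @param cartridge `"C400"` (window 70--400 nm) or `"C2000"` (250--2000
#'   nm).
#' @param volume_ml Sampled volume (ml), default 0.005 (a 5 ul injection).
#' @param n_bins Number of log-spaced bins across the window, default 64.
#' @return An object of class `mrps_instrument`.
#' @export
mrps_instrument <- function(cartridge = c("C400", "C2000"),
                            volume_ml = 0.005, n_bins = 64) {
  cartridge <- match.arg(cartridge)
  check_scalar(volume_ml, "volume_ml", min = 0)
  check_scalar(n_bins, "n_bins", min = 2)
  window <- if (cartridge == "C400") c(70, 400) else c(250, 2000)
  structure(
    list(cartridge = cartridge, window = window, volume_ml = volume_ml,
         bin_edges = exp(seq(log(window[1]), log(window[2]),
                             length.out = n_bins + 1))),
    class = "mrps_instrument"
  )
}

#' Expected (pre-noise) density of a landscape seen by an instrument
#'
#' The Poisson expectation of [apply_mrps_instrument()]: landscape bin mass
#' scaled to counts/ml/nm, with no count noise. Two conditions with equal
#' free cargo concentration have identical expected densities -- the
#' linked-equilibrium embedding.
#'
#' @param landscape A [generate_cluster_landscape()] result.
#' @param instrument An [mrps_instrument()].
#' @return Numeric vector of expected densities (counts/ml/nm).
#' @export
expected_density <- function(landscape, instrument) {
  mass <- landscape_bin_mass(landscape, instrument$bin_edges)
  mass * landscape$total_concentration / diff(instrument$bin_edges)
}

#' Observe a landscape through an MRPS cartridge
#'
#' Integrates the landscape over the instrument's bin grid (restricted to
#' the cartridge detection window), scales by total particle concentration
#' and sampled volume, draws Poisson counts, and converts back to
#' counts/ml/nm. Deterministic given `seed`. Assemblies outside the window
#' are invisible: a landscape entirely below 70 nm produces an all-zero
#' C-400 observation.
#'
#' @param landscape A [generate_cluster_landscape()] result.
#' @param instrument An [mrps_instrument()].
#' @param seed Integer seed or `NULL`.
#' @param condition Condition label for the output.
#' @return A [size_distribution()] on the instrument grid.
#' @export
apply_mrps_instrument <- function(landscape, instrument, seed = NULL,
                                  condition = "") {
  if (!inherits(instrument, "mrps_instrument"))
    stop("instrument must be an mrps_instrument", call. = FALSE)
  edges <- instrument$bin_edges
  widths <- diff(edges)
  expected <- landscape_bin_mass(landscape, edges) *
    landscape$total_concentration * instrument$volume_ml
  counts <- if (instrument$volume_ml > 0)
    with_seed(seed, stats::rpois(length(expected), expected))
  else rep(0L, length(expected))
  size_distribution(edges, counts / (instrument$volume_ml * widths +
                                       (instrument$volume_ml == 0)),
                    cartridge = instrument$cartridge, condition = condition)
}

#' Specify a synthetic experimental condition
#'
#' @param cargo_total Total cargo concentration (uM).
#' @param chaperone_total Total chaperone concentration (uM).
#' @param kd Dissociation constant (uM).
#' @param n_replicates Replicates per cartridge, default 3.
#' @param seed Integer master seed for this condition, or `NULL`.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(cargo_total, chaperone_total, kd,
                           n_replicates = 3, seed = NULL) {
  sys <- binding_system(cargo_total, chaperone_total, kd)
  check_scalar(n_replicates, "n_replicates", min = 1)
  structure(
    list(system = sys, n_replicates = as.integer(n_replicates), seed = seed),
    class = "condition_spec"
  )
}

#' Generate replicate MRPS observations for one condition
#'
#' Computes the free cargo concentration for the condition via
#' [solve_equilibrium()], builds the landscape from that free concentration
#' alone, and draws independent instrument observations, one per replicate,
#' with per-replicate sub-seeds derived from the condition seed. Because the
#' landscape depends only on free cargo, two conditions with equal free
#' cargo concentrations have identical expected (pre-noise) densities.
#'
#' @param spec A [condition_spec()].
#' @param params A [landscape_params()].
#' @param instrument An [mrps_instrument()].
#' @param condition Condition label; defaults to a summary of the spec.
#' @return A [replicate_set()].
#' @export
generate_replicates <- function(spec, params = landscape_params(),
                                instrument = mrps_instrument("C400"),
                                condition = NULL) {
  if (!inherits(spec, "condition_spec"))
    stop("spec must be a condition_spec", call. = FALSE)
  eq <- solve_equilibrium(spec$system)
  if (is.null(condition))
    condition <- sprintf("cargo%.4g_chap%.4g",
                         spec$system$cargo_total,
                         spec$system$chaperone_total)
  landscape <- generate_cluster_landscape(eq$cargo_free, params)
  seeds <- derive_seeds(spec$seed, spec$n_replicates)
  reps <- lapply(seeds, function(s)
    apply_mrps_instrument(landscape, instrument, seed = s,
                          condition = condition))
  out <- replicate_set(reps, condition = condition)
  attr(out, "cargo_free") <- eq$cargo_free
  out
}

#' Generate a synthetic FCS autocorrelation trace
#'
#' Converts each hydrodynamic radius to a diffusion time by inverting the
#' Stokes--Einstein calibration scaling, sums amplitude-weighted
#' single-component decays, and adds Gaussian noise. A single-component
#' mixture with zero noise round-trips exactly through
#' [fit_autocorrelation()].
#'
#' @param radii Hydrodynamic radii (m), > 0.
#' @param weights Mixture weights summing to 1; default equal weights.
#' @param geometry An [instrument_geometry()].
#' @param cal An [fcs_calibration()].
#' @param lags Lag times (s); default 50 log-spaced points over 1e-6--1 s.
#' @param n_particles Total particle number N in the detection volume,
#'   default 1.
#' @param noise_sd Standard deviation of additive Gaussian noise on G,
#'   default 0.
#' @param seed Integer seed or `NULL`.
#' @return An [autocorrelation_trace()].
#' @export
generate_fcs_trace <- function(radii, weights = NULL, geometry, cal,
                               lags = exp(seq(log(1e-6), log(1),
                                              length.out = 50)),
                               n_particles = 1, noise_sd = 0, seed = NULL) {
  if (length(radii) < 1L || any(!is.finite(radii)) || any(radii <= 0))
    stop("radii must be a non-empty vector of positive lengths",
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(radii), length(radii))
  if (length(weights) != length(radii) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must match radii and sum to 1", call. = FALSE)
  tauds <- radii * 6 * pi * cal$viscosity * cal$d_ref * cal$taud_ref /
    (.kB * cal$temperature)
  decay <- rowSums(vapply(seq_along(radii), function(i) {
    x <- lags / tauds[i]
    weights[i] / (1 + x) / sqrt(1 + x * geometry$kappa)
  }, numeric(length(lags))))
  g <- 1 + decay / n_particles
  if (noise_sd > 0)
    g <- g + with_seed(seed, stats::rnorm(length(g), sd = noise_sd))
  autocorrelation_trace(lags, g,
                        sd = if (noise_sd > 0) rep(noise_sd, length(g))
                             else NULL)
}

#' Generate the matched-concentration condition grid
#'
#' The matched-comparison experimental design: for each total chaperone
#' level, a mixture condition (fixed total cargo, that chaperone level) and
#' its matched cargo-only condition at the computed free cargo
#' concentration are both observed, with every requested instrument. All
#' sub-seeds are derived from the master seed and recorded.
#'
#' @param cargo_total Total cargo concentration (uM).
#' @param chaperone_levels Ascending total chaperone concentrations (uM).
#' @param kd Dissociation constant (uM).
#' @param params A [landscape_params()].
#' @param instruments A single [mrps_instrument()] or a list of them
#'   (default: both cartridges), named by cartridge.
#' @param n_replicates Replicates per condition per instrument, default 3.
#' @param seed Master seed.
#' @return An object of class `condition_grid`: list with `levels`,
#'   `cargo_free`, `matched_concentration`, and per-level lists `mixture`
#'   and `matched` of [replicate_set()]s (named by cartridge when several
#'   instruments are used), plus the seed table.
#' @export
generate_condition_grid <- function(cargo_total, chaperone_levels, kd,
                                    params = landscape_params(),
                                    instruments = list(
                                      C400 = mrps_instrument("C400"),
                                      C2000 = mrps_instrument("C2000")),
                                    n_replicates = 3, seed = NULL) {
  curve <- free_cargo_curve(cargo_total, chaperone_levels, kd)
  single <- inherits(instruments, "mrps_instrument")
  if (single) instruments <- list(instruments)
  n_lev <- length(chaperone_levels)
  n_inst <- length(instruments)
  seeds <- derive_seeds(seed, 2L * n_lev * n_inst)
  k <- 0L
  mixture <- vector("list", n_lev)
  matched <- vector("list", n_lev)
  for (i in seq_len(n_lev)) {
    mix_i <- vector("list", n_inst)
    mat_i <- vector("list", n_inst)
    for (j in seq_len(n_inst)) {
      k <- k + 1L
      mix_i[[j]] <- generate_replicates(
        condition_spec(cargo_total, chaperone_levels[i], kd, n_replicates,
                       seed = seeds[[k]]),
        params, instruments[[j]],
        condition = sprintf("mix_chap%.4g", chaperone_levels[i]))
      k <- k + 1L
      mat_i[[j]] <- generate_replicates(
        condition_spec(curve$cargo_free_uM[i], 0, kd, n_replicates,
                       seed = seeds[[k]]),
        params, instruments[[j]],
        condition = sprintf("cargo_only_%.4g", curve$cargo_free_uM[i]))
    }
    names(mix_i) <- names(mat_i) <- names(instruments)
    mixture[[i]] <- if (single) mix_i[[1]] else mix_i
    matched[[i]] <- if (single) mat_i[[1]] else mat_i
  }
  structure(
    list(levels = chaperone_levels, cargo_total = cargo_total, kd = kd,
         cargo_free = curve$cargo_free_uM,
         matched_concentration = curve$cargo_free_uM,
         mixture = mixture, matched = matched,
         seed = seed, sub_seeds = unlist(seeds)),
    class = "condition_grid"
  )
}

#' @export
print.condition_grid <- function(x, ...) {
  cat(sprintf(
    "condition_grid: cargo_total %.4g uM, Kd %.4g uM, %d chaperone levels\n",
    x$cargo_total, x$kd, length(x$levels)))
  print(data.frame(chaperone_total_uM = x$levels,
                   cargo_free_uM = signif(x$cargo_free, 3)))
  invisible(x)
}
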