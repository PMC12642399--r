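test_that("the landscape density is normalized and concentration-coupled", {
  edges <- exp(seq(log(1), log(5000), length.out = 4001))
  for (cf in c(0, 0.3, 1.5, 3)) {
    ls <- generate_cluster_landscape(cf)
    expect_equal(sum(landscape_bin_mass(ls, edges)), 1, tolerance = 1e-6)
    expect_equal(sum(ls$weights), 1)
  }
  # no cargo: all mass at the monomer peak
  ls0 <- generate_cluster_landscape(0)
  expect_equal(unname(ls0$weights[["monomer"]]), 1)
  expect_equal(ls0$total_concentration, 0)
  expect_gt(sum(landscape_bin_mass(ls0, c(1, 10))), 0.999)
  # condensate mode present iff free cargo strictly exceeds csat
  above <- generate_cluster_landscape(1.5)
  at <- generate_cluster_landscape(1)
  expect_gt(above$weights[["condensate"]], 0)
  expect_equal(unname(at$weights[["condensate"]]), 0)
  # tail scale grows with free cargo
  expect_gt(generate_cluster_landscape(2)$tail_scale_eff,
            generate_cluster_landscape(0.5)$tail_scale_eff)
})

test_that("plateau weight controls the mesoscale flatness flag", {
  inst <- mrps_instrument("C2000")
  with_plateau <- apply_mrps_instrument(
    generate_cluster_landscape(0.9, landscape_params()), inst, seed = 8)
  without <- apply_mrps_instrument(
    generate_cluster_landscape(0.9, landscape_params(plateau_weight = 0)),
    inst, seed = 8)
  expect_true(flatness_metric(with_plateau)$flat)
  expect_false(flatness_metric(without)$flat)
})

test_that("the hnRNPA2-style preset suppresses subsaturated tails", {
  p <- landscape_preset("hnrnpa2")
  below <- generate_cluster_landscape(1.5, p$params)  # below csat = 2
  above <- generate_cluster_landscape(2.5, p$params)
  expect_equal(unname(below$weights[["tail"]]), 0)
  expect_gt(above$weights[["tail"]], 0)
  expect_equal(landscape_preset("fus")$kd, 0.05)
  expect_equal(landscape_preset("fus_p525l")$kd, 0.2)
})

test_that("the instrument window bounds what can be observed", {
  # landscape entirely below 70 nm: monomer-only (no clusters)
  ls_small <- generate_cluster_landscape(0)
  ls_small$total_concentration <- 1e9  # particles exist, but all tiny
  obs <- apply_mrps_instrument(ls_small, mrps_instrument("C400"), seed = 2)
  expect_true(all(obs$density == 0))
  # mass above 2000 nm never appears in C-2000 output
  big <- landscape_params(condensate_mode_diameter = 2500,
                          condensate_weight = 0.5, tail_weight = 0,
                          plateau_weight = 0)
  obs2 <- apply_mrps_instrument(generate_cluster_landscape(3, big),
                                mrps_instrument("C2000"), seed = 3)
  expect_lte(max(obs2$bin_edges), 2000)
  # zero sampled volume: zero counts
  obs3 <- apply_mrps_instrument(generate_cluster_landscape(2),
                                mrps_instrument("C400", volume_ml = 0),
                                seed = 4)
  expect_true(all(obs3$density == 0))
})

test_that("instrument observations are Poisson around the expected density", {
  ls <- generate_cluster_landscape(1.5)
  inst <- mrps_instrument("C400")
  expec <- expected_density(ls, inst)
  obs <- sapply(1:200, function(s)
    apply_mrps_instrument(ls, inst, seed = s)$density)
  avg <- rowMeans(obs)
  widths <- diff(inst$bin_edges)
  se <- sqrt(expec / (widths * inst$volume_ml)) / sqrt(200)
  keep <- expec > 0
  expect_true(all(abs(avg - expec)[keep] < 5 * se[keep]))
})

test_that("replicate generation embeds the linked-equilibrium hypothesis", {
  params <- landscape_params()
  inst <- mrps_instrument("C400")
  # same free cargo from different (total cargo, chaperone): 2 uM with
  # 1 uM chaperone gives ~1.046 uM free, matching a cargo-only sample
  cf <- solve_equilibrium(binding_system(2, 1, 0.05))$cargo_free
  mix <- generate_cluster_landscape(cf, params)
  alone <- generate_cluster_landscape(
    solve_equilibrium(binding_system(cf, 0, 0.05))$cargo_free, params)
  expect_equal(expected_density(mix, inst), expected_density(alone, inst))
  # generate_replicates reports the free concentration and the grid shape
  rs <- generate_replicates(condition_spec(2, 1, 0.05, seed = 5), params,
                            inst)
  expect_equal(attr(rs, "cargo_free"), cf)
  expect_length(rs$replicates, 3)
  # doubling free cargo stochastically enlarges the pre-noise density
  lo <- expected_density(generate_cluster_landscape(0.5, params), inst)
  hi <- expected_density(generate_cluster_landscape(1, params), inst)
  expect_true(all(hi >= lo))
})

test_that("generators are pure functions of inputs and seed", {
  params <- landscape_params()
  inst <- mrps_instrument("C2000")
  ls <- generate_cluster_landscape(1.2, params)
  expect_identical(apply_mrps_instrument(ls, inst, seed = 7)$density,
                   apply_mrps_instrument(ls, inst, seed = 7)$density)
  geom <- test_geometry()
  cal <- test_calibration()
  t1 <- generate_fcs_trace(5e-9, geometry = geom, cal = cal,
                           noise_sd = 0.01, seed = 9)
  t2 <- generate_fcs_trace(5e-9, geometry = geom, cal = cal,
                           noise_sd = 0.01, seed = 9)
  expect_identical(t1$g_values, t2$g_values)
  # seeded generation does not disturb the caller's RNG stream
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(generate_fcs_trace(5e-9, geometry = geom, cal = cal,
                               noise_sd = 0.01, seed = 9))
  expect_identical(runif(1), a)
})

test_that("two-component traces fit between the component diffusion times", {
  geom <- test_geometry()
  cal <- test_calibration()
  r <- c(2e-9, 40e-9)
  tr <- generate_fcs_trace(r, weights = c(0.5, 0.5), geometry = geom,
                           cal = cal, n_particles = 3)
  fit <- fit_autocorrelation(tr, geom)
  tauds <- r * 6 * pi * cal$viscosity * cal$d_ref * cal$taud_ref /
    (1.380649e-23 * cal$temperature)
  expect_true(fit$converged)
  expect_gt(fit$taud, min(tauds))
  expect_lt(fit$taud, max(tauds))
})

test_that("the condition grid implements the matched-comparison design", {
  grid <- generate_condition_grid(2, c(0, 1, 2, 4, 6), 0.05,
                                  instruments = mrps_instrument("C400"),
                                  n_replicates = 2, seed = 31)
  expect_equal(signif(grid$matched_concentration, 2),
               c(2, 1.0, 0.29, 0.048, 0.025))
  expect_length(grid$mixture, 5)
  expect_length(grid$matched, 5)
  expect_true(all(vapply(c(grid$mixture, grid$matched), inherits,
                         logical(1), "replicate_set")))
  # chaperone level 0: mixture and matched coincide in expectation
  g0 <- generate_condition_grid(2, 0, 0.05,
                                instruments = mrps_instrument("C400"),
                                seed = 32)
  expect_equal(attr(g0$mixture[[1]], "cargo_free"),
               attr(g0$matched[[1]], "cargo_free"))
})
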