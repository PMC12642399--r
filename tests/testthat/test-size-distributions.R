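test_that("distribution tables round-trip through the reader", {
  # uniform grid: midpoint reconstruction recovers every edge exactly
  edges <- seq(70, 400, length.out = 101)
  set.seed(7)
  reps <- lapply(1:2, function(i)
    size_distribution(edges, rpois(100, 50), cartridge = "C400"))
  rs <- replicate_set(reps, condition = "demo")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distribution_table(rs, path)
  back <- read_distribution_table(path, cartridge = "C400",
                                  condition = "demo")
  expect_length(back$replicates, 2)
  expect_equal(back$bin_edges, edges, tolerance = 1e-9)
  expect_equal(replicate_matrix(back)[, 1], reps[[1]]$density,
               tolerance = 1e-6)
  # log-spaced grid: centers are not exact edge midpoints, so edges come
  # back approximately (well under a bin width) and densities exactly
  ledges <- log_edges(70, 400, 64)
  lrs <- replicate_set(list(size_distribution(ledges, rpois(64, 50),
                                              cartridge = "C400")))
  write_distribution_table(lrs, path)
  lback <- read_distribution_table(path, cartridge = "C400")
  expect_equal(lback$bin_edges, ledges, tolerance = 1e-3)
  expect_equal(replicate_matrix(lback)[, 1],
               lrs$replicates[[1]]$density, tolerance = 1e-6)
})

test_that("the reader rejects malformed tables with line information", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("diameter_nm,rep1", "100,5", "110,-2", "120,1"), path)
  expect_error(read_distribution_table(path), "line 3.*negative|negative")
  writeLines(c("diameter_nm,rep1", "100,5", "90,2"), path)
  expect_error(read_distribution_table(path), "increasing")
  writeLines(c("diameter_nm,rep1", "100,5", "110"), path)
  expect_error(read_distribution_table(path), "line 3")
  writeLines(character(0), path)
  expect_error(read_distribution_table(path), "parse error")
})

test_that("rebinning conserves particle content", {
  # identity grid
  edges <- c(0, 1, 2, 3)
  d <- size_distribution(edges, c(4, 6, 2))
  expect_equal(rebin_to_common_grid(d, edges)$density, c(4, 6, 2))
  # merging two adjacent equal-width bins averages densities
  expect_equal(rebin_to_common_grid(
    size_distribution(c(0, 1, 2), c(4, 6)), c(0, 2))$density, 5)
  # splitting a bin preserves density (uniform-within-bin)
  expect_equal(rebin_to_common_grid(
    size_distribution(c(0, 2), 3), c(0, 1, 2))$density, c(3, 3))
  # randomized grids: total count on the overlap is conserved
  set.seed(11)
  for (i in 1:50) {
    src <- sort(runif(12, 0, 100))
    dens <- runif(11, 0, 10)
    tgt <- sort(runif(8, min(src), max(src)))
    d <- size_distribution(src, dens)
    r <- rebin_to_common_grid(d, tgt)
    # counts of the source restricted to [min(tgt), max(tgt)]
    clip <- rebin_to_common_grid(d, range(tgt))
    expect_equal(sum(r$density * diff(tgt)),
                 clip$density * diff(range(tgt)), tolerance = 1e-9)
  }
  expect_error(rebin_to_common_grid(d, c(200, 300)), "overlap")
})

test_that("to_probability floors zeros and normalizes", {
  d <- size_distribution(c(0, 1, 2, 3), c(0, 10, 30))
  p <- to_probability(d, zero_floor = 1e-5)
  expect_equal(p$p, c(2.5e-7, 0.25, 0.75), tolerance = 1e-6)
  expect_equal(sum(p$p), 1, tolerance = 1e-12)
  expect_true(all(p$p > 0))
  # uniform positive densities on equal bins stay uniform
  u <- to_probability(size_distribution(0:5, rep(3, 5)))
  expect_equal(u$p, rep(0.2, 5))
  # scale invariance for strictly positive inputs
  d1 <- size_distribution(c(0, 1, 4), c(2, 5))
  expect_equal(to_probability(d1)$p,
               to_probability(size_distribution(c(0, 1, 4), c(2, 5) * 17))$p)
  # floor has no effect on strictly positive input
  expect_equal(to_probability(d1, zero_floor = 1e-5)$p,
               to_probability(d1, zero_floor = 0)$p)
  expect_error(to_probability(size_distribution(0:3, rep(0, 3)),
                              zero_floor = 0), "all-zero")
})

test_that("kl_divergence matches direct summation and Gibbs' inequality", {
  P <- pm_from_mass(c(0.5, 0.5))
  Q <- pm_from_mass(c(0.25, 0.75))
  expect_equal(kl_divergence(P, P), 0)
  expect_equal(kl_divergence(P, Q), 0.1438, tolerance = 1e-3)
  expect_equal(kl_divergence(Q, P), 0.1308, tolerance = 1e-3)
  # direct-summation oracle on randomized mass pairs, plus non-negativity
  set.seed(12)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    a <- rexp(n) + 1e-8
    b <- rexp(n) + 1e-8
    P <- pm_from_mass(a)
    Q <- pm_from_mass(b)
    direct <- sum((a / sum(a)) * log((a / sum(a)) / (b / sum(b))))
    expect_equal(kl_divergence(P, Q), direct, tolerance = 1e-12)
    expect_gte(kl_divergence(P, Q), 0)
  }
  expect_error(kl_divergence(P, pm_from_mass(c(1, 2, 3, 4, 5))), "grid")
})

test_that("kl_profile is query-vs-reference and tracks drift", {
  ref_mass <- c(5, 3, 2, 1)
  other <- c(1, 2, 3, 5)
  ref <- pm_from_mass(ref_mass)
  expect_equal(kl_profile(ref, list(ref)), 0)
  qs <- lapply(seq(0, 1, by = 0.2), function(t)
    pm_from_mass((1 - t) * ref_mass / sum(ref_mass) +
                   t * other / sum(other)))
  prof <- kl_profile(ref, qs)
  expect_equal(prof[1], 0)
  expect_true(all(diff(prof) >= 0))
})

test_that("flatness metric separates plateaus from exponential decay", {
  edges <- seq(300, 1300, by = 20)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  flat <- flatness_metric(size_distribution(edges, rep(4, 50)))
  expect_lt(flat$slope, 1e-10)
  expect_true(flat$flat)
  dec <- flatness_metric(size_distribution(edges, exp(-ctr / 100)))
  expect_equal(dec$slope, 0.01, tolerance = 1e-6)
  expect_false(dec$flat)
  expect_error(flatness_metric(size_distribution(c(0, 1, 2), c(1, 1))),
               "3 bins")
})

test_that("merging degenerate constant replicates returns the constant", {
  m <- merge_cartridges(constant_replicates(100, "C400"),
                        constant_replicates(100, "C2000"),
                        n_boot = 50, seed = 5)
  expect_equal(m$mean, rep(100, length(m$mean)), tolerance = 1e-9)
  expect_equal(max(m$spread), 0, tolerance = 1e-9)
})

test_that("merging is deterministic given the seed", {
  s <- lognormal_replicates("C400")
  l <- lognormal_replicates("C2000")
  m1 <- merge_cartridges(s$set, l$set, n_boot = 40, seed = 99)
  m2 <- merge_cartridges(s$set, l$set, n_boot = 40, seed = 99)
  expect_identical(m1, m2)
  m3 <- merge_cartridges(s$set, l$set, n_boot = 40, seed = 100)
  expect_false(identical(m1$mean, m3$mean))
})

test_that("merged means recover the generating density in exclusive ranges", {
  set.seed(21)
  s <- lognormal_replicates("C400", scale = 1e8)
  l <- lognormal_replicates("C2000", scale = 1e8)
  m <- merge_cartridges(s$set, l$set, n_boot = 1000, seed = 1)
  ctr <- (m$bin_edges[-1] + m$bin_edges[-length(m$bin_edges)]) / 2
  truth <- dlnorm(ctr, log(200), 0.8) * 1e8
  # per-bin Poisson standard error of a replicate mean, on the merged grid
  widths <- diff(m$bin_edges)
  se <- sqrt(truth / (widths * 0.005 * 3))
  excl <- (ctr > 80 & ctr < 240) | (ctr > 420 & ctr < 1800)
  dev <- abs(m$mean - truth)[excl]
  expect_true(mean(dev <= 3 * pmax(se[excl], 1)) > 0.9)
})

test_that("merge validates its inputs", {
  s <- constant_replicates(10, "C400")
  l <- constant_replicates(10, "C2000")
  expect_error(merge_cartridges(s, l, n_boot = 0), "n_boot")
  expect_error(merge_cartridges(s, l, subsample_fraction = 0), "fraction")
  expect_error(merge_cartridges(l, s), "70-400|overlap")
})
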