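#' Construct a binned particle-size distribution
#'
#' The MRPS observable: particle number density (counts per ml per nm of
#' diameter) on a grid of contiguous diameter bins. The two instrument
#' cartridges cover 70--400 nm (`"C400"`) and 250--2000 nm (`"C2000"`);
#' merged full-range distributions are labelled `"merged"` and simulated
#' ones `"synthetic"`.
#'
#' @param bin_edges Strictly increasing diameters (nm), length `n + 1`.
#' @param density Non-negative particle densities (counts/ml/nm), length `n`.
#' @param cartridge One of `"C400"`, `"C2000"`, `"merged"`, `"synthetic"`.
#' @param condition Free-text condition label.
#' @return An object of class `size_distribution`.
#' @export
size_distribution <- function(bin_edges, density,
                              cartridge = c("synthetic", "C400", "C2000",
                                            "merged"),
                              condition = "") {
  cartridge <- match.arg(cartridge)
  if (!is.numeric(bin_edges) || length(bin_edges) < 2L ||
      any(!is.finite(bin_edges)))
    stop("bin_edges must be a finite numeric vector of length >= 2",
         call. = FALSE)
  if (any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  if (!is.numeric(density) || length(density) != length(bin_edges) - 1L)
    stop("density must have length length(bin_edges) - 1", call. = FALSE)
  if (any(!is.finite(density)) || any(density < 0))
    stop("density must be finite and >= 0 element-wise", call. = FALSE)
  structure(
    list(bin_edges = as.numeric(bin_edges), density = as.numeric(density),
         cartridge = cartridge, condition = as.character(condition)[1]),
    class = "size_distribution"
  )
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "size_distribution [%s] '%s': %d bins over %.4g-%.4g nm, total %.4g particles/ml\n",
    x$cartridge, x$condition, length(x$density), min(x$bin_edges),
    max(x$bin_edges), sum(x$density * diff(x$bin_edges))))
  invisible(x)
}

# Bin centers of a size_distribution (or any edge vector).
bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Group replicate size distributions measured on one grid
#'
#' @param replicates List of [size_distribution()] objects sharing identical
#'   bin edges and cartridge.
#' @param condition Condition label (defaults to the first replicate's).
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(replicates, condition = NULL) {
  if (!is.list(replicates) || length(replicates) < 1L ||
      !all(vapply(replicates, inherits, logical(1), "size_distribution")))
    stop("replicates must be a non-empty list of size_distribution objects",
         call. = FALSE)
  e1 <- replicates[[1]]$bin_edges
  for (i in seq_along(replicates)) {
    if (!isTRUE(all.equal(replicates[[i]]$bin_edges, e1)))
      stop(sprintf("replicate %d has different bin edges", i), call. = FALSE)
    if (replicates[[i]]$cartridge != replicates[[1]]$cartridge)
      stop(sprintf("replicate %d has a different cartridge", i),
           call. = FALSE)
  }
  if (is.null(condition)) condition <- replicates[[1]]$condition
  structure(
    list(replicates = replicates, condition = as.character(condition)[1],
         cartridge = replicates[[1]]$cartridge, bin_edges = e1),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("replicate_set [%s] '%s': %d replicates x %d bins\n",
              x$cartridge, x$condition, length(x$replicates),
              length(x$bin_edges) - 1L))
  invisible(x)
}

#' Density matrix of a replicate set
#'
#' @param rs A [replicate_set()].
#' @return Numeric matrix of densities (counts/ml/nm), bins in rows and
#'   replicates in columns.
#' @export
replicate_matrix <- function(rs) {
  vapply(rs$replicates, function(d) d$density,
         numeric(length(rs$bin_edges) - 1L))
}

# Reconstruct contiguous bin edges from exported bin centers: interior edges
# at midpoints, end bins symmetric about their centers.
edges_from_centers <- function(centers) {
  n <- length(centers)
  if (n == 1L) {
    # degenerate single-bin table: unit-width bin around the center
    return(c(centers - 0.5, centers + 0.5))
  }
  mid <- (centers[-1] + centers[-n]) / 2
  c(2 * centers[1] - mid[1], mid, 2 * centers[n] - mid[n - 1])
}

#' Read a delimited particle-size distribution table
#'
#' Expects a header row and a first column of bin-center diameters in nm
#' (conventionally named `diameter_nm`), followed by one density column
#' (counts/ml/nm) per replicate. The field separator (comma or tab) is
#' auto-detected. Bin edges are reconstructed from the centers assuming
#' contiguous bins: interior edges at midpoints between consecutive centers,
#' end bins symmetric.
#'
#' @param path Path to the delimited text file.
#' @param cartridge,condition Labels attached to the replicates.
#' @param sep Field separator; `NULL` (default) auto-detects `,` vs tab.
#' @return A [replicate_set()].
#' @export
read_distribution_table <- function(path, cartridge = "synthetic",
                                    condition = "", sep = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("parse error in '%s': need a header and at least one data row",
                 path), call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncol <- length(fields[[1]])
  if (ncol < 2L)
    stop(sprintf("parse error in '%s': need a diameter column and >= 1 density column",
                 path), call. = FALSE)
  bad <- which(vapply(fields, length, integer(1)) != ncol)
  if (length(bad))
    stop(sprintf("parse error in '%s' at line %d: expected %d fields, got %d",
                 path, bad[1], ncol, length(fields[[bad[1]]])), call. = FALSE)
  vals <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = ncol)
  for (i in 2:length(lines)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (any(is.na(v)))
      stop(sprintf("parse error in '%s' at line %d: non-numeric field '%s'",
                   path, i, fields[[i]][which(is.na(v))[1]]), call. = FALSE)
    vals[i - 1L, ] <- v
  }
  centers <- vals[, 1]
  if (any(diff(centers) <= 0)) {
    row <- which(diff(centers) <= 0)[1] + 1L
    stop(sprintf("parse error in '%s' at line %d: diameters not strictly increasing",
                 path, row + 1L), call. = FALSE)
  }
  neg <- which(vals[, -1, drop = FALSE] < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("parse error in '%s' at line %d: negative density in column %d",
                 path, neg[1, 1] + 1L, neg[1, 2] + 1L), call. = FALSE)
  edges <- edges_from_centers(centers)
  reps <- lapply(seq_len(ncol - 1L), function(j)
    size_distribution(edges, vals[, j + 1L], cartridge = cartridge,
                      condition = condition))
  replicate_set(reps, condition = condition)
}

#' Write a replicate set or merged distribution as delimited text
#'
#' Inverse of [read_distribution_table()]: writes bin-center diameters and
#' one column per replicate (or `mean`/`spread` columns for a merged
#' distribution). Round-trips through the reader.
#'
#' @param x A [replicate_set()] or `merged_distribution`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_distribution_table <- function(x, path, sep = "\t") {
  if (inherits(x, "replicate_set")) {
    m <- replicate_matrix(x)
    colnames(m) <- paste0("rep", seq_len(ncol(m)))
    df <- data.frame(diameter_nm = bin_centers(x$bin_edges), m)
  } else if (inherits(x, "merged_distribution")) {
    df <- data.frame(diameter_nm = bin_centers(x$bin_edges),
                     mean_counts_per_ml_per_nm = x$mean,
                     spread = x$spread)
  } else stop("x must be a replicate_set or merged_distribution",
              call. = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Overlap matrix M (n_target x n_source): M[i, j] is the fraction of source
# bin j's width covered by target bin i, so counts_target = M %*%
# counts_source redistributes particle content proportionally to overlap
# length (uniform-within-bin assumption).
overlap_matrix <- function(src_edges, tgt_edges) {
  ns <- length(src_edges) - 1L
  nt <- length(tgt_edges) - 1L
  lo <- pmax(matrix(tgt_edges[-(nt + 1)], nt, ns),
             matrix(src_edges[-(ns + 1)], nt, ns, byrow = TRUE))
  hi <- pmin(matrix(tgt_edges[-1], nt, ns),
             matrix(src_edges[-1], nt, ns, byrow = TRUE))
  ov <- pmax(hi - lo, 0)
  sweep(ov, 2, diff(src_edges), "/")
}

#' Rebin a size distribution onto a different grid
#'
#' Redistributes per-bin particle content (density x bin width)
#' proportionally to overlap length, assuming particles are uniformly
#' distributed within each source bin. Total particle count over the
#' intersection of the two supports is conserved; target bins outside the
#' source support receive zero.
#'
#' @param dist A [size_distribution()].
#' @param target_edges Strictly increasing diameters (nm) overlapping the
#'   source support.
#' @return A [size_distribution()] on `target_edges`.
#' @export
rebin_to_common_grid <- function(dist, target_edges) {
  if (!inherits(dist, "size_distribution"))
    stop("dist must be a size_distribution", call. = FALSE)
  if (any(diff(target_edges) <= 0))
    stop("target_edges must be strictly increasing", call. = FALSE)
  src <- dist$bin_edges
  if (min(target_edges) >= max(src) || max(target_edges) <= min(src))
    stop("target grid does not overlap the source support", call. = FALSE)
  counts <- dist$density * diff(src)
  new_counts <- as.vector(overlap_matrix(src, target_edges) %*% counts)
  size_distribution(target_edges, new_counts / diff(target_edges),
                    cartridge = dist$cartridge, condition = dist$condition)
}

#' Merge dual-cartridge MRPS replicates into a full-range distribution
#'
#' The two MRPS cartridges cover 70--400 nm and 250--2000 nm with
#' independent concentration calibrations. Following the subset-resampling
#' scheme, each bootstrap draw (i) subsamples replicates (with replacement)
#' per cartridge and averages their densities, (ii) rebins both averages to
#' the common full-range grid, (iii) rescales the large-cartridge draw by the
#' ratio of mean densities in the 250--400 nm overlap, and (iv) stitches the
#' two at the overlap midpoint (325 nm): small-cartridge values below,
#' rescaled large-cartridge values above. Accumulating the draws yields the
#' per-bin mean and spread (standard deviation over draws) of the combined
#' distribution.
#'
#' @param small [replicate_set()] from the 70--400 nm cartridge.
#' @param large [replicate_set()] from the 250--2000 nm cartridge.
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param subsample_fraction Fraction of replicates drawn (with replacement,
#'   rounded up) per bootstrap draw; default 2/3.
#' @param seed Integer seed; the merge is deterministic given the seed.
#' @param target_edges Full-range output grid; default 96 log-spaced bins
#'   over 70--2000 nm.
#' @return An object of class `merged_distribution` with fields `bin_edges`,
#'   `mean`, `spread`, `n_boot`, `seed`, `condition`.
#' @export
merge_cartridges <- function(small, large, n_boot = 1000,
                             subsample_fraction = 2 / 3, seed = NULL,
                             target_edges = NULL) {
  if (!inherits(small, "replicate_set") || !inherits(large, "replicate_set"))
    stop("small and large must be replicate_set objects", call. = FALSE)
  check_scalar(n_boot, "n_boot", min = 1)
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]", call. = FALSE)
  if (min(small$bin_edges) < 70 - 1e-9 || max(small$bin_edges) > 400 + 1e-9)
    stop("small cartridge data must lie within 70-400 nm", call. = FALSE)
  if (min(large$bin_edges) < 250 - 1e-9 ||
      max(large$bin_edges) > 2000 + 1e-9)
    stop("large cartridge data must lie within 250-2000 nm", call. = FALSE)
  if (max(small$bin_edges) <= 250 || min(large$bin_edges) >= 400)
    stop("cartridges do not cover the 250-400 nm overlap; cross-scaling impossible",
         call. = FALSE)
  if (is.null(target_edges))
    target_edges <- exp(seq(log(70), log(2000), length.out = 97))

  ms <- replicate_matrix(small)
  ml <- replicate_matrix(large)
  Msmall <- overlap_matrix(small$bin_edges, target_edges)
  Mlarge <- overlap_matrix(large$bin_edges, target_edges)
  ws <- diff(small$bin_edges); wl <- diff(large$bin_edges)
  wt <- diff(target_edges)
  ctr <- bin_centers(target_edges)
  # cross-scale only on target bins fully covered by both cartridges, so
  # partially covered edge bins cannot bias the calibration ratio
  nt <- length(target_edges)
  in_overlap <- target_edges[-nt] >= max(min(small$bin_edges),
                                         min(large$bin_edges)) &
    target_edges[-1] <= min(max(small$bin_edges), max(large$bin_edges))
  if (!any(in_overlap))
    stop("no target bin lies fully inside the cartridge overlap",
         call. = FALSE)
  use_small <- ctr < 325
  ns_draw <- ceiling(subsample_fraction * ncol(ms))
  nl_draw <- ceiling(subsample_fraction * ncol(ml))

  draws <- with_seed(seed, {
    out <- matrix(NA_real_, length(wt), n_boot)
    for (b in seq_len(n_boot)) {
      ds <- rowMeans(ms[, sample.int(ncol(ms), ns_draw, replace = TRUE),
                        drop = FALSE])
      dl <- rowMeans(ml[, sample.int(ncol(ml), nl_draw, replace = TRUE),
                        drop = FALSE])
      ts <- as.vector(Msmall %*% (ds * ws)) / wt
      tl <- as.vector(Mlarge %*% (dl * wl)) / wt
      denom <- mean(tl[in_overlap])
      scale <- if (denom > 0) mean(ts[in_overlap]) / denom else 1
      out[, b] <- ifelse(use_small, ts, tl * scale)
    }
    out
  })
  structure(
    list(bin_edges = target_edges, mean = rowMeans(draws),
         spread = apply(draws, 1, stats::sd), n_boot = as.integer(n_boot),
         seed = seed, condition = small$condition),
    class = "merged_distribution"
  )
}

#' @export
print.merged_distribution <- function(x, ...) {
  cat(sprintf(
    "merged_distribution '%s': %d bins over %.4g-%.4g nm (%d bootstrap draws)\n",
    x$condition, length(x$mean), min(x$bin_edges), max(x$bin_edges),
    x$n_boot))
  invisible(x)
}

# Coerce a merged distribution to a plain size_distribution.
as_size_distribution <- function(x) {
  if (inherits(x, "size_distribution")) return(x)
  if (inherits(x, "merged_distribution"))
    return(size_distribution(x$bin_edges, pmax(x$mean, 0),
                             cartridge = "merged", condition = x$condition))
  if (inherits(x, "replicate_set"))
    return(size_distribution(x$bin_edges, rowMeans(replicate_matrix(x)),
                             cartridge = x$cartridge,
                             condition = x$condition))
  stop("cannot coerce to size_distribution", call. = FALSE)
}

#' Convert a size distribution to a zero-floored probability mass
#'
#' Zero densities are replaced by a small positive floor (in counts/ml/nm,
#' applied before normalization) so that divergence computations never see a
#' zero probability; per-bin mass is then floored density times bin width,
#' normalized to sum to one.
#'
#' @param dist A [size_distribution()] or [merge_cartridges()] result.
#' @param zero_floor Replacement for zero densities (default `1e-5`
#'   counts/ml/nm).
#' @return An object of class `probability_mass` with fields `bin_edges` and
#'   `p` (strictly positive, summing to 1).
#' @export
to_probability <- function(dist, zero_floor = 1e-5) {
  dist <- as_size_distribution(dist)
  check_scalar(zero_floor, "zero_floor", min = 0)
  d <- dist$density
  if (all(d == 0) && zero_floor == 0)
    stop("all-zero distribution with zero_floor = 0 cannot be normalized",
         call. = FALSE)
  d[d == 0] <- zero_floor
  mass <- d * diff(dist$bin_edges)
  structure(
    list(bin_edges = dist$bin_edges, p = mass / sum(mass),
         condition = dist$condition),
    class = "probability_mass"
  )
}

#' @export
print.probability_mass <- function(x, ...) {
  cat(sprintf("probability_mass '%s': %d bins over %.4g-%.4g nm\n",
              x$condition, length(x$p), min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Kullback--Leibler divergence between binned size distributions
#'
#' Computes `sum(P * log(P / Q))` in nats over a shared bin grid. Both
#' arguments must be [to_probability()] outputs on identical bin edges
#' (rebin first with [rebin_to_common_grid()] if they differ); the zero
#' floor applied there guarantees all terms are finite.
#'
#' @param P,Q `probability_mass` objects on identical grids. `P` is
#'   conventionally the perturbed (chaperone-containing) sample and `Q` the
#'   reference.
#' @return Non-negative divergence in nats; 0 iff `P == Q` element-wise.
#' @export
kl_divergence <- function(P, Q) {
  if (!inherits(P, "probability_mass") || !inherits(Q, "probability_mass"))
    stop("P and Q must be probability_mass objects", call. = FALSE)
  if (length(P$bin_edges) != length(Q$bin_edges) ||
      !isTRUE(all.equal(P$bin_edges, Q$bin_edges)))
    stop("P and Q are on different bin grids; rebin to a common grid first",
         call. = FALSE)
  sum(P$p * log(P$p / Q$p))
}

#' Divergence profile of a query series against one reference
#'
#' Computes `kl_divergence(query || reference)` for each query, in input
#' order: the divergence of each (e.g. chaperone-treated) sample from a
#' common untreated reference.
#'
#' @param reference A `probability_mass`.
#' @param queries List of `probability_mass` objects on the reference grid.
#' @return Numeric vector of divergences (nats).
#' @export
kl_profile <- function(reference, queries) {
  if (inherits(queries, "probability_mass")) queries <- list(queries)
  vapply(queries, kl_divergence, numeric(1), Q = reference)
}

#' Flatness of the size distribution in the mesoscale window
#'
#' The probability of forming a cluster of diameter d is a readout of the
#' self-assembly free-energy landscape (free energy proportional to
#' log p(d)), and a flattened landscape appears as a plateau of the size
#' distribution, typically over ~400--1100 nm. This metric fits a
#' least-squares line to `log p(d)` versus `d` over the window and reports
#' the absolute slope (1/nm); values near zero indicate the flattened
#' regime.
#'
#' @param dist A [size_distribution()] (or coercible).
#' @param window Diameter interval (nm), default `c(400, 1100)`.
#' @param threshold Flatness threshold on the slope magnitude (1/nm),
#'   default `1e-3`.
#' @param zero_floor Passed to [to_probability()].
#' @return A list with `slope` (absolute slope, 1/nm), `flat` (logical:
#'   `slope < threshold`) and `n_bins` used.
#' @export
flatness_metric <- function(dist, window = c(400, 1100), threshold = 1e-3,
                            zero_floor = 1e-5) {
  dist <- as_size_distribution(dist)
  pm <- to_probability(dist, zero_floor = zero_floor)
  ctr <- bin_centers(pm$bin_edges)
  dens <- pm$p / diff(pm$bin_edges)  # probability density, 1/nm
  sel <- ctr >= window[1] & ctr <= window[2]
  if (sum(sel) < 3L)
    stop(sprintf("fewer than 3 bins with centers in [%g, %g] nm",
                 window[1], window[2]), call. = FALSE)
  fit <- stats::lm(log(dens[sel]) ~ ctr[sel])
  slope <- abs(unname(stats::coef(fit)[2]))
  list(slope = slope, flat = slope < threshold, n_bins = sum(sel))
}

#' Pairwise divergence matrix between two sets of distributions
#'
#' @param rows,cols Named lists of `probability_mass` objects on one grid;
#'   entry `[i, j]` is `kl_divergence(rows[[i]] || cols[[j]])`.
#' @return A numeric matrix with the lists' names as dimnames.
#' @export
kl_matrix <- function(rows, cols) {
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(names(rows), names(cols)))
  for (i in seq_along(rows))
    for (j in seq_along(cols))
      m[i, j] <- kl_divergence(rows[[i]], cols[[j]])
  m
}
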