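#' Configuration for the linked-equilibrium analysis pipeline
#'
#' Collects every knob of the matched-comparison and titration analyses:
#' the condition grid, binding constant, intrinsic saturation
#' concentration, divergence and merging settings, and the master seed. All
#' randomness in a run derives from the seed, so outputs are reproducible
#' from the configuration alone.
#'
#' @param cargo_total Total cargo concentration (uM), default 2.
#' @param chaperone_levels Ascending total chaperone concentrations (uM),
#'   default `c(0, 1, 2, 4, 6)`.
#' @param kd Dissociation constant (uM), default 0.05.
#' @param csat0 Intrinsic saturation concentration (uM), default 1.
#' @param n_replicates Replicates per condition per cartridge, default 3.
#' @param n_boot Bootstrap draws for cartridge merging, default 1000.
#' @param subsample_fraction Replicate subsample fraction per draw, default
#'   2/3.
#' @param zero_floor Zero replacement before normalization (counts/ml/nm),
#'   default 1e-5.
#' @param seed Master seed (required).
#' @param params A [landscape_params()]; overridden by `preset`.
#' @param preset Optional [landscape_preset()] name; sets `kd` and
#'   `params`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cargo_total = 2,
                            chaperone_levels = c(0, 1, 2, 4, 6),
                            kd = 0.05, csat0 = 1, n_replicates = 3,
                            n_boot = 1000, subsample_fraction = 2 / 3,
                            zero_floor = 1e-5, seed,
                            params = landscape_params(), preset = NULL) {
  if (missing(seed) || is.null(seed))
    stop("pipeline_config requires a seed", call. = FALSE)
  if (!is.null(preset)) {
    p <- landscape_preset(preset)
    kd <- p$kd
    params <- p$params
  }
  check_scalar(cargo_total, "cargo_total", min = 0)
  check_scalar(kd, "kd", min = 0, strict_min = TRUE)
  check_scalar(csat0, "csat0", min = 0, strict_min = TRUE)
  structure(
    list(cargo_total = cargo_total, chaperone_levels = chaperone_levels,
         kd = kd, csat0 = csat0, n_replicates = as.integer(n_replicates),
         n_boot = as.integer(n_boot),
         subsample_fraction = subsample_fraction, zero_floor = zero_floor,
         seed = as.integer(seed), params = params,
         preset = if (is.null(preset)) NA_character_ else preset),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value schema matching the arguments of [pipeline_config()]
#' (`cargo_total`, `chaperone_levels`, `kd`, `csat0`, `n_replicates`,
#' `n_boot`, `subsample_fraction`, `zero_floor`, `seed`, `preset`), plus an
#' optional `landscape:` mapping passed to [landscape_params()].
#'
#' @param path Path to the YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("cargo_total", "chaperone_levels", "kd", "csat0",
                        "n_replicates", "n_boot", "subsample_fraction",
                        "zero_floor", "seed", "preset"))]
  if (!is.null(y$landscape))
    args$params <- do.call(landscape_params, y$landscape)
  do.call(pipeline_config, args)
}

# Stable hash of a configuration: md5 of its canonical JSON serialization.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# Merge a per-condition observation (named list of replicate sets by
# cartridge, or a single set) into one probability mass on a common grid.
condition_to_probability <- function(obs, config, seed) {
  if (inherits(obs, "replicate_set")) {
    return(to_probability(as_size_distribution(obs),
                          zero_floor = config$zero_floor))
  }
  merged <- merge_cartridges(obs$C400, obs$C2000, n_boot = config$n_boot,
                             subsample_fraction = config$subsample_fraction,
                             seed = seed)
  to_probability(merged, zero_floor = config$zero_floor)
}

#' Run the matched-concentration comparison
#'
#' Reproduces the matched-minimum analysis: for each mixture condition
#' (fixed total cargo, increasing chaperone) the free cargo concentration
#' is computed from the binding equilibrium, the full divergence matrix of
#' mixture distributions against a cargo-only library is evaluated, and the
#' per-row argmin is compared with the library entry nearest (in
#' log-concentration) to the computed free concentration. Under the linked
#' equilibrium the divergence minimum falls on the matched entry.
#'
#' When `mixture` and `library` are `NULL`, both are simulated from the
#' configuration with [generate_condition_grid()] (dual-cartridge
#' observations, bootstrap-merged). User data can be supplied as lists of
#' [replicate_set()]s (one per condition, or named lists with `C400` and
#' `C2000` entries for dual-cartridge merging), with `library_concentrations`
#' giving the cargo-only concentrations.
#'
#' @param config A [pipeline_config()].
#' @param mixture,library Optional observed data (see Details).
#' @param library_concentrations Cargo-only concentrations (uM) of the
#'   library entries; required when `library` is supplied.
#' @return An object of class `match_report`: list with the divergence
#'   matrix `kl` (rows mixtures, columns library), `cargo_free`,
#'   `library_concentrations`, `argmin`, `target`, `match_success`,
#'   `regime`, `config_hash`, `seed`.
#' @export
run_matched_comparison <- function(config, mixture = NULL, library = NULL,
                                   library_concentrations = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config", call. = FALSE)
  if (is.null(mixture) != is.null(library))
    stop("supply both mixture and library, or neither", call. = FALSE)
  if (is.null(mixture)) {
    grid <- generate_condition_grid(
      config$cargo_total, config$chaperone_levels, config$kd,
      params = config$params, n_replicates = config$n_replicates,
      seed = config$seed)
    mixture <- grid$mixture
    library <- grid$matched
    library_concentrations <- grid$matched_concentration
    cargo_free <- grid$cargo_free
  } else {
    if (is.null(library_concentrations) ||
        length(library_concentrations) != length(library))
      stop("library_concentrations must match the library length",
           call. = FALSE)
    if (length(mixture) != length(config$chaperone_levels))
      stop("mixture must have one entry per chaperone level", call. = FALSE)
    cargo_free <- free_cargo_curve(config$cargo_total,
                                   config$chaperone_levels,
                                   config$kd)$cargo_free_uM
  }
  seeds <- derive_seeds((config$seed %% 2000000000L) + 1L,
                        length(mixture) + length(library))
  mix_pm <- lapply(seq_along(mixture), function(i)
    condition_to_probability(mixture[[i]], config, seeds[[i]]))
  lib_pm <- lapply(seq_along(library), function(j)
    condition_to_probability(library[[j]], config,
                             seeds[[length(mixture) + j]]))
  names(mix_pm) <- sprintf("chap_%.4g", config$chaperone_levels)
  names(lib_pm) <- sprintf("cargo_%.4g", library_concentrations)
  kl <- kl_matrix(mix_pm, lib_pm)
  argmin <- apply(kl, 1, which.min)
  target <- vapply(cargo_free, function(cf)
    which.min(abs(log(pmax(library_concentrations, 1e-12)) -
                    log(max(cf, 1e-12)))), integer(1))
  regime <- classify_regime(cargo_free, config$csat0)$regime
  structure(
    list(kl = kl, cargo_free = cargo_free,
         library_concentrations = library_concentrations,
         argmin = argmin, target = target,
         match_success = argmin == target, regime = regime,
         config_hash = config_hash(config), seed = config$seed),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat("Matched-concentration comparison\n")
  df <- data.frame(cargo_free_uM = signif(x$cargo_free, 3),
                   regime = x$regime,
                   kl_argmin = colnames(x$kl)[x$argmin],
                   matched = x$match_success)
  rownames(df) <- rownames(x$kl)
  print(df)
  cat(sprintf("match success: %d / %d\n", sum(x$match_success),
              length(x$match_success)))
  invisible(x)
}

#' Run the chaperone titration report
#'
#' For each chaperone level: the free cargo concentration, the assembly
#' regime relative to the intrinsic saturation concentration, the
#' divergence of the level's size distribution from the zero-chaperone
#' reference, and the mesoscale flatness metric. This is the summary used
#' to contrast a high-affinity chaperone (distributions diverge sharply
#' from the untreated reference) with a weak-binding variant (distributions
#' stay close to it).
#'
#' @param config A [pipeline_config()]; the chaperone levels must include
#'   0 (the reference).
#' @param data Optional list of per-level observations (as in
#'   [run_matched_comparison()]); simulated from the config when `NULL`.
#' @return An object of class `titration_report`: data frame with columns
#'   `chaperone_total_uM`, `cargo_free_uM`, `regime`, `kl_vs_reference`,
#'   `flatness_slope`, `flat`, with the config hash and seed as attributes.
#' @export
run_titration_report <- function(config, data = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config", call. = FALSE)
  if (!any(config$chaperone_levels == 0))
    stop("chaperone_levels must include the zero-chaperone reference",
         call. = FALSE)
  if (is.null(data)) {
    grid <- generate_condition_grid(
      config$cargo_total, config$chaperone_levels, config$kd,
      params = config$params, n_replicates = config$n_replicates,
      seed = config$seed)
    data <- grid$mixture
  } else if (length(data) != length(config$chaperone_levels))
    stop("data must have one entry per chaperone level", call. = FALSE)
  seeds <- derive_seeds((config$seed %% 2000000000L) + 2L, length(data))
  pm <- lapply(seq_along(data), function(i)
    condition_to_probability(data[[i]], config, seeds[[i]]))
  ref <- pm[[which(config$chaperone_levels == 0)[1]]]
  curve <- free_cargo_curve(config$cargo_total, config$chaperone_levels,
                            config$kd)
  flat <- lapply(pm, function(p) {
    sd <- size_distribution(p$bin_edges, p$p / diff(p$bin_edges))
    tryCatch(flatness_metric(sd), error = function(e)
      list(slope = NA_real_, flat = NA))
  })
  out <- data.frame(
    chaperone_total_uM = config$chaperone_levels,
    cargo_free_uM = curve$cargo_free_uM,
    regime = classify_regime(curve$cargo_free_uM, config$csat0)$regime,
    kl_vs_reference = kl_profile(ref, pm),
    flatness_slope = vapply(flat, `[[`, numeric(1), "slope"),
    flat = vapply(flat, function(f) isTRUE(f$flat), logical(1))
  )
  attr(out, "config_hash") <- config_hash(config)
  attr(out, "seed") <- config$seed
  class(out) <- c("titration_report", "data.frame")
  out
}

#' Write an analysis report to disk
#'
#' Emits a JSON summary, delimited tables, and a run log carrying the
#' configuration hash, seed and package version. Outputs contain no
#' timestamps, so a fixed report writes byte-identical files on every call.
#'
#' @param report A `match_report` or `titration_report`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory", call. = FALSE)
  files <- character(0)
  ver <- as.character(utils::packageVersion("phaselink"))
  if (inherits(report, "match_report")) {
    p <- file.path(dir, "kl_matrix.tsv")
    utils::write.table(report$kl, p, sep = "\t", quote = FALSE,
                       col.names = NA)
    files <- c(files, p)
    p <- file.path(dir, "match_summary.json")
    jsonlite::write_json(
      list(cargo_free_uM = report$cargo_free,
           library_concentrations_uM = report$library_concentrations,
           argmin = unname(report$argmin), target = unname(report$target),
           match_success = unname(report$match_success),
           regime = report$regime),
      p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
    log <- list(config_hash = report$config_hash, seed = report$seed,
                package_version = ver)
  } else if (inherits(report, "titration_report")) {
    p <- file.path(dir, "titration.tsv")
    utils::write.table(as.data.frame(report), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, p)
    p <- file.path(dir, "titration.json")
    jsonlite::write_json(as.list(as.data.frame(report)), p,
                         auto_unbox = FALSE, digits = NA)
    files <- c(files, p)
    log <- list(config_hash = attr(report, "config_hash"),
                seed = attr(report, "seed"), package_version = ver)
  } else stop("report must be a match_report or titration_report",
              call. = FALSE)
  p <- file.path(dir, "run_log.json")
  jsonlite::write_json(log, p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  invisible(files)
}
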