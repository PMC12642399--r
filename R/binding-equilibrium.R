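#' Specify a 1:1 chaperone--cargo binding system
#'
#' Bundles the inputs of the single-site binding-equilibrium model: the total
#' concentration of a self-associating cargo protein (e.g. FUS), the total
#' concentration of its chaperone (e.g. Kap-beta2), and the dissociation
#' constant of the 1:1 complex. All concentrations are in micromolar.
#'
#' @param cargo_total Total cargo concentration (uM), >= 0.
#' @param chaperone_total Total chaperone concentration (uM), >= 0.
#' @param kd Dissociation constant of the complex (uM), > 0. The
#'   stoichiometric limit kd -> 0 is available as
#'   [stoichiometric_free_cargo()].
#' @return An object of class `binding_system`.
#' @seealso [solve_equilibrium()], [free_cargo_curve()]
#' @examples
#' binding_system(cargo_total = 2, chaperone_total = 1, kd = 0.05)
#' @export
binding_system <- function(cargo_total, chaperone_total, kd) {
  check_scalar(cargo_total, "cargo_total", min = 0)
  check_scalar(chaperone_total, "chaperone_total", min = 0)
  check_scalar(kd, "kd", min = 0, strict_min = TRUE)
  structure(
    list(cargo_total = cargo_total, chaperone_total = chaperone_total,
         kd = kd),
    class = "binding_system"
  )
}

#' @export
print.binding_system <- function(x, ...) {
  cat("1:1 binding system (uM): cargo_total =", x$cargo_total,
      " chaperone_total =", x$chaperone_total, " Kd =", x$kd, "\n")
  invisible(x)
}

#' Solve the 1:1 binding equilibrium for free and bound concentrations
#'
#' Computes the unique physically admissible equilibrium of
#' cargo + chaperone <-> complex. With total cargo `C`, total chaperone `K`
#' and dissociation constant `kd`, the free cargo concentration `F` is the
#' root of
#' \deqn{F^2 + (k_d + K - C) F - k_d C = 0, \quad 0 \le F \le C,}
#' evaluated in the cancellation-safe form
#' \deqn{F = \frac{2 k_d C}{b + \sqrt{b^2 + 4 k_d C}}, \quad b = k_d + K - C,}
#' which avoids the catastrophic cancellation of the textbook quadratic
#' formula when `b` is large and positive.
#'
#' @param system A [binding_system()].
#' @return An object of class `equilibrium_state`: a list with elements
#'   `cargo_free`, `chaperone_free` and `complex` (all uM), satisfying mass
#'   conservation for both species and the mass-action relation
#'   `cargo_free * chaperone_free / complex == kd` whenever `complex > 0`.
#' @examples
#' solve_equilibrium(binding_system(2, 1, 0.05))  # free cargo ~ 1.05 uM
#' @export
solve_equilibrium <- function(system) {
  if (!inherits(system, "binding_system"))
    system <- do.call(binding_system, as.list(system))
  C <- system$cargo_total
  K <- system$chaperone_total
  kd <- system$kd
  if (C == 0) {
    f <- 0
  } else {
    b <- kd + K - C
    f <- 2 * kd * C / (b + sqrt(b * b + 4 * kd * C))
  }
  f <- min(max(f, 0), C)
  cplx <- C - f
  structure(
    list(cargo_free = f, chaperone_free = K - cplx, complex = cplx,
         system = system),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, digits = 4, ...) {
  cat("Equilibrium state (uM):\n")
  cat("  cargo_free     =", signif(x$cargo_free, digits), "\n")
  cat("  chaperone_free =", signif(x$chaperone_free, digits), "\n")
  cat("  complex        =", signif(x$complex, digits), "\n")
  invisible(x)
}

#' Free cargo in the stoichiometric (infinite-affinity) limit
#'
#' The kd -> 0 limit of [solve_equilibrium()]: the chaperone sequesters
#' cargo 1:1 until one species is exhausted, so the free cargo concentration
#' is `max(cargo_total - chaperone_total, 0)`.
#'
#' @param cargo_total,chaperone_total Concentrations (uM), >= 0.
#' @return Free cargo concentration (uM).
#' @export
stoichiometric_free_cargo <- function(cargo_total, chaperone_total) {
  check_scalar(cargo_total, "cargo_total", min = 0)
  check_scalar(chaperone_total, "chaperone_total", min = 0)
  max(cargo_total - chaperone_total, 0)
}

#' Free cargo concentration across a chaperone titration
#'
#' Applies [solve_equilibrium()] at each total chaperone concentration,
#' keeping total cargo and Kd fixed: the theoretical titration underlying the
#' matched-concentration experimental design.
#'
#' @param cargo_total Total cargo concentration (uM).
#' @param chaperone_levels Ascending vector of total chaperone
#'   concentrations (uM), all >= 0.
#' @param kd Dissociation constant (uM).
#' @return An object of class `titration_curve`: a data frame with columns
#'   `chaperone_total_uM` and `cargo_free_uM` (non-increasing), with the
#'   inputs stored as attributes.
#' @examples
#' free_cargo_curve(2, c(0, 1, 2, 4, 6), 0.05)
#' @export
free_cargo_curve <- function(cargo_total, chaperone_levels, kd) {
  if (!is.numeric(chaperone_levels) || length(chaperone_levels) < 1L)
    stop("chaperone_levels must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(chaperone_levels)) || any(chaperone_levels < 0))
    stop("chaperone_levels must be finite and >= 0", call. = FALSE)
  if (is.unsorted(chaperone_levels, strictly = FALSE))
    stop("chaperone_levels must be sorted in ascending order", call. = FALSE)
  free <- vapply(
    chaperone_levels,
    function(k) solve_equilibrium(binding_system(cargo_total, k, kd))$cargo_free,
    numeric(1)
  )
  out <- data.frame(chaperone_total_uM = chaperone_levels,
                    cargo_free_uM = free)
  attr(out, "cargo_total") <- cargo_total
  attr(out, "kd") <- kd
  class(out) <- c("titration_curve", "data.frame")
  out
}

#' Specify a polyphasic-linkage model for the saturation concentration
#'
#' Under polyphasic linkage, a ligand that binds a phase-separating
#' macromolecule shifts its saturation concentration by the ratio of binding
#' polynomials in the two coexisting phases:
#' \deqn{c_{sat,L} = c_{sat,0} \, P_{dil} / P_{den}.}
#' For a single binding site, `P = 1 + [L]/kd` in each phase. A dense-phase
#' dissociation constant of `Inf` means the ligand does not bind in the dense
#' phase (`P_den = 1`), the regime in which preferential dilute-phase binding
#' raises the saturation concentration.
#'
#' @param csat0 Intrinsic saturation concentration without ligand (uM), > 0.
#' @param kd_dilute Ligand dissociation constant in the dilute phase (uM),
#'   > 0.
#' @param kd_dense Ligand dissociation constant in the dense phase (uM), > 0
#'   or `Inf` (default: no dense-phase binding).
#' @return An object of class `phase_linkage`.
#' @seealso [csat_shift()]
#' @export
phase_linkage <- function(csat0, kd_dilute, kd_dense = Inf) {
  check_scalar(csat0, "csat0", min = 0, strict_min = TRUE)
  check_scalar(kd_dilute, "kd_dilute", min = 0, strict_min = TRUE)
  check_scalar(kd_dense, "kd_dense", min = 0, strict_min = TRUE,
               allow_inf = TRUE)
  structure(list(csat0 = csat0, kd_dilute = kd_dilute, kd_dense = kd_dense),
            class = "phase_linkage")
}

#' Ligand-shifted saturation concentration
#'
#' Evaluates `csat0 * (1 + L/kd_dilute) / (1 + L/kd_dense)` at free ligand
#' concentration `L`. The result exceeds `csat0` exactly when dilute-phase
#' binding is preferred (`kd_dilute < kd_dense`), equals it when binding in
#' the two phases is equivalent, and is vectorized over `ligand_free`.
#'
#' @param linkage A [phase_linkage()].
#' @param ligand_free Free ligand concentration(s) (uM), >= 0.
#' @return Shifted saturation concentration(s) (uM).
#' @examples
#' csat_shift(phase_linkage(1, 0.05, Inf), 0.05)  # doubles csat
#' @export
csat_shift <- function(linkage, ligand_free) {
  if (!inherits(linkage, "phase_linkage"))
    stop("linkage must be a phase_linkage object", call. = FALSE)
  if (!is.numeric(ligand_free) || any(!is.finite(ligand_free)) ||
      any(ligand_free < 0))
    stop("ligand_free must be finite and >= 0", call. = FALSE)
  p_dil <- 1 + ligand_free / linkage$kd_dilute
  p_den <- if (is.infinite(linkage$kd_dense)) rep(1, length(ligand_free))
           else 1 + ligand_free / linkage$kd_dense
  # equal binding polynomials give csat0 exactly, with no float division
  linkage$csat0 * ifelse(p_dil == p_den, 1, p_dil / p_den)
}

#' Classify the assembly regime of a solution
#'
#' A solution condenses only when the free, self-association-competent cargo
#' concentration strictly exceeds the saturation concentration; at or below
#' it, only monomers and mesoscale clusters populate the dilute phase. Exact
#' equality is classified as `subsaturated` (condensation requires strict
#' exceedance; equality is a measure-zero boundary and the conservative call
#' avoids false condensation claims).
#'
#' @param cargo_free Free cargo concentration(s) (uM), >= 0.
#' @param csat Saturation concentration(s) (uM), > 0.
#' @return A data frame with columns `cargo_free`, `csat`, `ratio`
#'   (`cargo_free / csat`) and `regime` (`"saturated"` or `"subsaturated"`).
#' @examples
#' classify_regime(c(2, 0.5, 1), 1)
#' @export
classify_regime <- function(cargo_free, csat) {
  if (!is.numeric(cargo_free) || any(!is.finite(cargo_free)) ||
      any(cargo_free < 0))
    stop("cargo_free must be finite and >= 0", call. = FALSE)
  if (!is.numeric(csat) || any(!is.finite(csat)) || any(csat <= 0))
    stop("csat must be finite and > 0", call. = FALSE)
  n <- max(length(cargo_free), length(csat))
  cargo_free <- rep_len(cargo_free, n)
  csat <- rep_len(csat, n)
  data.frame(
    cargo_free = cargo_free,
    csat = csat,
    ratio = cargo_free / csat,
    regime = ifelse(cargo_free > csat, "saturated", "subsaturated")
  )
}

#' Matched cargo-only concentration for a chaperone-containing condition
#'
#' For a mixture of cargo and chaperone, returns the cargo-only concentration
#' predicted to reproduce the mixture's assembly size distribution: the free
#' cargo concentration at equilibrium. Under the linked-equilibrium
#' hypothesis the size distribution depends on free -- not total -- cargo, so
#' a cargo-only sample at this concentration is the mixture's experimental
#' match.
#'
#' @param system A [binding_system()].
#' @return Matched cargo-only concentration (uM).
#' @examples
#' matched_cargo_concentration(binding_system(2, 1, 0.05))  # ~1.05 uM
#' @export
matched_cargo_concentration <- function(system) {
  solve_equilibrium(system)$cargo_free
}
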