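# Internal helpers shared across modules.

# Boltzmann constant, J/K (SI exact).
.kB <- 1.380649e-23

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded generators never perturb the
#' global random stream. A `NULL` seed evaluates `expr` with the current
#' stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number or NULL", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `n` reproducible sub-seeds from a master seed. Used to give each
# replicate / condition / trace its own stream while keeping the whole
# pipeline a pure function of (inputs, master seed).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# Validate that `x` is a single finite numeric; `name` appears in errors.
check_scalar <- function(x, name, min = -Inf, strict_min = FALSE,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L)
    stop(sprintf("%s must be a single numeric value", name), call. = FALSE)
  if (!allow_inf && !is.finite(x))
    stop(sprintf("%s must be finite, got %s", name, format(x)), call. = FALSE)
  if (strict_min && !(x > min))
    stop(sprintf("%s must be > %g, got %g", name, min, x), call. = FALSE)
  if (!strict_min && x < min)
    stop(sprintf("%s must be >= %g, got %g", name, min, x), call. = FALSE)
  invisible(x)
}

# Trapezoidal cumulative integral of y over x (both numeric vectors).
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}
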