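#' Age- and size-dependent physiology
#'
#' Individual quantities that close the movement and habitat models:
#' straight carapace length from a von Bertalanffy growth curve, mass from the
#' length allometry, maximum sustainable speed from the metabolic scaling
#' argument, normalized food demand, and the two mass-dependent lower pivotal
#' temperatures expressing gigantothermy (larger animals tolerate colder
#' water).
#'
#' All functions are vectorized over their first argument.
#'
#' @param age Age in years (>= 0).
#' @param L Straight carapace length in metres (> 0).
#' @param M Mass in kg (>= 0).
#' @param params A [stamm_params()] object.
#'
#' @return `scl_at_age()`: length (m). `mass_from_scl()`: mass (kg).
#'   `vmax()`: maximum sustainable speed (m s^-1). `food_norm()`: normalized
#'   food demand in (0, 1). `pivotal_temps()`: a tibble with columns `T1`,
#'   `T2` (degC).
#' @examples
#' p <- stamm_params()
#' scl_at_age(c(0, 1, 5), p)
#' vmax(1.43, p) * (1 - 0.5)   # adult swim speed in average habitat
#' @name physiology
NULL

#' @rdname physiology
#' @export
scl_at_age <- function(age, params = stamm_params()) {
  if (any(age < 0)) stop("age must be >= 0")
  params$L_inf * (1 - exp(-params$k_growth * (age + params$a0)))
}

#' @rdname physiology
#' @export
mass_from_scl <- function(L, params = stamm_params()) {
  if (any(L <= 0)) stop("L must be > 0")
  params$mass_coeff * L^params$mass_exp
}

#' @rdname physiology
#' @export
vmax <- function(L, params = stamm_params()) {
  if (any(L <= 0)) stop("L must be > 0")
  params$v0 * L^params$vm_exp
}

#' @rdname physiology
#' @export
food_norm <- function(age, params = stamm_params()) {
  if (any(age < 0)) stop("age must be >= 0")
  x <- exp(-params$food_rate * (age + params$food_a0))
  # Exponents 1.86 and 0.094 are tied to the allometry (mass_exp - 1) and to
  # f0; keep them expressed that way so alternate calibrations stay coherent.
  e1 <- params$mass_exp - 1
  num <- params$f0 * x * (1 - x)^e1
  # den = 1 - (1 - x)^f0, written to stay accurate as x -> 0 (old animals),
  # where num ~ f0*x and den ~ f0*x so the ratio tends to 1.
  den <- -expm1(params$f0 * log1p(-x))
  out <- num / den
  out[x == 0] <- 1
  out
}

#' @rdname physiology
#' @export
pivotal_temps <- function(M, params = stamm_params()) {
  if (any(M < 0)) stop("M must be >= 0")
  sq <- sqrt(M)
  tibble::tibble(
    T1 = params$t1_intercept - params$t1_slope * sq,
    T2 = params$t2_intercept - params$t2_slope * sq
  )
}

# internal fast path: plain-list physiology for the daily loop
physiology_list <- function(age, params) {
  L <- params$L_inf * (1 - exp(-params$k_growth * (age + params$a0)))
  M <- params$mass_coeff * L^params$mass_exp
  sq <- sqrt(M)
  list(age = age, L = L, M = M,
       Vm = params$v0 * L^params$vm_exp,
       F0 = food_norm(age, params),
       T1 = params$t1_intercept - params$t1_slope * sq,
       T2 = params$t2_intercept - params$t2_slope * sq)
}

#' Full physiological state at a given age
#'
#' Chains the physiology functions once per simulated day: length, mass,
#' maximum sustainable speed, normalized food demand and pivotal temperatures.
#'
#' @inheritParams physiology
#' @return A tibble with columns `age`, `L`, `M`, `Vm`, `F0`, `T1`, `T2`.
#' @examples
#' physiology_at_age(c(0, 2, 10), stamm_params())
#' @export
physiology_at_age <- function(age, params = stamm_params()) {
  if (any(age < 0)) stop("age must be >= 0")
  tibble::as_tibble(physiology_list(age, params))
}
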