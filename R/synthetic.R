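# All generators draw from a private RNG stream seeded per call, so the
# caller's global random state is never consulted or disturbed.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Growth-curve parameters for the synthetic stand generator
#'
#' Parameters of a saturating (Chapman-Richards-type) stand trajectory:
#' `D(t) = d_max * (1 - exp(-k_d * t))^p_d` for diameter, the analogous
#' form for height, exponential survival `N(t) = n0 * exp(-m * t)` for
#' stocking, and a linear form-factor decline from `f0` to `f1` over the
#' age span. Defaults are least-squares fits to the packaged pre-thinning
#' Balikpapan stand trajectory: asymptotic diameter 30 cm and height
#' 14.5 m, 2450 stems/ha initial stocking with ~2.9% yr^-1 mortality and a
#' form factor falling from 0.85 to 0.60 as stems age; the implied MAI
#' curve is unimodal and culminates between ages 20 and 30.
#'
#' @param d_max Asymptotic mean diameter, cm (> 0).
#' @param k_d Diameter rate constant, yr^-1 (>= 0).
#' @param p_d Diameter shape exponent, dimensionless (> 0).
#' @param h_max,k_h,p_h Height-curve analogues (m, yr^-1, dimensionless).
#' @param n0 Initial stocking, stems ha^-1 (> 0).
#' @param m Mortality rate, yr^-1 (>= 0); `m = 0` keeps stocking constant.
#' @param f0,f1 Form factor at the youngest and oldest generated age,
#'   with `0 < f1 <= f0 <= 1`.
#' @return A list of class `growth_curve_params`.
#' @export
growth_curve_params <- function(d_max = 30, k_d = 0.025, p_d = 0.85,
                                h_max = 14.5, k_h = 0.048, p_h = 1.05,
                                n0 = 2450, m = 0.029,
                                f0 = 0.85, f1 = 0.60) {
  if (d_max <= 0 || h_max <= 0 || n0 <= 0) {
    stop("d_max, h_max and n0 must be positive", call. = FALSE)
  }
  if (k_d < 0 || k_h < 0 || m < 0) {
    stop("rate constants must be non-negative", call. = FALSE)
  }
  if (p_d <= 0 || p_h <= 0) stop("shape exponents must be positive",
                                 call. = FALSE)
  if (!(f1 > 0 && f1 <= f0 && f0 <= 1)) {
    stop("form factors need 0 < f1 <= f0 <= 1", call. = FALSE)
  }
  structure(list(d_max = d_max, k_d = k_d, p_d = p_d,
                 h_max = h_max, k_h = k_h, p_h = p_h,
                 n0 = n0, m = m, f0 = f0, f1 = f1),
            class = "growth_curve_params")
}

chapman_richards <- function(t, ymax, k, p) ymax * (1 - exp(-k * t))^p

#' Generate a synthetic stand trajectory
#'
#' Evaluates the growth curves of [growth_curve_params()] at the requested
#' ages and returns a [stand_table()]: saturating diameter and height,
#' exponentially declining stocking (rounded to whole stems) and a linear
#' form-factor decline. Optional multiplicative lognormal-free noise
#' (normal with coefficient of variation `noise_cv`, applied to D and H)
#' is off by default so that invariant checks are exact; all randomness is
#' drawn from a private stream seeded by `seed`.
#'
#' @param params A [growth_curve_params()].
#' @param ages Strictly increasing positive measurement ages, years.
#' @param noise_cv Coefficient of variation of multiplicative noise on
#'   diameter and height; 0 (default) for a deterministic trajectory.
#' @param seed Integer seed for the noise stream.
#' @param label Label for the resulting stand table.
#' @return A [stand_table()].
#' @examples
#' generate_stand_trajectory(growth_curve_params(), ages = c(3, 10, 25, 40))
#' @export
generate_stand_trajectory <- function(params = growth_curve_params(),
                                      ages, noise_cv = 0, seed = 1L,
                                      label = "synthetic") {
  if (length(ages) == 0L || any(!is.finite(ages)) || any(ages <= 0) ||
      (length(ages) > 1L && any(diff(ages) <= 0))) {
    stop("ages must be strictly increasing and positive", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  d <- chapman_richards(ages, params$d_max, params$k_d, params$p_d)
  h <- chapman_richards(ages, params$h_max, params$k_h, params$p_h)
  n <- round(params$n0 * exp(-params$m * ages))
  f <- if (length(ages) > 1L) {
    params$f0 + (params$f1 - params$f0) *
      (ages - ages[1L]) / (ages[length(ages)] - ages[1L])
  } else {
    rep(params$f0, 1L)
  }
  if (noise_cv > 0) {
    with_local_seed(seed, {
      d <- d * pmax(0.1, stats::rnorm(length(d), 1, noise_cv))
      h <- h * pmax(0.1, stats::rnorm(length(h), 1, noise_cv))
    })
  }
  stand_table(age = ages, n = n, d = d, h = h, f = f, label = label)
}

#' Generate a synthetic tree list
#'
#' Draws `n` stem diameters from a normal distribution truncated at zero
#' (negative draws are redrawn) and assigns each tree a height from a
#' deterministic height-diameter relation, `h = 1.3 + 0.55 * d`. Feeds
#' [low_thin()].
#'
#' @param n Number of trees (>= 1).
#' @param mean_d,sd_d Mean and standard deviation of diameter, cm
#'   (`sd_d = 0` gives identical trees).
#' @param seed Integer seed; identical seeds give identical lists.
#' @return Data frame with columns `diameter` (cm) and `height` (m).
#' @export
generate_tree_list <- function(n, mean_d = 15, sd_d = 3, seed = 1L) {
  if (!is.finite(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (sd_d < 0) stop("sd_d must be >= 0", call. = FALSE)
  if (mean_d <= 0) stop("mean_d must be positive", call. = FALSE)
  d <- with_local_seed(seed, {
    x <- stats::rnorm(n, mean_d, sd_d)
    while (any(x <= 0)) {                     # truncate at zero by redraw
      x[x <= 0] <- stats::rnorm(sum(x <= 0), mean_d, sd_d)
    }
    x
  })
  data.frame(diameter = d, height = 1.3 + 0.55 * d)
}

#' Income-model parameters for the synthetic household generator
#'
#' @param n_households Number of households (>= 1).
#' @param income_min,income_max Truncation range of annual net income,
#'   million IDR; defaults span the six observed income classes (13-36).
#' @param income_mean,income_sd Mean and sd of the parent normal, million
#'   IDR.
#' @param cost_fraction_range Range of the cost-to-net-income ratio;
#'   defaults to the 0.35-0.45 observed across the returns table.
#' @param size_range Integer range of household size, persons (within
#'   1-10).
#' @return A list of class `income_model_params`.
#' @export
income_model_params <- function(n_households = 30,
                                income_min = 13, income_max = 36,
                                income_mean = 24.5, income_sd = 6,
                                cost_fraction_range = c(0.35, 0.45),
                                size_range = c(3L, 5L)) {
  if (n_households < 1) stop("n_households must be >= 1", call. = FALSE)
  if (income_min <= 0 || income_max <= income_min) {
    stop("need 0 < income_min < income_max", call. = FALSE)
  }
  if (income_sd < 0) stop("income_sd must be >= 0", call. = FALSE)
  if (any(size_range < 1) || any(size_range > 10) ||
      size_range[2L] < size_range[1L]) {
    stop("size_range must be increasing within [1, 10]", call. = FALSE)
  }
  structure(list(n_households = as.integer(n_households),
                 income_min = income_min, income_max = income_max,
                 income_mean = income_mean, income_sd = income_sd,
                 cost_fraction_range = cost_fraction_range,
                 size_range = as.integer(size_range)),
            class = "income_model_params")
}

#' Generate synthetic household income records
#'
#' Draws annual net incomes from a normal distribution truncated to
#' `[income_min, income_max]` (out-of-range draws are redrawn), operating
#' costs as a uniform fraction of net income, and household sizes uniform
#' over `size_range`. All randomness comes from a private stream seeded by
#' `seed`.
#'
#' @param params An [income_model_params()].
#' @param seed Integer seed; identical seeds give identical records.
#' @return Data frame with columns `net_income` and `cost` (million IDR
#'   yr^-1) and `household_size` (persons), suitable for
#'   [classify_households()] and [diminishing_returns()].
#' @export
generate_household_incomes <- function(params = income_model_params(),
                                       seed = 1L) {
  n <- params$n_households
  with_local_seed(seed, {
    inc <- stats::rnorm(n, params$income_mean, params$income_sd)
    bad <- inc < params$income_min | inc > params$income_max
    while (any(bad)) {
      inc[bad] <- stats::rnorm(sum(bad), params$income_mean, params$income_sd)
      bad <- inc < params$income_min | inc > params$income_max
    }
    frac <- stats::runif(n, params$cost_fraction_range[1L],
                         params$cost_fraction_range[2L])
    size <- sample(seq(params$size_range[1L], params$size_range[2L]), n,
                   replace = TRUE)
    data.frame(net_income = inc, cost = inc * frac, household_size = size)
  })
}

#' Fit a Chapman-Richards curve to an age series
#'
#' Least-squares fit of `y = ymax * (1 - exp(-k * t))^p` to observed
#' values, via Levenberg-Marquardt ([minpack.lm::nlsLM()], which is robust
#' on exact, zero-residual data). Used to verify that the generator's
#' parameters are recoverable from its own noise-free output.
#'
#' @param t Ages, years.
#' @param y Observed values (e.g. diameters, cm).
#' @param start Named list of starting values `ymax`, `k`, `p`.
#' @return Named numeric vector with elements `ymax`, `k`, `p`.
#' @export
fit_growth_curve <- function(t, y,
                             start = list(ymax = max(y) * 1.2,
                                          k = 0.1, p = 1)) {
  fit <- minpack.lm::nlsLM(
    y ~ ymax * (1 - exp(-k * t))^p,
    data = data.frame(t = t, y = y),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  stats::coef(fit)
}
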