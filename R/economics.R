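#' Valuation configuration
#'
#' Bundle of constants for the direct-use valuation: managed area, stumpage
#' price, exchange rate, calendar basis, beneficiary population and
#' rotation length. Defaults describe the Balikpapan Bay scenario: a 300 ha
#' fishery/forest area, IDR 500,000 per m^3 stumpage, 1 US$ = IDR 13,300,
#' a community of 164 people and a 20-year rotation.
#'
#' @param area_ha Managed forest area, ha.
#' @param price_idr_per_m3 Stumpage price, IDR per m^3.
#' @param fx Exchange rate, IDR per US$.
#' @param days_per_year Days per year used for daily income conversion.
#' @param population Number of people sharing the income.
#' @param rotation_years Rotation (years between establishment and harvest).
#' @return A list of class `valuation_config`.
#' @export
valuation_config <- function(area_ha = 300,
                             price_idr_per_m3 = 500000,
                             fx = 13300,
                             days_per_year = 365,
                             population = 164,
                             rotation_years = 20) {
  cfg <- list(area_ha = area_ha, price_idr_per_m3 = price_idr_per_m3,
              fx = fx, days_per_year = days_per_year,
              population = population, rotation_years = rotation_years)
  if (any(!vapply(cfg, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v) && v > 0, logical(1L)))) {
    stop("all valuation constants must be single positive numbers",
         call. = FALSE)
  }
  class(cfg) <- "valuation_config"
  cfg
}

#' Nominal rate of return
#'
#' Per-period compound growth rate of a nominal (inflation-inclusive)
#' value: `i = (I_n / V_0)^(1/n) - 1`, where `I_n` is the nominal value
#' after `n` periods and `V_0` the initial value.
#'
#' @param value_n Nominal value after `n` periods (> 0).
#' @param value_0 Initial value (> 0).
#' @param n_periods Number of compounding periods (> 0).
#' @return Rate per period, as a fraction. Vectorised.
#' @examples
#' nrr(36.5, 10, 12)  # ~0.114 per month
#' @export
nrr <- function(value_n, value_0, n_periods) {
  ok <- function(v) all(is.finite(v)) && all(v > 0)
  if (!ok(value_n) || !ok(value_0) || !ok(n_periods)) {
    stop("all NRR inputs must be positive", call. = FALSE)
  }
  (value_n / value_0)^(1 / n_periods) - 1
}

#' Monthly nominal rate of return from annual net income and cost
#'
#' Treats the operating cost as the capital at risk and the gross annual
#' return (net income plus cost) as the value it grows to over 12 months:
#' `100 * (((net + cost) / cost)^(1/12) - 1)` percent per month. This is
#' the compounding that reproduces the published fisher return rates.
#'
#' @param net Annual net income, million IDR (> 0).
#' @param cost Annual operating cost, million IDR (> 0).
#' @return NRR, percent per month. Vectorised.
#' @examples
#' monthly_nrr(26.5, 10)  # ~11.4
#' @export
monthly_nrr <- function(net, cost) {
  if (any(!is.finite(net)) || any(net <= 0)) {
    stop("net income must be positive", call. = FALSE)
  }
  if (any(!is.finite(cost)) || any(cost <= 0)) {
    stop("cost must be positive", call. = FALSE)
  }
  100 * nrr(net + cost, cost, 12)
}

#' Sturges class count and width
#'
#' Sturges' rule for classing a series of `n` observations spanning a range
#' `R`: the class count is `1 + 3.332 * log10(n)` (rounded to the nearest
#' integer) and the class width is `R / (1 + 3.332 * log10(n))`.
#'
#' @param range_ Range of the series (max - min), same units as the data.
#' @param n Number of observations (>= 1).
#' @return `sturges_class_width()`: the raw (unrounded) width;
#'   `sturges_class_count()`: the integer class count.
#' @examples
#' sturges_class_width(23, 30)  # ~3.88, i.e. width-4 classes
#' sturges_class_count(30)      # 6
#' @export
sturges_class_width <- function(range_, n) {
  if (!is.finite(range_) || range_ <= 0) {
    stop("range must be positive", call. = FALSE)
  }
  if (!is.finite(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  range_ / (1 + 3.332 * log10(n))
}

#' @rdname sturges_class_width
#' @export
sturges_class_count <- function(n) {
  if (!is.finite(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  round(1 + 3.332 * log10(n))
}

#' Class households into income classes
#'
#' Groups household records into contiguous, integer-bounded, inclusive
#' income classes (in million IDR) and summarises each class: counts,
#' person totals, total annual net income and income per person per day in
#' US$. By default the class width is Sturges' width for the observed
#' range, rounded to the nearest whole million IDR, with the lowest bound
#' at `floor(min(income))`; explicit bounds (e.g. a published classing)
#' can be supplied instead.
#'
#' @param records Data frame with columns `net_income` (million IDR yr^-1,
#'   > 0) and `household_size` (persons, >= 1); an optional `cost` column
#'   is ignored here.
#' @param config A [valuation_config()]; supplies the exchange rate and
#'   days per year.
#' @param bounds Optional data frame with integer columns `lower` and
#'   `upper` defining the classes. Membership is by inclusive bounds; a
#'   non-integer income between two classes falls in the class whose
#'   `upper` is the last bound below it plus one (i.e. classes cover the
#'   half-open intervals `[lower, upper + 1)`), so contiguous printed
#'   classes like 13-16, 17-20 tile the whole range.
#' @return Data frame of class summaries: `lower`, `upper`,
#'   `median_income` (class midpoint, million IDR), `n_households`,
#'   `persons_per_household` (mean), `total_persons`, `total_net_income`
#'   (million IDR yr^-1) and `usd_per_person_day`. Classes with no
#'   households get zero totals and `NA` daily income.
#' @examples
#' hh <- data.frame(net_income = c(14.5, 18.5, 34.5),
#'                  household_size = c(3, 3, 3))
#' classify_households(hh)
#' @export
classify_households <- function(records, config = valuation_config(),
                                bounds = NULL) {
  if (is.null(records$net_income) || nrow(records) == 0L) {
    stop("need a non-empty data frame with a 'net_income' column",
         call. = FALSE)
  }
  inc <- records$net_income
  size <- records$household_size
  if (is.null(size)) size <- rep(1L, length(inc))
  if (any(!is.finite(inc)) || any(inc <= 0)) {
    stop("net incomes must be positive", call. = FALSE)
  }
  if (any(size < 1)) stop("household sizes must be >= 1", call. = FALSE)

  if (is.null(bounds)) {
    rng <- diff(range(inc))
    w <- if (rng > 0) max(1, round(sturges_class_width(rng, length(inc))))
         else 1
    lo0 <- floor(min(inc))
    k <- ceiling((floor(max(inc)) - lo0 + 1) / w)
    bounds <- data.frame(lower = lo0 + (seq_len(k) - 1L) * w)
    bounds$upper <- bounds$lower + w - 1L
  }
  if (is.null(bounds$lower) || is.null(bounds$upper) ||
      any(bounds$upper < bounds$lower)) {
    stop("bounds must have 'lower' and 'upper' columns with upper >= lower",
         call. = FALSE)
  }
  # inclusive integer bounds; class i covers [lower_i, upper_i + 1)
  idx <- findInterval(inc, bounds$lower)
  if (any(idx == 0L) || any(inc >= bounds$upper[nrow(bounds)] + 1)) {
    stop("supplied class bounds do not cover all incomes", call. = FALSE)
  }
  agg <- function(v) as.numeric(tapply(v, factor(idx, seq_len(nrow(bounds))),
                                       sum, default = 0))
  out <- data.frame(
    lower = bounds$lower,
    upper = bounds$upper,
    median_income = (bounds$lower + bounds$upper) / 2,
    n_households = agg(rep(1, length(inc))),
    total_persons = agg(size),
    total_net_income = agg(inc)
  )
  out$persons_per_household <- ifelse(out$n_households > 0,
                                      out$total_persons / out$n_households,
                                      NA_real_)
  out$usd_per_person_day <- ifelse(
    out$total_persons > 0,
    out$total_net_income * 1e6 / out$total_persons /
      config$days_per_year / config$fx,
    NA_real_)
  out[c("lower", "upper", "median_income", "n_households",
        "persons_per_household", "total_persons", "total_net_income",
        "usd_per_person_day")]
}

#' Annual income from wood production
#'
#' Direct-use value of the standing stock spread over one rotation:
#' `area * volume_per_ha * price / rotation_years`, in IDR per year.
#'
#' @param config A [valuation_config()].
#' @param standing_volume Standing volume, m^3 ha^-1 (>= 0).
#' @return Annual wood income, IDR yr^-1.
#' @examples
#' wood_annual_income(valuation_config(), 98.99)  # ~742 million IDR/yr
#' @export
wood_annual_income <- function(config, standing_volume) {
  if (any(!is.finite(standing_volume)) || any(standing_volume < 0)) {
    stop("standing volume must be non-negative", call. = FALSE)
  }
  config$area_ha * standing_volume * config$price_idr_per_m3 /
    config$rotation_years
}

#' Income per person per day
#'
#' Converts an annual income in IDR to income per person per day, in IDR or
#' US$: `annual / population / days_per_year`, divided by the exchange rate
#' when `in_usd`.
#'
#' @param annual_idr Annual income, IDR yr^-1 (>= 0).
#' @param config A [valuation_config()]; supplies population, days per
#'   year and exchange rate.
#' @param in_usd Convert to US$ at `config$fx`? Default `FALSE` (IDR).
#' @return Income per person per day. Vectorised in `annual_idr` (linear).
#' @examples
#' per_person_per_day(1080353280, valuation_config())           # ~18048 IDR
#' per_person_per_day(742425000, valuation_config(), in_usd = TRUE)  # ~0.933
#' @export
per_person_per_day <- function(annual_idr, config = valuation_config(),
                               in_usd = FALSE) {
  if (any(!is.finite(annual_idr)) || any(annual_idr < 0)) {
    stop("annual income must be non-negative", call. = FALSE)
  }
  out <- annual_idr / config$population / config$days_per_year
  if (in_usd) out <- out / config$fx
  out
}

#' Overfishing rate
#'
#' Relative excess of fishing income over wood-harvest income per person
#' per day, `100 * (fishing - wood) / wood` percent; used as a proxy for
#' fishing pressure when fishing pays better than sustainable wood
#' harvest. Scale-invariant: both incomes may be in IDR or US$ as long as
#' the units agree.
#'
#' @param fishing_pppd Fishing income per person per day.
#' @param wood_pppd Wood income per person per day (> 0).
#' @return Overfishing rate, percent.
#' @examples
#' overfishing_rate(18048.3, 12402.6)  # ~45.5
#' @export
overfishing_rate <- function(fishing_pppd, wood_pppd) {
  if (any(!is.finite(wood_pppd)) || any(wood_pppd <= 0)) {
    stop("wood income must be positive", call. = FALSE)
  }
  100 * (fishing_pppd - wood_pppd) / wood_pppd
}

#' Diminishing-returns table of monthly NRR
#'
#' Computes the monthly nominal rate of return for a series of annual
#' (net income, cost) pairs and marks the row with the highest return;
#' ties are broken by the first occurrence. Plotted against cost this
#' exhibits the diminishing-marginal-returns hump typical of small-scale
#' fisheries investment.
#'
#' @param net,cost Annual net incomes and operating costs, million IDR
#'   (all > 0), equal length.
#' @return Data frame with columns `net`, `cost`, `nrr_pct` and logical
#'   `is_max`; the attribute `peak` holds the index of the maximum row.
#' @examples
#' diminishing_returns(c(14.5, 26.5), c(7, 10))
#' @export
diminishing_returns <- function(net, cost) {
  if (length(net) == 0L || length(net) != length(cost)) {
    stop("need equal-length, non-empty net and cost vectors", call. = FALSE)
  }
  r <- monthly_nrr(net, cost)
  i <- which.max(r)
  out <- data.frame(net = net, cost = cost, nrr_pct = r,
                    is_max = seq_along(r) == i)
  attr(out, "peak") <- i
  out
}
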