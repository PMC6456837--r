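#' Stem volume from diameter, height and form factor
#'
#' Volume of a single stem as the cylinder on its basal area, reduced by the
#' form factor: `V = (pi/4) * (d/100)^2 * h * f`. Diameter is taken in cm
#' and converted to m internally; the result is in cubic metres.
#'
#' @param d Stem diameter, cm (> 0).
#' @param h Branch-free height, m (> 0).
#' @param f Form factor, dimensionless in (0, 1].
#' @return Stem volume, m^3. Vectorised over its arguments.
#' @examples
#' tree_volume(5.0, 2.0, 0.85)
#' @export
tree_volume <- function(d, h, f) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("diameter must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("height must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(f)) || any(f <= 0 | f > 1)) {
    stop("form factor must lie in (0, 1]", call. = FALSE)
  }
  (pi / 4) * (d / 100)^2 * h * f
}

#' Standing volume per hectare
#'
#' Stand-level volume as stocking times mean stem volume:
#' `N * (pi/4) * (D/100)^2 * H * F`, in m^3 per hectare.
#'
#' @param n Stocking, stems per hectare (>= 0).
#' @param d,h,f Mean stem attributes, as in [tree_volume()].
#' @return Standing volume, m^3 ha^-1. Vectorised.
#' @examples
#' stand_volume(2500, 5.0, 2.0, 0.85)  # ~8.34 m^3/ha
#' @export
stand_volume <- function(n, d, h, f) {
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("stocking must be non-negative and finite", call. = FALSE)
  }
  n * tree_volume(d, h, f)
}

#' Mean annual increment
#'
#' MAI at age `t` is the total standing volume divided by the stand age,
#' `V_t / t`. Its culmination age is the classical biological rotation age.
#'
#' @param v Total standing volume, m^3 ha^-1 (>= 0).
#' @param t Stand age, years (> 0).
#' @return MAI, m^3 ha^-1 yr^-1. Vectorised.
#' @examples
#' mai(134.64, 25)  # 5.39
#' @export
mai <- function(v, t) {
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("age must be positive", call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("volume must be non-negative", call. = FALSE)
  }
  v / t
}

#' Periodic annual increment
#'
#' PAI (also called current annual increment, CAI) between two measurement
#' ages is the volume difference divided by the interval length,
#' `(V_t - V_prev) / dt`. It may be negative if volume declines.
#'
#' @param v_t Volume at the later age, m^3 ha^-1.
#' @param v_prev Volume at the earlier age, m^3 ha^-1.
#' @param dt Interval between the two ages, years (> 0); irregular
#'   measurement intervals are used as given, never an assumed 1-year step.
#' @return PAI, m^3 ha^-1 yr^-1. Vectorised.
#' @examples
#' pai(98.99, 83.90, 2)  # 7.55
#' @export
pai <- function(v_t, v_prev, dt) {
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    stop("interval must be positive", call. = FALSE)
  }
  (v_t - v_prev) / dt
}

#' Growth summary of a stand table
#'
#' Augments each row of a stand table with total standing volume (via
#' [stand_volume()]), MAI and PAI. PAI uses the actual interval to the
#' previous measurement age and is `NA` for the first row, where no
#' previous measurement exists.
#'
#' @param table A [stand_table()].
#' @return A data frame of class `growth_table` with the stand-table
#'   columns plus `tv`, `mai` and `pai` (first `pai` is `NA`). Values are
#'   kept in full precision; round only for presentation.
#' @examples
#' st <- stand_table(age = c(3, 7), n = c(2500, 1750),
#'                   d = c(5.0, 7.2), h = c(2.0, 4.0), f = c(0.85, 0.82))
#' growth_table(st)
#' @export
growth_table <- function(table) {
  validate_stand_table(table)
  tv <- stand_volume(table$n, table$d, table$h, table$f)
  out <- as.data.frame(table)
  out$tv <- tv
  out$mai <- mai(tv, table$age)
  out$pai <- c(NA_real_,
               if (nrow(out) > 1L) pai(tv[-1L], tv[-nrow(out)],
                                       diff(table$age)))
  class(out) <- c("growth_table", "data.frame")
  attr(out, "label") <- attr(table, "label")
  out
}

#' Culmination point of the MAI series
#'
#' Returns the age and value at which mean annual increment peaks; ties are
#' broken by the earliest age, the economically relevant rotation signal.
#'
#' @param growth A `growth_table` (from [growth_table()]) or any data frame
#'   with `age` and `mai` columns.
#' @return A list with elements `age` (years) and `mai` (m^3 ha^-1 yr^-1).
#' @examples
#' st <- stand_table(age = c(10, 20, 30), n = c(2000, 1500, 1000),
#'                   d = c(8, 14, 18), h = c(5, 9, 11), f = c(0.8, 0.7, 0.6))
#' peak_mai(growth_table(st))
#' @export
peak_mai <- function(growth) {
  if (is.null(growth$mai) || is.null(growth$age) || nrow(growth) == 0L) {
    stop("need a non-empty growth table with 'age' and 'mai' columns",
         call. = FALSE)
  }
  i <- which.max(growth$mai)  # which.max takes the first maximum
  list(age = growth$age[i], mai = growth$mai[i])
}
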