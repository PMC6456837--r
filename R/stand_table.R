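#' Construct a stand table
#'
#' A stand table summarises an even-aged stand at a sequence of measurement
#' ages: stocking, mean stem diameter, branch-free height and form factor.
#' It is the basic input of all growth-and-yield computations in this
#' package.
#'
#' @param age Stand ages in years; strictly increasing positive integers.
#' @param n Stocking, live stems per hectare (non-negative).
#' @param d Mean stem diameter at each age, cm (> 0).
#' @param h Mean branch-free height at each age, m (> 0).
#' @param f Stem form factor at each age, dimensionless in (0, 1].
#' @param label Free-text label, e.g. `"pre-thinning"`.
#'
#' @return A data frame of class `stand_table` with columns
#'   `age`, `n`, `d`, `h`, `f` and a `label` attribute.
#' @examples
#' stand_table(age = c(3, 7), n = c(2500, 1750),
#'             d = c(5.0, 7.2), h = c(2.0, 4.0), f = c(0.85, 0.82))
#' @export
stand_table <- function(age, n, d, h, f, label = "") {
  x <- data.frame(age = as.numeric(age), n = as.numeric(n),
                  d = as.numeric(d), h = as.numeric(h), f = as.numeric(f))
  class(x) <- c("stand_table", "data.frame")
  attr(x, "label") <- as.character(label)[1]
  validate_stand_table(x)
  x
}

#' Validate a stand table
#'
#' Checks the structural invariants of a [stand_table()]: non-empty,
#' strictly increasing positive ages, non-negative stocking, positive
#' diameter and height, form factor in (0, 1].
#'
#' @param x A `stand_table` (or a data frame with its columns).
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_stand_table <- function(x) {
  req <- c("age", "n", "d", "h", "f")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("stand table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0L) stop("stand table has no rows", call. = FALSE)
  bad_num <- which(!stats::complete.cases(x[req]) |
                     !apply(x[req], 1L, function(r) all(is.finite(r))))
  if (length(bad_num)) {
    stop("non-numeric or missing value in stand table row ", bad_num[1L],
         call. = FALSE)
  }
  if (any(x$age <= 0)) {
    stop("ages must be positive (row ", which(x$age <= 0)[1L], ")",
         call. = FALSE)
  }
  if (nrow(x) > 1L && any(diff(x$age) <= 0)) {
    stop("ages must be strictly increasing (row ",
         which(diff(x$age) <= 0)[1L] + 1L, ")", call. = FALSE)
  }
  if (any(x$n < 0)) {
    stop("stocking must be non-negative (row ", which(x$n < 0)[1L], ")",
         call. = FALSE)
  }
  if (any(x$d <= 0) || any(x$h <= 0)) {
    stop("diameter and height must be positive (row ",
         which(x$d <= 0 | x$h <= 0)[1L], ")", call. = FALSE)
  }
  if (any(x$f <= 0 | x$f > 1)) {
    stop("form factor must lie in (0, 1] (row ",
         which(x$f <= 0 | x$f > 1)[1L], ")", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.stand_table <- function(x, ...) {
  lbl <- attr(x, "label")
  cat("Stand table", if (nzchar(lbl)) paste0(" (", lbl, ")"), ": ",
      nrow(x), " ages, ", min(x$age), "-", max(x$age), " yr\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
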