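#' Read a stand table from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns
#' `age,n,d_cm,h_m,f` (extra columns are ignored), one row per measurement
#' age. Row-level validation failures are reported with the file line
#' number (header is line 1).
#'
#' @param path Path to the CSV file.
#' @param label Label for the resulting table; defaults to the file name.
#' @return A [stand_table()].
#' @export
read_stand_table <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    stop("cannot parse ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  req <- c("age", "n", "d_cm", "h_m", "f")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) stop(path, ": no data rows", call. = FALSE)
  for (col in req) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad)) {
      stop(path, " line ", bad[1L] + 1L, ": non-numeric value in column '",
           col, "'", call. = FALSE)
    }
    raw[[col]] <- v
  }
  if (nrow(raw) > 1L && any(diff(raw$age) <= 0)) {
    stop(path, " line ", which(diff(raw$age) <= 0)[1L] + 2L,
         ": ages not strictly increasing", call. = FALSE)
  }
  stand_table(age = raw$age, n = raw$n, d = raw$d_cm, h = raw$h_m,
              f = raw$f, label = label)
}

#' Write a growth table to CSV
#'
#' Emits `age,n,d_cm,h_m,f,tv,mai,pai`; the first row's `pai` cell is left
#' empty. Values are written in full precision unless `digits` is given
#' (presentation rounding only — keep analysis files unrounded).
#'
#' @param growth A `growth_table` from [growth_table()].
#' @param path Output path.
#' @param digits Optional number of decimals for `tv`, `mai`, `pai`.
#' @return `path`, invisibly.
#' @export
write_growth_table <- function(growth, path, digits = NULL) {
  out <- data.frame(age = growth$age, n = growth$n, d_cm = growth$d,
                    h_m = growth$h, f = growth$f, tv = growth$tv,
                    mai = growth$mai, pai = growth$pai)
  if (!is.null(digits)) {
    for (col in c("tv", "mai", "pai")) out[[col]] <- round(out[[col]], digits)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tree list from CSV
#'
#' Expects header `diameter_cm,height_m` (height optional), one row per
#' tree, as consumed by [low_thin()].
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `diameter` and (if present) `height`.
#' @export
read_tree_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(raw$diameter_cm)) {
    stop(path, ": missing column 'diameter_cm'", call. = FALSE)
  }
  out <- data.frame(diameter = as.numeric(raw$diameter_cm))
  if (!is.null(raw$height_m)) out$height <- as.numeric(raw$height_m)
  if (any(is.na(out$diameter))) {
    stop(path, " line ", which(is.na(out$diameter))[1L] + 1L,
         ": non-numeric diameter", call. = FALSE)
  }
  out
}

#' Read household income records from CSV
#'
#' Expects header `net_income_midr,cost_midr,household_size` (cost
#' optional); incomes and costs in million IDR per year.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `net_income`, `cost` (if present) and
#'   `household_size`.
#' @export
read_households <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(raw$net_income_midr) || is.null(raw$household_size)) {
    stop(path, ": need columns 'net_income_midr' and 'household_size'",
         call. = FALSE)
  }
  out <- data.frame(net_income = as.numeric(raw$net_income_midr),
                    household_size = as.integer(raw$household_size))
  if (!is.null(raw$cost_midr)) out$cost <- as.numeric(raw$cost_midr)
  out
}

#' Read a valuation configuration from a flat key-value file
#'
#' Parses lines of the form `key = value` (or `key: value`; `#` starts a
#' comment). Recognised keys are the arguments of [valuation_config()];
#' unknown keys are an error, absent keys keep their defaults.
#'
#' @param path Path to the configuration file.
#' @return A [valuation_config()].
#' @export
read_valuation_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[=:]\\s*(.+)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) {
    stop(path, ": cannot parse line '", lines[bad[1L]], "'", call. = FALSE)
  }
  keys <- vapply(kv, `[`, "", 2L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 3L)))
  known <- names(formals(valuation_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop(path, ": unknown key(s) ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(vals))) {
    stop(path, ": non-numeric value for key ", keys[which(is.na(vals))[1L]],
         call. = FALSE)
  }
  do.call(valuation_config, as.list(stats::setNames(vals, keys)))
}

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits,
                                       big.mark = "")

#' Write a combined analysis report
#'
#' Writes a plain-text report with machine-readable CSV sections (growth
#' tables, thinning contrast, valuation) followed by a human-readable
#' summary of the headline quantities: MAI culmination, MAI gain, annual
#' incomes and the overfishing rate. Sections whose input is `NULL` are
#' omitted. CSV sections carry full precision; only the summary is rounded
#' to `digits` decimals.
#'
#' @param path Output path.
#' @param growth A `growth_table`, or a named list of them, or `NULL`.
#' @param contrast Output of [thinning_contrast()], or `NULL`.
#' @param valuation Named list as returned in the `valuation` element of
#'   [run_balikpapan_scenario()], or `NULL`.
#' @param digits Decimals used in the summary section (default 2).
#' @return `path`, invisibly.
#' @export
write_report <- function(path, growth = NULL, contrast = NULL,
                         valuation = NULL, digits = 2) {
  if (digits < 0) stop("digits must be >= 0", call. = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  section <- function(name, df) {
    writeLines(paste0("# ", name), con)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    writeLines("", con)
  }
  if (!is.null(growth)) {
    if (is.data.frame(growth)) growth <- list(growth = growth)
    for (nm in names(growth)) section(paste("growth:", nm), growth[[nm]])
  }
  if (!is.null(contrast)) section("thinning contrast", contrast)
  if (!is.null(valuation)) {
    section("valuation", as.data.frame(valuation))
  }
  writeLines("# summary", con)
  if (!is.null(growth)) {
    for (nm in names(growth)) {
      pk <- peak_mai(growth[[nm]])
      writeLines(sprintf("peak MAI (%s): %s m3/ha/yr at age %d", nm,
                         fmt_num(pk$mai, digits), as.integer(pk$age)), con)
    }
  }
  if (!is.null(contrast)) {
    i <- which.max(contrast$mai_gain_pct)
    writeLines(sprintf(
      "stems removed: %d-%d per ha; max MAI gain %s%% at age %d",
      as.integer(min(contrast$stems_removed)),
      as.integer(max(contrast$stems_removed)),
      fmt_num(contrast$mai_gain_pct[i], digits),
      as.integer(contrast$age[i])), con)
  }
  if (!is.null(valuation)) {
    writeLines(sprintf(
      "wood income: %s IDR/yr (%s US$/person/day)",
      fmt_num(valuation$wood_annual_idr, 0),
      fmt_num(valuation$wood_pppd_usd, 3)), con)
    writeLines(sprintf(
      "fishing income: %s IDR/yr (%s IDR/person/day)",
      fmt_num(valuation$fishing_annual_idr, 0),
      fmt_num(valuation$fishing_pppd_idr, 0)), con)
    writeLines(sprintf("overfishing rate: %s%%",
                       fmt_num(valuation$overfishing_pct, 1)), con)
  }
  invisible(path)
}
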