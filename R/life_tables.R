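#' Construct and validate a life table
#'
#' A life table maps integer age (years) to the annual probability of death
#' `qx`. Ages must be contiguous and `qx` in \[0, 1\]; the terminal age may
#' (and in the bundled table does) carry `qx = 1`.
#'
#' @param age Integer ages, contiguous and strictly increasing.
#' @param qx Annual death probabilities, same length as `age`.
#' @return A `life_table` tibble with columns `age` and `qx`.
#' @export
life_table <- function(age, qx) {
  tb <- tibble::tibble(age = as.integer(age), qx = as.numeric(qx))
  if (nrow(tb) == 0) abort("life table is empty", class = "netcea_validation_error")
  if (anyNA(tb)) abort("life table contains missing values",
                       class = "netcea_validation_error")
  if (any(diff(tb$age) != 1L)) {
    abort("life table ages must be contiguous and strictly increasing",
          class = "netcea_validation_error")
  }
  if (any(tb$qx < 0 | tb$qx > 1)) {
    abort("life table qx values must lie in [0, 1]",
          class = "netcea_validation_error")
  }
  class(tb) <- c("life_table", class(tb))
  tb
}

#' Read a life table from CSV
#'
#' Expects two columns, age and annual death probability, in that order; a
#' header row is optional. Validation (contiguous ages, `qx` in \[0, 1\]) is
#' applied on read.
#'
#' @param path CSV file path.
#' @return A `life_table` tibble.
#' @seealso [write_life_table()]
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Life table file not found: ", path), class = "netcea_input_error")
  }
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*[0-9]", first)
  tb <- readr::read_csv(path, col_names = has_header, show_col_types = FALSE)
  life_table(tb[[1]], tb[[2]])
}

#' Write a life table to CSV
#'
#' @param lt A `life_table`.
#' @param path Output CSV path (columns `age`, `qx`).
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  readr::write_csv(tibble::tibble(age = lt$age, qx = lt$qx), path)
  invisible(path)
}

#' Bundled synthetic US-style period life table
#'
#' Loads the life table shipped with the package: a synthetic
#' Gompertz–Makeham approximation of an adult US period mortality curve
#' (see [synth_life_table()]), covering ages 0–100 with `qx = 1` at 100.
#' It stands in for the published US life tables so that base-case runs need
#' no download; it is an approximation, not a reproduction of any specific
#' vintage.
#'
#' @return A `life_table` tibble.
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "life_table_us_synthetic.csv",
                      package = "netcea", mustWork = TRUE)
  load_life_table(path)
}

#' Background mortality at a given age
#'
#' The annual other-cause death probability is the life-table `qx` at `age`
#' multiplied by a relative risk and clamped to \[0, 1\].
#'
#' @param lt A `life_table`.
#' @param age Age in whole years; must be covered by the table.
#' @param rr Relative-risk multiplier (>= 0), default 1.
#' @return Annual death probability in \[0, 1\].
#' @export
background_death_prob <- function(lt, age, rr = 1) {
  if (any(rr < 0)) abort("`rr` must be >= 0", class = "netcea_domain_error")
  i <- match(as.integer(age), lt$age)
  if (anyNA(i)) {
    abort(paste0("age ", paste(age[is.na(i)], collapse = ", "),
                 " outside life table range ", min(lt$age), "-", max(lt$age)),
          class = "netcea_domain_error")
  }
  pmin(1, lt$qx[i] * rr)
}

#' Synthesize a Gompertz–Makeham life table
#'
#' Annual death probability `qx(age) = min(1, a + b * exp(c * age))`, with the
#' terminal age forced to `qx = 1`. The defaults (`a = 5e-4`, `b = 3e-5`,
#' `c = 0.09`) trace a plausible adult US period mortality curve: roughly
#' 9 per 10,000 at age 30, rising exponentially to near-certain death by 100.
#'
#' @param a Makeham (age-independent) hazard term, >= 0.
#' @param b Gompertz level, > 0.
#' @param c Gompertz slope (per year of age), > 0.
#' @param max_age Terminal age; `qx(max_age)` is set to 1.
#' @return A `life_table` covering ages 0 to `max_age`.
#' @examples
#' lt <- synth_life_table()
#' background_death_prob(lt, 40)
#' @export
synth_life_table <- function(a = 5e-4, b = 3e-5, c = 0.09, max_age = 100) {
  if (a < 0) abort("`a` must be >= 0", class = "netcea_domain_error")
  if (b <= 0 || c <= 0) abort("`b` and `c` must be > 0", class = "netcea_domain_error")
  age <- 0:max_age
  qx <- pmin(1, a + b * exp(c * age))
  qx[length(qx)] <- 1
  life_table(age, qx)
}
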