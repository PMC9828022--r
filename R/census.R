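#' Age-structured abundance table
#'
#' Container for per-year, per-age stock-assessment output: abundance at
#' the start of the year, total mortality (natural + fishing), maturity
#' proportion and relative fecundity. On construction, abundance is
#' multiplied by maturity so that downstream formulas operate on mature
#' (breeding) numbers.
#'
#' @param df Data frame with columns `year`, `age`, `N` (abundance at year
#'   start), `Z` (total mortality per year), `maturity` (proportion mature
#'   in the age class) and `fecundity` (relative eggs per mature female).
#' @param p Fraction of the year elapsed at peak spawning (default 10/12,
#'   i.e. around 1 November).
#' @return An object of class `age_table`.
#' @export
age_table <- function(df, p = 10 / 12) {
  need <- c("year", "age", "N", "Z", "maturity", "fecundity")
  if (!all(need %in% names(df))) {
    stop("age table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$N < 0)) stop("N must be >= 0")
  if (any(df$Z < 0)) stop("Z must be >= 0")
  if (any(df$maturity < 0 | df$maturity > 1)) stop("maturity must be in [0, 1]")
  if (any(df$fecundity < 0)) stop("fecundity must be >= 0")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (anyDuplicated(df[c("year", "age")])) stop("duplicate year/age rows")
  df <- df[order(df$year, df$age), , drop = FALSE]
  df$N_mature <- df$N * df$maturity
  structure(list(data = df, p = p), class = "age_table")
}

#' @export
print.age_table <- function(x, ...) {
  yrs <- range(x$data$year)
  cat("age_table:", yrs[1], "-", yrs[2], "; ages",
      min(x$data$age), "-", max(x$data$age), "; p =",
      format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Read an age-structured table from delimited text
#'
#' @param path TSV/CSV file with the [age_table()] columns.
#' @param sep Field separator (default tab).
#' @param p Fraction of year elapsed at peak spawning.
#' @return An `age_table`.
#' @export
read_age_table <- function(path, sep = "\t", p = 10 / 12) {
  if (!file.exists(path)) stop("age table not found: ", path)
  age_table(utils::read.table(path, header = TRUE, sep = sep), p = p)
}

#' Abundance of breeding adults at peak spawning
#'
#' `N_ps,t = sum_a N_a,t * exp(-p * Z_a,t)` over mature numbers, i.e. the
#' start-of-year mature abundance of each age class discounted by total
#' mortality to the within-year moment of peak spawning.
#'
#' @param tbl An [age_table()].
#' @param year Year to evaluate (must be present in the table).
#' @return Peak-spawning abundance (same units as `N`).
#' @export
peak_spawning_abundance <- function(tbl, year) {
  stopifnot(inherits(tbl, "age_table"))
  d <- tbl$data[tbl$data$year == year, , drop = FALSE]
  if (nrow(d) == 0) stop("year not in table: ", year)
  sum(d$N_mature * exp(-tbl$p * d$Z))
}

#' Fecundity-weighted generation length
#'
#' Per year, female generation length is the average age of mature females
#' weighted by egg production (`sum a N m f / sum N m f`); male generation
#' length assumes equal contribution per mature individual
#' (`sum a N m / sum N m`). The sex-averaged value is the mean of the two,
#' and years in `years_range` are averaged with equal weight.
#'
#' @param tbl An [age_table()].
#' @param years_range Years to average over (default: all years present).
#' @return List with `female`, `male` and `average` generation lengths in
#'   years, plus `per_year` (data frame).
#' @export
generation_length <- function(tbl, years_range = NULL) {
  stopifnot(inherits(tbl, "age_table"))
  years_range <- years_range %||% sort(unique(tbl$data$year))
  per <- do.call(rbind, lapply(years_range, function(y) {
    d <- tbl$data[tbl$data$year == y, , drop = FALSE]
    if (nrow(d) == 0) stop("year not in table: ", y)
    wf <- d$N_mature * d$fecundity
    wm <- d$N_mature
    if (sum(wf) <= 0 || sum(wm) <= 0) {
      stop("no mature fish (zero denominator) in year ", y)
    }
    data.frame(year = y,
               female = sum(d$age * wf) / sum(wf),
               male = sum(d$age * wm) / sum(wm))
  }))
  fem <- mean(per$female)
  mal <- mean(per$male)
  list(female = fem, male = mal, average = (fem + mal) / 2, per_year = per)
}

#' Effective-to-census population size ratio
#'
#' @param ne_diploid Effective population size (diploid individuals).
#' @param nc Census abundance (> 0).
#' @return `ne_diploid / nc`.
#' @export
ne_nc_ratio <- function(ne_diploid, nc) {
  if (any(nc <= 0)) stop("census size must be positive")
  ne_diploid / nc
}
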