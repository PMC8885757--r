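#' Convert reported whale-oil quantities to whale equivalents
#'
#' Historical whaling returns are frequently tabulated as oil landed rather
#' than whales killed. Oil is converted to barrels (1 tun = 8 barrels,
#' 1 cask = 6.5 barrels) and divided by the average right-whale yield.
#' Fractional whale equivalents are preserved: the production model is
#' continuous and rounding would bias low-catch years.
#'
#' @param amount Non-negative oil quantity (vectorised).
#' @param unit One of `"barrel"`, `"tun"`, `"cask"` (recycled against
#'   `amount`).
#' @param barrels_per_whale Average oil yield of one right whale, in barrels.
#'   Default 60.
#' @return Numeric vector of whale equivalents.
#' @examples
#' oil_to_whales(60, "barrel")   # 1 whale
#' oil_to_whales(15, "tun")      # 2 whales
#' @export
oil_to_whales <- function(amount, unit = c("barrel", "tun", "cask"),
                          barrels_per_whale = 60) {
  stopifnot(is.numeric(amount), all(is.finite(amount)), all(amount >= 0),
            is.numeric(barrels_per_whale), barrels_per_whale > 0)
  unit <- as.character(unit)
  bad <- !unit %in% c("barrel", "tun", "cask")
  if (any(bad)) {
    stop("unknown oil unit(s): ", paste(unique(unit[bad]), collapse = ", "),
         " (must be 'barrel', 'tun' or 'cask')")
  }
  per_barrel <- c(barrel = 1, tun = 8, cask = 6.5)
  amount * unname(per_barrel[unit]) / barrels_per_whale
}

#' Struck-and-lost correction factor for a given year
#'
#' Landed catches understate removals because some whales were fatally struck
#' but never secured. The correction is era specific: no correction before
#' 1771 or after 1973, a pre-modern factor for 1771-1850 and a modern factor
#' for 1851-1973 (era boundaries inclusive).
#'
#' @param year Integer calendar year(s) within 1648-2030.
#' @param slr1 Pre-modern (1771-1850) multiplier; base-case prior mean 1.6.
#' @param slr2 Modern (1851-1973) multiplier; base-case prior mean 1.09.
#' @return Numeric vector of multipliers, one per year.
#' @export
slr_factor <- function(year, slr1 = 1.6, slr2 = 1.09) {
  stopifnot(is.numeric(year), all(year >= 1648 & year <= 2030),
            is.numeric(slr1), length(slr1) == 1, is.finite(slr1), slr1 > 0,
            is.numeric(slr2), length(slr2) == 1, is.finite(slr2), slr2 > 0)
  out <- rep(1, length(year))
  out[year >= 1771 & year <= 1850] <- slr1
  out[year >= 1851 & year <= 1973] <- slr2
  out
}

validate_catch_bounds <- function(bounds) {
  stopifnot(is.data.frame(bounds),
            all(c("year", "c_min", "c_max") %in% names(bounds)))
  if (anyNA(bounds[c("year", "c_min", "c_max")])) {
    stop("catch bounds contain missing values")
  }
  if (any(bounds$c_min < 0)) stop("c_min must be non-negative")
  if (any(bounds$c_min > bounds$c_max)) {
    bad <- bounds$year[bounds$c_min > bounds$c_max]
    stop("c_min > c_max in year(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(bounds$year)) stop("duplicated years in catch bounds")
  bounds[order(bounds$year), , drop = FALSE]
}

#' Effective annual removals from low/high catch bounds
#'
#' The true landings in year y are interpolated between the low and high
#' reconstructed series by a single time-invariant catch parameter,
#' `C_y = c_min + pi * (c_max - c_min)`, then inflated by the era-specific
#' struck-and-lost factor. Years of the modelled era absent from `bounds`
#' are treated as zero catch (not missing): the state model needs a complete
#' series.
#'
#' @param bounds Data frame with columns `year`, `c_min`, `c_max`.
#' @param pi Catch parameter in `[0, 1]` mixing the low (0) and high (1)
#'   series.
#' @param slr1,slr2 Struck-and-lost multipliers (see [slr_factor()]).
#' @param years Optional integer vector of years over which to expand the
#'   series (default: the range of `bounds`).
#' @return Data frame with columns `year` and `catch_effective`.
#' @export
effective_catches <- function(bounds, pi, slr1 = 1.6, slr2 = 1.09,
                              years = NULL) {
  stopifnot(is.numeric(pi), length(pi) == 1, pi >= 0, pi <= 1)
  bounds <- validate_catch_bounds(bounds)
  if (is.null(years)) years <- seq(min(bounds$year), max(bounds$year))
  c_min <- c_max <- numeric(length(years))
  m <- match(years, bounds$year)
  hit <- !is.na(m)
  c_min[hit] <- bounds$c_min[m[hit]]
  c_max[hit] <- bounds$c_max[m[hit]]
  catch <- (c_min + pi * (c_max - c_min)) * slr_factor(years, slr1, slr2)
  data.frame(year = years, catch_effective = catch)
}

#' Read a catch-bounds table from CSV
#'
#' Expects header `year,c_min,c_max`; values are whales (possibly fractional
#' after oil conversion).
#'
#' @param path Path to a CSV file.
#' @return Validated data frame ordered by year.
#' @export
read_catch_series <- function(path) {
  validate_catch_bounds(utils::read.csv(path))
}

#' Write an effective catch series to CSV
#'
#' @param catches Data frame as returned by [effective_catches()].
#' @param path Output path; header is `year,catch_effective`.
#' @return `path`, invisibly.
#' @export
write_catch_series <- function(catches, path) {
  stopifnot(all(c("year", "catch_effective") %in% names(catches)))
  utils::write.csv(catches[c("year", "catch_effective")], path,
                   row.names = FALSE)
  invisible(path)
}
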