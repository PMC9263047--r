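#' Default adult age bands
#'
#' Builds the age banding used throughout the package: a first band spanning
#' ages 18--25, five-year bands 26--30 through 91--95, and an open-ended
#' band labelled `"95+"` (internally 96--100). Band midpoints are carried as
#' the numeric locations used by the irregular-spacing RW2 penalty, so the
#' wider first band makes the age axis genuinely irregular.
#'
#' @return A data frame with columns `label`, `lower`, `upper` (both
#'   inclusive, in years) and `midpoint`.
#' @export
#' @examples
#' head(default_age_bands())
default_age_bands <- function() {
  lower <- c(18, seq(26, 91, by = 5), 96)
  upper <- c(25, seq(30, 95, by = 5), 100)
  label <- c("18-25", paste0(seq(26, 91, by = 5), "-", seq(30, 95, by = 5)), "95+")
  data.frame(label = label, lower = lower, upper = upper,
             midpoint = (lower + upper) / 2, stringsAsFactors = FALSE)
}

#' Construct an age-period-cohort grid
#'
#' Defines the discretisation shared by aggregation, model fitting and
#' projection: ordered age bands, survey years (possibly unequally spaced),
#' half-open five-year birth-cohort bins `(lower, upper]`, and the integer
#' cohort index map `k = M(I - i) + j`. Cohort bins are anchored so that the
#' oldest band at the first period falls in the first bin; by default they
#' extend to cover every birth year reachable as `period - age` over the
#' grid. Numeric locations (band midpoints, calendar years, bin midpoints)
#' are stored per axis for the irregular-spacing RW2 penalties.
#'
#' @param age_bands Data frame as returned by [default_age_bands()].
#' @param periods Increasing integer vector of survey years.
#' @param M Number of periods per age band in the cohort index map
#'   (default 1; the five-year bands and near-five-year survey spacing make
#'   this the natural choice, with irregular spacing handled in the prior,
#'   not the index).
#' @param cohort_width Width of the cohort bins in years (default 5).
#' @return An object of class `apc_grid` with elements `age_bands`,
#'   `periods`, `cohort_bins` (data frame with `lower`, `upper`, `label`,
#'   `midpoint`), `M`, `I`, `J`, `K`, and `locations` (list with `age`,
#'   `period`, `cohort`).
#' @export
#' @examples
#' g <- apc_grid()
#' g$K            # number of cohort bins
#' g$cohort_bins$label[1]
apc_grid <- function(age_bands = default_age_bands(),
                     periods = c(1997L, 2001L, 2004L, 2008L, 2013L, 2018L),
                     M = 1L, cohort_width = 5L) {
  stopifnot(is.data.frame(age_bands), nrow(age_bands) >= 3,
            length(periods) >= 3, all(diff(periods) > 0), M >= 1)
  if (any(age_bands$lower > age_bands$upper))
    stop("age band lower bounds must not exceed upper bounds")
  if (any(diff(age_bands$lower) <= 0) ||
      any(age_bands$lower[-1] != age_bands$upper[-nrow(age_bands)] + 1))
    stop("age bands must be disjoint, ordered and contiguous")
  if (age_bands$lower[1] > 18)
    stop("first age band must cover age 18")

  I <- nrow(age_bands)
  J <- length(periods)
  K <- M * (I - 1L) + J

  # Anchor: cell (i = I, j = 1) has k = 1; its typical birth year is
  # periods[1] - midpoint[I].  Choose bin edges on multiples of cohort_width
  # so that this birth year falls in the first bin and the K bins then run
  # consecutively.  Extend to the right if period - age reaches further.
  birth_lo <- min(periods) - max(age_bands$upper)
  birth_hi <- max(periods) - min(age_bands$lower)
  first_upper <- cohort_width * ceiling(birth_lo / cohort_width)
  n_bins <- max(K, ceiling((birth_hi - first_upper) / cohort_width) + 1L)
  lower <- first_upper - cohort_width + cohort_width * (seq_len(n_bins) - 1L)
  upper <- lower + cohort_width
  bins <- data.frame(lower = lower, upper = upper,
                     label = sprintf("(%d, %d]", lower, upper),
                     midpoint = (lower + upper) / 2)

  structure(list(
    age_bands = age_bands, periods = as.integer(periods),
    cohort_bins = bins, M = as.integer(M),
    I = I, J = J, K = nrow(bins),
    locations = list(age = age_bands$midpoint,
                     period = as.numeric(periods),
                     cohort = bins$midpoint)
  ), class = "apc_grid")
}

#' @export
print.apc_grid <- function(x, ...) {
  cat("APC grid: ", x$I, " age bands (", x$age_bands$label[1], " .. ",
      x$age_bands$label[x$I], "), ", x$J, " periods (",
      min(x$periods), "-", max(x$periods), "), ", x$K,
      " cohort bins (", x$cohort_bins$label[1], " .. ",
      x$cohort_bins$label[x$K], "), M = ", x$M, "\n", sep = "")
  invisible(x)
}

#' Cohort index map
#'
#' Maps an (age band, period) cell to its birth-cohort index via
#' `k = M(I - i) + j`, so the oldest age band at the first period belongs to
#' the earliest cohort.
#'
#' @param i Age-band index (1 = youngest) in `1..I`.
#' @param j Period index in `1..J`.
#' @param M Periods per age band.
#' @param I Number of age bands.
#' @return Integer cohort index `k` in `1 .. M(I-1)+J`. Vectorised over
#'   `i` and `j`.
#' @export
#' @examples
#' cohort_index(2, 3, M = 1, I = 5)  # 6
cohort_index <- function(i, j, M, I) {
  if (any(i < 1L | i > I) || any(j < 1L))
    stop("cohort_index: age or period index out of range for this grid")
  as.integer(M * (I - i) + j)
}

#' Assign a birth year to a cohort bin
#'
#' Bins are half-open intervals `(lower, upper]`: the upper bound belongs to
#' the bin, the lower does not, matching the `(1895, 1900]` convention.
#'
#' @param birth_year Integer birth year(s).
#' @param bins Cohort-bin data frame (`lower`, `upper`) from an `apc_grid`.
#' @return Integer bin index per birth year.
#' @export
assign_cohort_bin <- function(birth_year, bins) {
  idx <- findInterval(birth_year, bins$lower + 1e-9) # (lower, upper]
  bad <- idx < 1L |
    birth_year > bins$upper[pmax(pmin(idx, nrow(bins)), 1L)] |
    birth_year <= bins$lower[1]
  if (any(bad))
    stop("birth year(s) ", paste(unique(birth_year[bad]), collapse = ", "),
         " outside cohort-bin coverage; rebuild the grid")
  as.integer(idx)
}

#' Locate ages in age bands
#'
#' @param age Integer ages.
#' @param grid An `apc_grid`.
#' @return Integer band index per age.
#' @export
age_band_index <- function(age, grid) {
  ab <- grid$age_bands
  idx <- findInterval(age, ab$lower)
  if (any(age < ab$lower[1]))
    stop("age below the first band; filter records to age >= ", ab$lower[1])
  if (any(age > ab$upper[nrow(ab)]))
    stop("age exceeds the oldest band (", ab$upper[nrow(ab)], ")")
  as.integer(idx)
}

#' Aggregate survey microdata into model-ready cell counts
#'
#' Collapses respondent records onto the (age band x period x stratum) grid.
#' In `crude` mode `y` is the respondent count with the outcome and `N` the
#' respondent count. In `effective` mode survey weights enter through the
#' Kish effective sample size: the cell prevalence is the weighted outcome
#' mean, `N = (sum w)^2 / sum(w^2)` and `y = prevalence * N`, so that
#' weighted information is neither over- nor under-counted in the binomial
#' likelihood. Cells in the observation window with no respondents are
#' emitted with `N = 0` and flagged `observed = FALSE`.
#'
#' @param records Microdata data frame (see [read_microdata()]); must contain
#'   `year`, `age`, the outcome column, `weight_survey`, and any stratum
#'   columns.
#' @param grid An `apc_grid`.
#' @param outcome `"overweight"` or `"obese"`.
#' @param strata Character vector of stratum column names (e.g. `"sex"`), or
#'   `NULL` for a pooled aggregation.
#' @param weighting `"crude"` or `"effective"`.
#' @return A data frame of class `cell_counts` with columns the stratum
#'   variables, `i`, `j`, `k`, `y`, `N`, `observed`.
#' @export
aggregate_cells <- function(records, grid, outcome = c("overweight", "obese"),
                            strata = "sex",
                            weighting = c("effective", "crude")) {
  outcome <- match.arg(outcome)
  weighting <- match.arg(weighting)
  if (!outcome %in% names(records))
    stop("outcome column '", outcome, "' not found in records")
  if (any(records$age < 18))
    stop("records must be filtered to age >= 18 before aggregation")
  if (any(is.na(records[[outcome]])))
    stop("records must have non-missing '", outcome, "' before aggregation")

  i <- age_band_index(records$age, grid)
  j <- match(records$year, grid$periods)
  if (any(is.na(j)))
    stop("record year(s) outside the grid periods: ",
         paste(unique(records$year[is.na(j)]), collapse = ", "))

  w <- if (weighting == "effective") records$weight_survey else rep(1, nrow(records))
  out <- as.numeric(records[[outcome]])

  strat_df <- if (length(strata)) records[, strata, drop = FALSE] else NULL
  key_levels <- if (length(strata)) {
    lapply(strat_df, function(v) sort(unique(v)))
  } else list()

  full <- expand.grid(c(key_levels, list(i = seq_len(grid$I), j = seq_len(grid$J))),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  keys <- c(lapply(seq_along(strata), function(s) strat_df[[s]]),
            list(i = i, j = j))
  names(keys) <- c(strata, "i", "j")
  grp <- interaction(as.data.frame(keys), drop = FALSE, lex.order = TRUE)

  sw   <- tapply(w, grp, sum)
  sw2  <- tapply(w^2, grp, sum)
  swy  <- tapply(w * out, grp, sum)
  n    <- tapply(rep(1, nrow(records)), grp, sum)

  key_full <- interaction(full, drop = FALSE, lex.order = TRUE)
  m <- match(as.character(key_full), names(sw))
  pick <- function(v) { out <- as.numeric(v[m]); out[is.na(out)] <- 0; out }
  sw <- pick(sw); sw2 <- pick(sw2); swy <- pick(swy); n <- pick(n)

  if (weighting == "crude") {
    N <- n
    y <- swy # weights are 1 in crude mode
  } else {
    N <- ifelse(sw2 > 0, sw^2 / sw2, 0)
    phat <- ifelse(sw > 0, swy / sw, 0)
    y <- phat * N
  }

  res <- full
  res$k <- cohort_index(res$i, res$j, grid$M, grid$I)
  res$y <- as.numeric(y)
  res$N <- as.numeric(N)
  res$observed <- n > 0
  class(res) <- c("cell_counts", "data.frame")
  attr(res, "outcome") <- outcome
  attr(res, "weighting") <- weighting
  attr(res, "strata") <- strata
  res
}
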