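#' Body-mass-index category flags
#'
#' BMI is weight / height^2 (kg/m^2). Overweight is BMI >= 25 and obesity
#' BMI >= 30, both thresholds inclusive, so obesity implies overweight.
#'
#' @param height Height in metres (> 0).
#' @param weight Weight in kilograms (> 0).
#' @return Data frame with columns `bmi`, `overweight`, `obese`. Vectorised.
#' @export
#' @examples
#' bmi_flags(1.60, 80)   # bmi 31.25, overweight and obese
bmi_flags <- function(height, weight) {
  if (any(height <= 0, na.rm = TRUE) || any(weight <= 0, na.rm = TRUE))
    stop("height and weight must be positive")
  bmi <- weight / height^2
  data.frame(bmi = bmi, overweight = bmi >= 25, obese = bmi >= 30)
}

# Fixed euro bands for the income quintile labels.
income_breaks <- c(-Inf, 750, 1000, 1500, 2500, Inf)
income_labels <- c("<750", "750-1000", "1000-1500", "1500-2500", ">2500")

#' Equivalized household income and quintile band
#'
#' Divides total household income by an equivalence scale giving weight 1.0
#' to the first adult, 0.5 to each additional adult (18+ years) and 0.3 to
#' each child, then assigns the fixed euro bands "<750", "750-1000",
#' "1000-1500", "1500-2500", ">2500" (quintiles 1 to 5).
#'
#' @param member_ages Integer vector of household member ages (at least one
#'   adult).
#' @param total_income Total available household income, euro/month (>= 0).
#' @return List with `income` (equivalized euro/month), `quintile` (1..5)
#'   and `band` (label).
#' @export
#' @examples
#' equivalized_income(c(40, 38, 10), 3600)  # 2000 euro -> quintile 4
equivalized_income <- function(member_ages, total_income) {
  if (total_income < 0) stop("household income must be non-negative")
  adults <- sum(member_ages >= 18)
  children <- sum(member_ages < 18)
  if (adults < 1) stop("household must contain at least one adult")
  divisor <- 1.0 + 0.5 * (adults - 1) + 0.3 * children
  inc <- total_income / divisor
  q <- findInterval(inc, income_breaks[-1], left.open = TRUE) + 1L
  q <- min(q, 5L)
  list(income = inc, quintile = q, band = income_labels[q])
}

#' Filter microdata to the eligible analysis sample
#'
#' Retains respondents aged 18 or over with non-missing height and weight,
#' and reports the number removed per reason (a flowchart-style audit).
#'
#' @param records Microdata data frame with at least `age`, `height_m`,
#'   `weight_kg`.
#' @return The filtered data frame, with an attribute `removed` giving a
#'   named count per exclusion reason (`under_18`, `missing_anthropometry`).
#' @export
filter_eligible <- function(records) {
  if (nrow(records) == 0) {
    attr(records, "removed") <- c(under_18 = 0L, missing_anthropometry = 0L)
    return(records)
  }
  under <- !is.na(records$age) & records$age < 18
  kept <- records[!under, , drop = FALSE]
  miss <- is.na(kept$height_m) | is.na(kept$weight_kg)
  out <- kept[!miss, , drop = FALSE]
  attr(out, "removed") <- c(under_18 = sum(under),
                            missing_anthropometry = sum(miss))
  out
}

#' Crude outcome prevalence in a survey year
#'
#' @param records Microdata data frame with `year` and the outcome column.
#' @param outcome Outcome column name (`"overweight"` or `"obese"`).
#' @param year Survey year.
#' @return Proportion of respondents with the outcome among non-missing
#'   outcome values in that year.
#' @export
crude_prevalence <- function(records, outcome, year) {
  sub <- records[records$year == year & !is.na(records[[outcome]]), ]
  if (nrow(sub) == 0) stop("no eligible records in year ", year)
  mean(sub[[outcome]])
}

#' Design-weighted prevalence rate per 100,000
#'
#' Computes the survey-weighted prevalence, scaled to a rate per 100,000
#' population, with a normal-approximation interval whose standard error
#' uses the Kish effective sample size `(sum w)^2 / sum(w^2)`.
#'
#' @param records Microdata with `year`, the outcome column, and
#'   `weight_survey` (> 0).
#' @param outcome Outcome column name.
#' @param year Survey year.
#' @param conf Confidence level for the interval (default 0.95).
#' @return List with `rate`, `lower`, `upper` (per 100,000) and `n_eff`.
#' @export
weighted_rate_per_100k <- function(records, outcome, year, conf = 0.95) {
  sub <- records[records$year == year & !is.na(records[[outcome]]), ]
  w <- sub$weight_survey
  if (nrow(sub) == 0 || sum(w) <= 0) stop("no positive weight in year ", year)
  if (any(w <= 0)) stop("survey weights must be positive")
  p <- sum(w * sub[[outcome]]) / sum(w)
  n_eff <- sum(w)^2 / sum(w^2)
  se <- sqrt(pmax(p * (1 - p), 0) / n_eff)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(rate = 1e5 * p,
       lower = 1e5 * max(p - z * se, 0),
       upper = 1e5 * min(p + z * se, 1),
       n_eff = n_eff)
}

#' Percent change between two rates
#'
#' @param rate_from Baseline rate (> 0).
#' @param rate_to Later rate.
#' @return `100 * (rate_to - rate_from) / rate_from`, unrounded.
#' @export
#' @examples
#' percent_change(12978, 16339)  # 25.90
percent_change <- function(rate_from, rate_to) {
  if (any(rate_from <= 0)) stop("baseline rate must be positive")
  100 * (rate_to - rate_from) / rate_from
}

#' Read survey microdata from delimited text
#'
#' Reads the comma-separated microdata dialect with header columns `year`,
#' `age`, `sex`, `education`, `income_q`, `urbanisation`, `nationality`,
#' `height_m`, `weight_kg`, `weight_survey`, and derives `bmi`,
#' `overweight`, `obese`.
#'
#' @param path Path to a CSV file.
#' @return Microdata data frame with derived BMI columns.
#' @export
read_microdata <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "age", "sex", "education", "income_q", "urbanisation",
            "nationality", "height_m", "weight_kg", "weight_survey")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("microdata missing column(s): ", paste(miss, collapse = ", "))
  fl <- bmi_flags(rec$height_m, rec$weight_kg)
  rec$bmi <- fl$bmi; rec$overweight <- fl$overweight; rec$obese <- fl$obese
  rec
}

#' Write survey microdata to delimited text
#'
#' @param records Microdata data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(records, path) {
  keep <- c("year", "age", "sex", "education", "income_q", "urbanisation",
            "nationality", "height_m", "weight_kg", "weight_survey")
  utils::write.csv(records[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-wave descriptive summary
#'
#' A compact descriptive table per survey year: sample size, median age,
#' percentage women, and crude overweight/obesity prevalence (percent,
#' rounded to the nearest integer for display parity with survey reports).
#'
#' @param records Microdata data frame with derived outcome columns.
#' @return Data frame with one row per survey year.
#' @export
wave_summary <- function(records) {
  yrs <- sort(unique(records$year))
  do.call(rbind, lapply(yrs, function(y) {
    sub <- records[records$year == y, ]
    data.frame(
      year = y, n = nrow(sub),
      median_age = stats::median(sub$age),
      pct_woman = round(100 * mean(sub$sex == "woman")),
      pct_overweight = round(100 * crude_prevalence(sub, "overweight", y)),
      pct_obese = round(100 * crude_prevalence(sub, "obese", y))
    )
  }))
}
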