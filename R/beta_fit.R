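#' Fit the B-factor decay rate versus absorbed dose
#'
#' Linear fit `B = intercept + beta * dose` to a per-wedge B-factor series.
#' By default the fit is weighted by `1 / se_b^2` when standard errors are
#' available and finite; otherwise ordinary least squares is used.
#'
#' @param series A [scale_wedge_series()] result, or any data frame with
#'   columns `nominal_dose` and `b` (optionally `se_b`).
#' @param weighted Use inverse-variance weights when `se_b` is available
#'   (default `TRUE`).
#'
#' @return An object of class `decay_fit`: list with `beta` (slope, squared
#'   angstroms per MGy), `intercept`, `se_beta`, `r_squared`, `n`, the
#'   underlying `lm` fit and the data.
#' @export
#' @examples
#' d <- tibble::tibble(nominal_dose = 0:10, b = 1 + 0.9 * (0:10))
#' fit_beta(d)
fit_beta <- function(series, weighted = TRUE) {
  df <- tibble::as_tibble(series)
  stopifnot(all(c("nominal_dose", "b") %in% names(df)))
  df <- df[is.finite(df$nominal_dose) & is.finite(df$b), ]
  if (nrow(df) < 3) abort("need at least 3 wedges to fit beta")
  if (diff(range(df$nominal_dose)) <= 0) abort("doses have zero spread")
  w <- NULL
  if (weighted && "se_b" %in% names(df) &&
      all(is.finite(df$se_b)) && all(df$se_b > 0)) {
    w <- 1 / df$se_b^2
  }
  fit <- lm(b ~ nominal_dose, data = df, weights = w)
  sm <- suppressWarnings(summary(fit))  # exact series trip summary.lm
  structure(list(
    beta = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    se_beta = sm$coefficients[2, 2],
    r_squared = sm$r.squared,
    n = nrow(df),
    weighted = !is.null(w),
    fit = fit,
    data = df
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> beta = %.4g +/- %.2g A^2/MGy (intercept %.3g A^2, r^2 = %.4f, n = %d%s)\n",
    x$beta, x$se_beta, x$intercept, x$r_squared, x$n,
    if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' @rdname fit_beta
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "beta"),
    estimate = c(x$intercept, x$beta),
    std.error = c(suppressWarnings(summary(x$fit))$coefficients[1, 2], x$se_beta)
  )
}

#' @rdname fit_beta
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(beta = x$beta, se_beta = x$se_beta,
                 intercept = x$intercept, r.squared = x$r_squared,
                 nobs = x$n, weighted = x$weighted)
}

#' Population standard deviation
#'
#' `sqrt(mean((x - mean(x))^2))` — divisor `n`, not `n - 1`. This is the
#' convention used when summarizing per-position decay rates measured on
#' the same crystal.
#'
#' @param x Numeric vector with at least one finite value.
#' @return The population standard deviation.
#' @export
population_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 1) abort("population_sd needs at least one value")
  sqrt(mean((x - mean(x))^2))
}

# round half away from zero, for report tables
.round_report <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize decay rates measured at several crystal positions
#'
#' Averages the per-position decay rates of one sample, reports their
#' population standard deviation (flagged `NA` when only a single position
#' was measured) and applies the composition correction
#' `beta_corrected = beta / correction_factor` (see
#' [beta_correction_factor()]).
#'
#' @param betas Numeric vector of per-position decay rates, or a data frame
#'   with a `beta` column (extra columns such as `position` are kept).
#' @param correction_factor Ratio of true to nominal dose rate (default 1).
#'
#' @return An object of class `sensitivity_report`: tibble with one row per
#'   position (`position`, `beta`, `beta_corrected`) and attributes
#'   `beta_average`, `beta_std` (0 when a single position, with
#'   `std_is_na = TRUE`), `correction_factor`.
#' @export
summarize_positions <- function(betas, correction_factor = 1) {
  if (is.data.frame(betas)) {
    df <- tibble::as_tibble(betas)
    stopifnot("beta" %in% names(df))
    if (!"position" %in% names(df)) df$position <- seq_len(nrow(df))
  } else {
    df <- tibble::tibble(position = seq_along(betas), beta = as.numeric(betas))
  }
  if (nrow(df) < 1) abort("need at least one position")
  if (correction_factor <= 0) abort("correction_factor must be > 0")
  df$beta_corrected <- df$beta / correction_factor
  single <- nrow(df) == 1
  structure(df, class = c("sensitivity_report", class(df)),
            beta_average = mean(df$beta),
            beta_std = if (single) 0 else population_sd(df$beta),
            std_is_na = single,
            correction_factor = correction_factor)
}

#' @rdname summarize_positions
#' @param x A `sensitivity_report`.
#' @param ... Unused.
#' @method glance sensitivity_report
#' @export
glance.sensitivity_report <- function(x, ...) {
  tibble::tibble(
    n_positions = nrow(x),
    beta_average = attr(x, "beta_average"),
    beta_std = attr(x, "beta_std"),
    std_is_na = attr(x, "std_is_na"),
    correction_factor = attr(x, "correction_factor")
  )
}

#' Multi-sample sensitivity table
#'
#' Builds a report-style table from per-position decay rates of several
#' samples: per-sample average, population standard deviation (`NA` for
#' single-position samples) and composition-corrected rates, all rounded to
#' two decimals (half away from zero) as conventionally presented.
#'
#' @param df Data frame with columns `crystal`, `beta` and optionally
#'   `position` and `correction_factor` (per row or per crystal).
#'
#' @return Tibble with columns `crystal`, `position`, `beta`,
#'   `beta_average`, `beta_std`, `beta_corrected`.
#' @export
sensitivity_table <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("crystal", "beta") %in% names(df)))
  if (!"position" %in% names(df)) {
    df <- df |> dplyr::group_by(.data$crystal) |>
      dplyr::mutate(position = dplyr::row_number()) |> dplyr::ungroup()
  }
  if (!"correction_factor" %in% names(df)) df$correction_factor <- 1
  df |>
    dplyr::group_by(.data$crystal) |>
    dplyr::mutate(
      beta_average = .round_report(mean(.data$beta)),
      beta_std = ifelse(dplyr::n() == 1, NA_real_,
                        .round_report(population_sd(.data$beta))),
      beta_corrected = .round_report(.data$beta / .data$correction_factor)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("crystal", "position", "beta", "beta_average",
                  "beta_std", "beta_corrected")
}
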