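#' Resolution-shell statistics of a reflection table
#'
#' Bins reflections into equal-width shells in `s2` and reports per-shell
#' mean intensity, mean sigma and observation count. The last shell is the
#' highest-`s2` one; its `mean_J / mean_sigma` is the conventional
#' last-shell signal-to-noise ratio. Empty bins are merged into their lower
#' neighbour (the result is flagged via the `merged` attribute).
#'
#' @param reflections Tibble with columns `s2`, `J`, `sigma`, and
#'   optionally `shell`.
#' @param n_shells Number of shells (default 10).
#' @param s2_range Optional length-2 numeric giving the binning range; by
#'   default the data range. Supplying a common range aligns shell tables
#'   across wedges.
#' @param use_shell_column If `TRUE` (default) and the reflections already
#'   carry a `shell` assignment (as simulated data do), group by it instead
#'   of re-binning; `s2_mid` is then the mean `s2` within the shell.
#'
#' @return Tibble with columns `shell`, `s2_lo`, `s2_hi`, `s2_mid`,
#'   `mean_J`, `mean_sigma`, `n_obs`.
#' @export
shell_statistics <- function(reflections, n_shells = 10, s2_range = NULL,
                             use_shell_column = TRUE) {
  stopifnot(all(c("s2", "J", "sigma") %in% names(reflections)))
  if (nrow(reflections) < 1) abort("no reflections to bin")
  if (use_shell_column && "shell" %in% names(reflections)) {
    out <- reflections |>
      dplyr::group_by(shell = .data$shell) |>
      dplyr::summarise(s2_lo = min(.data$s2), s2_hi = max(.data$s2),
                       s2_mid = mean(.data$s2),
                       mean_J = mean(.data$J),
                       mean_sigma = mean(.data$sigma),
                       n_obs = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(.data$shell) |>
      dplyr::relocate("shell", "s2_lo", "s2_hi", "s2_mid")
    attr(out, "merged") <- FALSE
    return(out)
  }
  # discrete s2 grids (e.g. wedge files from the simulator, where each
  # reflection sits at its shell midpoint) are grouped by value: equal-width
  # bins would split such a grid unevenly
  if (dplyr::n_distinct(reflections$s2) <= n_shells) {
    out <- reflections |>
      dplyr::group_by(s2_mid = .data$s2) |>
      dplyr::summarise(mean_J = mean(.data$J),
                       mean_sigma = mean(.data$sigma),
                       n_obs = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(.data$s2_mid) |>
      dplyr::mutate(shell = dplyr::row_number(),
                    s2_lo = .data$s2_mid, s2_hi = .data$s2_mid) |>
      dplyr::relocate("shell", "s2_lo", "s2_hi", "s2_mid")
    attr(out, "merged") <- FALSE
    return(out)
  }
  rng <- s2_range %||% range(reflections$s2)
  edges <- seq(rng[1], rng[2], length.out = n_shells + 1)
  # half-open bins, last bin closed
  bin <- findInterval(reflections$s2, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tab <- tibble::tibble(bin = bin, J = reflections$J,
                        sigma = reflections$sigma) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_J = mean(.data$J),
                     mean_sigma = mean(.data$sigma),
                     n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bin)
  merged <- nrow(tab) < n_shells
  out <- tab |>
    dplyr::mutate(shell = .data$bin,
                  s2_lo = edges[.data$bin],
                  s2_hi = edges[.data$bin + 1],
                  s2_mid = (.data$s2_lo + .data$s2_hi) / 2) |>
    dplyr::select("shell", "s2_lo", "s2_hi", "s2_mid",
                  "mean_J", "mean_sigma", "n_obs")
  attr(out, "merged") <- merged
  if (merged) warn("empty resolution shell(s) merged with neighbour")
  out
}

#' Fit a relative scale and B-factor of one wedge against a reference
#'
#' Weighted linear regression of the log shell-mean ratio:
#' `ln(mean_J_wedge / mean_J_ref) = ln(k) - 2 * dB * s2`, over the shells
#' present in both tables. Shells with non-positive mean intensity in either
#' table are excluded (with a warning); at least two usable shells are
#' required. Weights are `n_obs / (relative variance)`, with the relative
#' variance of a Wilson shell mean taken as
#' `(1 + (mean_sigma / mean_J)^2) / n_obs` summed over wedge and reference.
#'
#' @param wedge,reference Shell tables from [shell_statistics()], aligned on
#'   the `shell` column.
#' @param extra_relvar Optional additional relative variance per shell of
#'   the reference (used internally by [scale_wedge_series()]).
#'
#' @return One-row tibble: `k` (relative scale), `b` (relative B in squared
#'   angstroms), `se_b` (standard error), `n_shells_used`.
#' @export
fit_wedge_scale <- function(wedge, reference, extra_relvar = 0) {
  d <- dplyr::inner_join(wedge, reference, by = "shell",
                         suffix = c("_w", "_r"))
  if (nrow(d) < 2) abort("fewer than 2 aligned shells; degenerate fit")
  usable <- d$mean_J_w > 0 & d$mean_J_r > 0
  if (any(!usable)) {
    warn(sprintf("%d shell(s) with non-positive mean excluded from scaling",
                 sum(!usable)))
  }
  d <- d[usable, ]
  if (nrow(d) < 2) abort("fewer than 2 usable shells; degenerate fit")
  relvar <- (1 + (d$mean_sigma_w / d$mean_J_w)^2) / d$n_obs_w +
    (1 + (d$mean_sigma_r / d$mean_J_r)^2) / d$n_obs_r + extra_relvar
  y <- log(d$mean_J_w / d$mean_J_r)
  x <- d$s2_mid_w
  fit <- lm(y ~ x, weights = 1 / relvar)
  sm <- suppressWarnings(summary(fit))  # exact fits trip summary.lm
  se_slope <- if (nrow(d) > 2) sm$coefficients[2, 2] else NA_real_
  tibble::tibble(k = exp(unname(coef(fit)[1])),
                 b = -unname(coef(fit)[2]) / 2,
                 se_b = se_slope / 2,
                 n_shells_used = nrow(d))
}

#' Jointly scale a series of wedges against a self-consistent reference
#'
#' Iterates between (i) building a reference curve as the precision-weighted
#' average of the shell means of all wedges brought onto a common scale, and
#' (ii) refitting each wedge's relative scale `k_i` and B-factor `B_i`
#' against that reference with [fit_wedge_scale()]. The gauge is fixed so
#' that the first wedge has `B = 0` and the largest scale is
#' `k = 1` (scales are reported relative to the maximum over wedges).
#'
#' @param reflections Long tibble of all wedges, with columns `wedge_index`,
#'   `nominal_dose`, `s2`, `J`, `sigma` (as produced by
#'   [simulate_experiment()] or [read_wedge_series()]).
#' @param n_shells Number of resolution shells (default 10), binned on the
#'   pooled `s2` range so all wedges share shell edges.
#' @param max_iter Maximum number of reference/refit iterations.
#' @param tol Convergence threshold on the largest per-wedge B change
#'   between iterations, in squared angstroms.
#'
#' @return An object of class `wedge_scales`: a tibble with one row per
#'   wedge (`wedge_index`, `nominal_dose`, `k`, `b`, `se_b`, `snr_last`,
#'   `n_shells_used`), ordered by `wedge_index`. Attributes: `converged`,
#'   `n_iter`, `shell_edges`.
#' @export
scale_wedge_series <- function(reflections, n_shells = 10,
                               max_iter = 50, tol = 1e-8) {
  stopifnot(all(c("wedge_index", "s2", "J", "sigma") %in% names(reflections)))
  if (!"nominal_dose" %in% names(reflections)) {
    reflections$nominal_dose <- NA_real_
  }
  idx <- sort(unique(reflections$wedge_index))
  if (length(idx) < 2) abort("need at least 2 wedges to scale jointly")
  rng <- range(reflections$s2)

  wedges <- purrr::map(idx, function(i) {
    shell_statistics(dplyr::filter(reflections, .data$wedge_index == i),
                     n_shells = n_shells, s2_range = rng)
  })
  # wedges share the underlying reflection set, so their shell tables align
  # whether shells come from the simulation grid or from common-range bins
  doses <- purrr::map_dbl(idx, function(i) {
    reflections$nominal_dose[match(i, reflections$wedge_index)]
  })
  snr_last <- purrr::map_dbl(wedges, function(w) {
    last <- w[nrow(w), ]
    last$mean_J / last$mean_sigma
  })

  nw <- length(wedges)
  k <- rep(1, nw)
  b <- rep(0, nw)
  se_b <- rep(NA_real_, nw)
  nsh <- rep(NA_integer_, nw)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    # reference: precision-weighted average of descaled shell means
    ref <- purrr::imap_dfr(wedges, function(w, i) {
      dplyr::mutate(w,
                    mean_J = .data$mean_J / (k[i] * exp(-2 * b[i] * .data$s2_mid)),
                    mean_sigma = .data$mean_sigma /
                      (k[i] * exp(-2 * b[i] * .data$s2_mid)),
                    .wedge = i)
    }) |>
      dplyr::group_by(.data$shell, .data$s2_lo, .data$s2_hi, .data$s2_mid) |>
      dplyr::summarise(
        mean_J = sum(.data$n_obs * .data$mean_J) / sum(.data$n_obs),
        mean_sigma = sum(.data$n_obs * .data$mean_sigma) / sum(.data$n_obs),
        n_obs = sum(.data$n_obs), .groups = "drop") |>
      dplyr::arrange(.data$shell)

    b_old <- b
    fits <- purrr::map_dfr(wedges, fit_wedge_scale, reference = ref)
    k <- fits$k
    b <- fits$b
    se_b <- fits$se_b
    nsh <- fits$n_shells_used
    # gauge fixing: B relative to the first wedge, k relative to the max
    b <- b - b[1]
    k <- k / max(k)
    if (max(abs(b - b_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warn("joint scaling did not converge; returning last iterate")

  out <- tibble::tibble(wedge_index = idx, nominal_dose = doses,
                        k = k, b = b, se_b = se_b, snr_last = snr_last,
                        n_shells_used = nsh)
  structure(out, class = c("wedge_scales", class(out)),
            converged = converged, n_iter = iter,
            shell_edges = seq(rng[1], rng[2], length.out = n_shells + 1))
}
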