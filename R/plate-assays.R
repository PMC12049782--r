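#' Endpoint fluorescence calling
#'
#' A clone is called fluorescent when its RFU reading exceeds the
#' negative-control threshold (default 600 RFU at gain 50).
#'
#' @param rfu numeric vector of endpoint RFU readings (one per clone).
#' @param rfu_threshold threshold, default 600.
#' @return list with `positive` (logical vector) and `fraction` (fraction
#'   of screened clones above threshold).
#' @export
#' @examples
#' call_fluorescent(c(700, 500, 601))
call_fluorescent <- function(rfu, rfu_threshold = 600) {
  stopifnot(all(rfu >= 0))
  pos <- rfu > rfu_threshold
  list(positive = pos, fraction = mean(pos))
}

#' Biomass-normalized fluorescence
#'
#' RFU / OD600 for clones that grew; clones at or below the OD cutoff
#' (strict inequality, default 1.0) are excluded and flagged.
#'
#' @param rfu,od600 numeric vectors.
#' @param od_min OD600 cutoff, default 1.0.
#' @return data.frame with `rfu`, `od600`, `included`,
#'   `normalized_fluorescence` (NA for excluded clones).
#' @export
normalized_fluorescence <- function(rfu, od600, od_min = 1.0) {
  stopifnot(length(rfu) == length(od600), all(rfu >= 0), all(od600 >= 0))
  included <- od600 > od_min
  data.frame(rfu = rfu, od600 = od600, included = included,
             normalized_fluorescence = ifelse(included, rfu / od600, NA_real_))
}

#' Transformation efficiency (cfu per microgram donor DNA)
#'
#' @param colonies total colonies counted.
#' @param plated_fraction fraction of the recovery mix plated, in (0, 1].
#' @param dna_ug micrograms of donor cassette DNA transformed.
#' @return cfu per microgram.
#' @export
transformation_efficiency <- function(colonies, plated_fraction = 1.0, dna_ug) {
  if (dna_ug <= 0) stop("dna_ug must be positive")
  if (plated_fraction <= 0 || plated_fraction > 1)
    stop("plated_fraction must be in (0, 1]")
  colonies / plated_fraction / dna_ug
}

#' Summarize transformation / integration efficiency across replicates
#'
#' Integration (targeting) efficiency is the fluorescent fraction;
#' integrations per microgram is its product with the transformation
#' efficiency, reported as mean with standard error across replicates.
#'
#' @param cfu_per_ug numeric vector, one value per replicate.
#' @param fluorescent_fraction numeric vector in `[0, 1]`, recycled.
#' @return list of class `efficiency_summary`.
#' @export
efficiency_summary <- function(cfu_per_ug, fluorescent_fraction) {
  stopifnot(all(fluorescent_fraction >= 0 & fluorescent_fraction <= 1))
  integ <- cfu_per_ug * fluorescent_fraction
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(list(
    cfu_per_ug_mean = mean(cfu_per_ug), cfu_per_ug_se = se(cfu_per_ug),
    fluorescent_fraction_mean = mean(fluorescent_fraction),
    integrations_per_ug_mean = mean(integ), integrations_per_ug_se = se(integ),
    n = length(integ)), class = "efficiency_summary")
}

#' @export
print.efficiency_summary <- function(x, ...) {
  cat(sprintf(
    "Transformation: %.0f (SE +/- %.0f) cfu/ug; fluorescent fraction %.2f; integrations: %.0f (SE +/- %.0f) per ug [n = %d]\n",
    x$cfu_per_ug_mean, x$cfu_per_ug_se, x$fluorescent_fraction_mean,
    x$integrations_per_ug_mean, x$integrations_per_ug_se, x$n))
  invisible(x)
}

#' Specific growth rate from a kinetic curve
#'
#' Fits ln(OD600) against time by least squares over an explicit window
#' (e.g. 9-11 h post inoculation); the slope is the specific growth rate
#' in 1/h. The fit is invariant to scaling OD by a positive constant and
#' to time translation.
#'
#' @param time hours, strictly increasing.
#' @param od600 OD600 readings, positive within the window.
#' @param window `c(start, end)` in hours (inclusive).
#' @return list of class `growth_fit`: `mu` (1/h), `window`, `n`,
#'   `r_squared`.
#' @export
#' @examples
#' t <- seq(0, 12, by = 1/12)
#' growth_rate(t, 0.1 * exp(0.15 * t), window = c(9, 11))
growth_rate <- function(time, od600, window) {
  stopifnot(length(time) == length(od600), !is.unsorted(time, strictly = TRUE),
            length(window) == 2)
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 3) stop("need at least 3 points inside the window")
  if (any(od600[sel] <= 0)) stop("non-positive OD600 inside the window")
  fit <- stats::lm(log(od600[sel]) ~ time[sel])
  y <- log(od600[sel])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-20) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(mu = unname(stats::coef(fit)[2]), window = window,
                 n = sum(sel), r_squared = r2),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("mu = %.4f /h over %g-%g h (n = %d, R^2 = %.4f)\n",
              x$mu, x$window[1], x$window[2], x$n, x$r_squared))
  invisible(x)
}

#' Maximal-slope exponential window (optional helper)
#'
#' Heuristic automatic window: slides a window of `width` hours and keeps
#' the one with the largest fitted slope of ln(OD600).
#'
#' @inheritParams growth_rate
#' @param width window width in hours, default 2.
#' @return a `growth_fit` for the best window.
#' @export
find_exponential_window <- function(time, od600, width = 2) {
  starts <- time[time + width <= max(time)]
  fits <- lapply(starts, function(s) {
    sel <- time >= s & time <= s + width
    if (sum(sel) < 3 || any(od600[sel] <= 0)) return(NULL)
    growth_rate(time, od600, c(s, s + width))
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no valid window found")
  fits[[which.max(vapply(fits, function(f) f$mu, numeric(1)))]]
}

#' Read plate-reader data in long CSV format
#'
#' Expects columns `clone`, `time` (hours), `od600`, `rfu` (case
#' insensitive; extra columns pass through). Kinetic curves are one row
#' per clone and time point; endpoint plates use a single time point.
#'
#' @param path CSV file.
#' @return data.frame sorted by clone and time.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("clone", "time", "od600", "rfu")
  if (!all(need %in% names(df)))
    stop("plate CSV needs columns: ", paste(need, collapse = ", "))
  df[order(df$clone, df$time), , drop = FALSE]
}

#' Simulate a kinetic growth/fluorescence curve
#'
#' Logistic biomass growth sampled every 5 minutes with optional
#' multiplicative noise; fluorescence proportional to biomass. Used as the
#' test fixture for growth-rate recovery.
#'
#' @param mu specific growth rate (1/h).
#' @param od0 inoculation OD600.
#' @param od_max carrying capacity.
#' @param hours total duration.
#' @param interval_min sampling interval in minutes, default 5.
#' @param noise_sd multiplicative log-normal noise sd, default 0.
#' @param rfu_per_od fluorescence yield, default 1500.
#' @param seed integer seed.
#' @return data.frame with `time` (h), `od600`, `rfu`.
#' @export
simulate_growth_curve <- function(mu, od0 = 0.02, od_max = 1.5, hours = 40,
                                  interval_min = 5, noise_sd = 0,
                                  rfu_per_od = 1500, seed = 1L) {
  time <- seq(0, hours, by = interval_min / 60)
  od <- od_max / (1 + (od_max / od0 - 1) * exp(-mu * time))
  with_seed(seed, {
    if (noise_sd > 0) od <- od * exp(stats::rnorm(length(od), 0, noise_sd))
    data.frame(time = time, od600 = od, rfu = rfu_per_od * od)
  })
}
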