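# The 4-step risk pipeline: dose-response (OEL derivation), exposure
# posterior, hazard-quotient forecast with 90% credible interval, and
# control-band classification. HQ = airborne concentration / OEL, reported
# in percent; HQ > 100% flags potential risk.

risk_bands <- c("negligible", "caution", "potential risk", "high risk")

#' Dose-response configuration
#'
#' Captures the point of departure (NOAEL or LOAEL, ug/m3), the uncertainty
#' factor dividing it down to a human-safe limit, and whether the material is
#' CMR (carcinogenic / mutagenic / reprotoxic), which switches the
#' dose-response from the threshold model to the linear (non-threshold)
#' model.
#'
#' @param point_of_departure Positive dose, ug/m3.
#' @param pod_kind `"NOAEL"` or `"LOAEL"`. A LOAEL gets an extra
#'   `loael_factor` on top of the uncertainty factor because the
#'   no-effect level lies below it.
#' @param uncertainty_factor Safety divisor, >= 1; conventionally 100.
#' @param cmr Logical CMR flag; `TRUE` selects the linear model.
#' @param mode `"threshold"` or `"linear"`; defaults to linear iff `cmr`.
#' @param loael_factor Extra divisor applied when `pod_kind = "LOAEL"`
#'   (default 10).
#' @param linear_factor Extra divisor standing in for low-dose linear
#'   extrapolation to an acceptable-risk level in CMR mode (default 10).
#' @return A `dose_response_config` object.
#' @export
dose_response_config <- function(point_of_departure,
                                 pod_kind = c("NOAEL", "LOAEL"),
                                 uncertainty_factor = 100,
                                 cmr = FALSE,
                                 mode = NULL,
                                 loael_factor = 10,
                                 linear_factor = 10) {
  pod_kind <- match.arg(pod_kind)
  if (is.null(mode)) mode <- if (isTRUE(cmr)) "linear" else "threshold"
  mode <- match.arg(mode, c("threshold", "linear"))
  if (!(point_of_departure > 0)) stop("point_of_departure must be positive", call. = FALSE)
  if (uncertainty_factor < 1) stop("uncertainty_factor must be >= 1", call. = FALSE)
  if (loael_factor < 1 || linear_factor < 1)
    stop("extrapolation factors must be >= 1", call. = FALSE)
  structure(list(point_of_departure = point_of_departure, pod_kind = pod_kind,
                 uncertainty_factor = uncertainty_factor, cmr = isTRUE(cmr),
                 mode = mode, loael_factor = loael_factor,
                 linear_factor = linear_factor),
            class = "dose_response_config")
}

#' Derive an occupational exposure limit
#'
#' Threshold model: `POD / uncertainty_factor`. Linear (CMR) model:
#' `POD / (uncertainty_factor * linear_factor)`, the extra documented factor
#' standing in for low-dose linear extrapolation. In either mode a LOAEL
#' point of departure is divided by a further `loael_factor`.
#'
#' @param cfg A [dose_response_config()].
#' @return The OEL in ug/m3 (always positive).
#' @examples
#' derive_oel(dose_response_config(1000))  # NOAEL 1000, factor 100 -> 10
#' @export
derive_oel <- function(cfg) {
  stopifnot(inherits(cfg, "dose_response_config"))
  div <- cfg$uncertainty_factor
  if (cfg$pod_kind == "LOAEL") div <- div * cfg$loael_factor
  if (cfg$mode == "linear") div <- div * cfg$linear_factor
  cfg$point_of_departure / div
}

#' Discrete distribution over labelled bins
#'
#' The common currency of the risk step: a tibble with one row per bin
#' carrying its label, representative value and probability. Representatives
#' default to the geometric midpoint `sqrt(lo*hi)` of each bin (arithmetic
#' midpoint for a bin touching zero), which reduces ratio bias on
#' width-growing grids.
#'
#' @param prob Probability vector (sums to 1 within 1e-9).
#' @param edges Bin edges (`length(prob) + 1`), used to derive
#'   representatives and labels when not given directly.
#' @param representative,state Optional explicit representatives / labels.
#' @return A `bin_distribution` tibble (`state`, `representative`, `prob`).
#' @export
bin_distribution <- function(prob, edges = NULL, representative = NULL,
                             state = NULL) {
  if (abs(sum(prob) - 1) > 1e-9) stop("probabilities must sum to 1", call. = FALSE)
  if (any(prob < 0)) stop("negative probability", call. = FALSE)
  if (is.null(representative)) {
    if (is.null(edges)) stop("need edges or explicit representatives", call. = FALSE)
    representative <- bin_representatives(edges)
  }
  if (is.null(state)) {
    state <- if (!is.null(edges)) bin_labels(edges) else as.character(representative)
  }
  out <- tibble::tibble(state = state, representative = as.numeric(representative),
                        prob = as.numeric(prob))
  class(out) <- c("bin_distribution", class(out))
  out
}

#' Degenerate single-value distribution
#' @param value The point value (e.g. an OEL from [derive_oel()]).
#' @return A one-row [bin_distribution()].
#' @export
point_mass <- function(value) {
  bin_distribution(1, representative = value, state = as.character(value))
}

# Posterior of one discretized-continuous variable as a bin_distribution.
node_posterior <- function(net, var, evidence = NULL) {
  if (!var %in% bn_vars(net))
    stop("network has no '", var, "' variable", call. = FALSE)
  post <- posterior_marginals(net, evidence)
  v <- net$variables[[var]]
  bin_distribution(posterior_vector(post, var),
                   edges = v$bin_edges,
                   representative = if (is.null(v$bin_edges)) seq_along(v$states),
                   state = v$states)
}

#' Exposure posterior over concentration bins
#'
#' The exposure-assessment step: the posterior of the airborne-concentration
#' variable given the entered evidence, as a [bin_distribution()] over the
#' width-growing concentration bins. Deterministic given network + evidence.
#'
#' @inheritParams joint_enumeration
#' @param var Name of the concentration variable (default
#'   `"concentration"`).
#' @return A `bin_distribution` tibble.
#' @export
exposure_posterior <- function(net, evidence = NULL, var = "concentration") {
  node_posterior(net, var, evidence)
}

#' OEL posterior over limit bins
#'
#' The dose-response step when the limit is carried inside the network (the
#' OEL node, parameterized by its CMR parent) rather than supplied as a
#' single derived number.
#'
#' @inheritParams exposure_posterior
#' @param var Name of the OEL variable (default `"oel"`).
#' @return A `bin_distribution` tibble.
#' @export
oel_posterior <- function(net, evidence = NULL, var = "oel") {
  node_posterior(net, var, evidence)
}

# Smallest x with cumulative weight >= p (discrete, weights on values x).
discrete_quantile <- function(x, w, p) {
  ord <- order(x)
  cw <- cumsum(w[ord])
  vapply(p, function(pp) x[ord][which(cw >= pp - 1e-12)[1]], 0)
}

#' Hazard-quotient forecast
#'
#' Forms the discrete distribution of HQ = concentration / OEL (in percent)
#' from the exposure and OEL bin distributions, treated as independent: every
#' pairwise ratio of bin representatives receives the product of the two bin
#' probabilities. Reports the mean HQ, the equal-tailed 90% credible interval
#' (5% and 95% quantiles of the ratio distribution), a re-binned HQ
#' distribution on a log-spaced grid, per-axis means and 90% intervals for
#' the heat map, and the control band of the mean.
#'
#' @param exposure [bin_distribution()] over concentration bins (ug/m3).
#' @param oel [bin_distribution()] over OEL bins (ug/m3); a point mass from
#'   [derive_oel()] is fine. Mass on a zero representative is rejected.
#' @param hq_edges Edges (in %) of the reporting grid for the re-binned HQ
#'   distribution; ratios beyond the last edge are absorbed into the top bin.
#' @return An `hq_forecast` object with fields `mean_hq`, `interval_90`,
#'   `band`, `hq_distribution`, `atoms`, `mean_concentration`,
#'   `conc_interval_90`, `mean_oel`, `oel_interval_90`.
#' @export
hazard_quotient <- function(exposure, oel,
                            hq_edges = c(0, 10^seq(0, 5, by = 0.25))) {
  stopifnot(inherits(exposure, "bin_distribution"),
            inherits(oel, "bin_distribution"))
  if (abs(sum(exposure$prob) - 1) > 1e-9 || abs(sum(oel$prob) - 1) > 1e-9)
    stop("input distributions must be normalized", call. = FALSE)
  if (any(oel$representative <= 0 & oel$prob > 0))
    stop("OEL distribution has mass on a non-positive representative", call. = FALSE)

  ratio <- 100 * outer(exposure$representative, 1 / oel$representative)
  wt <- outer(exposure$prob, oel$prob)
  atoms <- tibble::tibble(hq = as.numeric(ratio), prob = as.numeric(wt)) |>
    dplyr::filter(.data$prob > 0) |>
    dplyr::group_by(.data$hq) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop") |>
    dplyr::arrange(.data$hq)

  mean_hq <- sum(atoms$hq * atoms$prob)
  interval_90 <- discrete_quantile(atoms$hq, atoms$prob, c(0.05, 0.95))

  idx <- pmin(findInterval(atoms$hq, hq_edges, rightmost.closed = TRUE),
              length(hq_edges) - 1L)
  idx <- pmax(idx, 1L)
  hq_prob <- numeric(length(hq_edges) - 1L)
  agg <- rowsum(atoms$prob, idx)
  hq_prob[as.integer(rownames(agg))] <- agg[, 1L]
  hq_distribution <- tibble::tibble(
    lower = hq_edges[-length(hq_edges)], upper = hq_edges[-1], prob = hq_prob)

  structure(list(
    mean_hq = mean_hq,
    interval_90 = stats::setNames(interval_90, c("lo", "hi")),
    band = band_of(mean_hq),
    hq_distribution = hq_distribution,
    atoms = atoms,
    mean_concentration = sum(exposure$representative * exposure$prob),
    conc_interval_90 = stats::setNames(
      discrete_quantile(exposure$representative, exposure$prob, c(0.05, 0.95)),
      c("lo", "hi")),
    mean_oel = sum(oel$representative * oel$prob),
    oel_interval_90 = stats::setNames(
      discrete_quantile(oel$representative, oel$prob, c(0.05, 0.95)),
      c("lo", "hi"))),
    class = "hq_forecast")
}

band_of <- function(mean_hq) {
  cut(mean_hq, breaks = c(-Inf, 10, 100, 1000, Inf),
      labels = risk_bands, right = TRUE)[[1]]
}

#' Control-band classification
#'
#' Maps a mean hazard quotient to a control band. The acceptable /
#' potential-risk inflection sits exactly at HQ = 100%: `HQ > 100%` (strict)
#' is classified as at least "potential risk". The 10% and 1000% cuts are
#' reporting conventions for heat-map granularity.
#'
#' @param forecast An `hq_forecast` (or a bare mean HQ in percent).
#' @return A factor level among `negligible` (<= 10%), `caution`
#'   (10-100%], `potential risk` (100-1000%], `high risk` (> 1000%).
#' @export
classify_risk <- function(forecast) {
  hq <- if (inherits(forecast, "hq_forecast")) forecast$mean_hq else forecast
  band_of(hq)
}

#' Heat-map coordinates for a forecast
#'
#' One row per forecast: x = mean OEL, y = mean concentration (both ug/m3,
#' the estimated mean values used as HQ coordinates) plus the 90% interval
#' endpoints for each axis and the control band — the machine-readable record
#' behind the control-banding heat map.
#'
#' @param forecast An `hq_forecast`.
#' @param label Optional material / scenario label.
#' @return A one-row tibble (`label`, `oel`, `concentration`, `oel_lo`,
#'   `oel_hi`, `conc_lo`, `conc_hi`, `mean_hq`, `band`).
#' @export
heatmap_point <- function(forecast, label = NA_character_) {
  stopifnot(inherits(forecast, "hq_forecast"))
  tibble::tibble(
    label = label,
    oel = forecast$mean_oel,
    concentration = forecast$mean_concentration,
    oel_lo = forecast$oel_interval_90[["lo"]],
    oel_hi = forecast$oel_interval_90[["hi"]],
    conc_lo = forecast$conc_interval_90[["lo"]],
    conc_hi = forecast$conc_interval_90[["hi"]],
    mean_hq = forecast$mean_hq,
    band = as.character(forecast$band))
}

#' @export
print.hq_forecast <- function(x, ...) {
  cat("<hq_forecast> mean HQ ", sprintf("%.1f%%", x$mean_hq),
      " [90% CI ", sprintf("%.1f", x$interval_90[["lo"]]), "-",
      sprintf("%.1f", x$interval_90[["hi"]]), "%], band: ",
      as.character(x$band), "\n", sep = "")
  invisible(x)
}

#' @method tidy hq_forecast
#' @export
tidy.hq_forecast <- function(x, ...) x$hq_distribution

#' @method glance hq_forecast
#' @export
glance.hq_forecast <- function(x, ...) {
  tibble::tibble(mean_hq = x$mean_hq,
                 hq_lo = x$interval_90[["lo"]], hq_hi = x$interval_90[["hi"]],
                 mean_concentration = x$mean_concentration,
                 mean_oel = x$mean_oel, band = as.character(x$band))
}

#' Control-banding heat map
#'
#' Renders one or more forecasts on the OEL x concentration plane: band
#' background shaded by HQ, a point at the mean coordinates, a dashed segment
#' for the 90% OEL interval and a solid segment for the 90% concentration
#' interval.
#'
#' @param points A tibble of [heatmap_point()] rows (or a single
#'   `hq_forecast`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_control_banding <- function(points, ...) {
  if (inherits(points, "hq_forecast")) points <- heatmap_point(points)
  rng_o <- range(c(points$oel_lo, points$oel_hi, points$oel)) * c(0.5, 2)
  rng_c <- range(c(points$conc_lo, points$conc_hi, points$concentration)) * c(0.5, 2)
  grid <- tidyr::expand_grid(
    oel = exp(seq(log(rng_o[1]), log(rng_o[2]), length.out = 80)),
    concentration = exp(seq(log(rng_c[1]), log(rng_c[2]), length.out = 80)))
  grid$band <- factor(
    vapply(100 * grid$concentration / grid$oel,
           function(h) as.character(band_of(h)), ""),
    levels = risk_bands)
  ggplot2::ggplot(points, ggplot2::aes(x = .data$oel, y = .data$concentration)) +
    ggplot2::geom_raster(data = grid, ggplot2::aes(fill = .data$band), alpha = 0.5) +
    ggplot2::scale_fill_manual(values = c(
      "negligible" = "#2c7bb6", "caution" = "#ffffbf",
      "potential risk" = "#fdae61", "high risk" = "#d7191c"), drop = FALSE) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$oel_lo, xend = .data$oel_hi,
                                       yend = .data$concentration),
                          linetype = "dashed") +
    ggplot2::geom_segment(ggplot2::aes(y = .data$conc_lo, yend = .data$conc_hi,
                                       xend = .data$oel)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -1, na.rm = TRUE) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "OEL (ug/m3, 90% interval dashed)",
                  y = "NM concentration in air (ug/m3, 90% interval solid)",
                  fill = "control band")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot hq_forecast
#' @export
autoplot.hq_forecast <- function(object, ...) plot_control_banding(object, ...)
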