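#' Remove dilution bias from a biomass map
#'
#' Model predictions regress to the mean (high biomass under-, low
#' biomass over-estimated). Following standard practice, an ordinary
#' least-squares line `observed = a + b * estimated` is fitted on
#' reference pairs and applied pixelwise; negatives are clipped to 0.
#'
#' @param agb Biomass matrix (Mg/ha).
#' @param observed,estimated Reference pairs (>= 20) of observed and
#'   model-estimated biomass.
#' @return Corrected matrix with attributes `bias_a`, `bias_b` and the
#'   input's `provenance`.
#' @export
bias_correct <- function(agb, observed, estimated) {
  stopifnot(length(observed) == length(estimated), length(observed) >= 20)
  if (stats::sd(estimated) == 0)
    stop_fc("firecarb_zero_variance", "estimates have zero variance; cannot fit bias line")
  fit <- stats::lm(observed ~ estimated)
  a <- stats::coef(fit)[[1]]; b <- stats::coef(fit)[[2]]
  out <- pmax(a + b * agb, 0)
  attr(out, "provenance") <- attr(agb, "provenance")
  attr(out, "bias_a") <- a
  attr(out, "bias_b") <- b
  out
}

#' Biomass-consumption map
#'
#' Pixelwise difference `pre - post` (Mg/ha). Negative pixels (possible
#' where two independently modeled maps disagree) are *retained* so
#' stratum sums stay unbiased; their fraction is reported as attribute
#' `negative_fraction`.
#'
#' @param pre,post Biomass matrices on the same grid.
#' @return Difference matrix with attributes `negative_fraction` and
#'   `pair` (the provenance pair tag).
#' @export
consumption_map <- function(pre, post) {
  if (!identical(dim(pre), dim(post)))
    stop_fc("firecarb_grid_mismatch", "pre/post maps on different grids")
  delta <- pre - post
  attr(delta, "negative_fraction") <- mean(delta < 0, na.rm = TRUE)
  attr(delta, "pair") <- paste0(attr(pre, "provenance") %||% "pre", "-",
                                attr(post, "provenance") %||% "post")
  delta
}

fc_severity_levels <- c("unburned", "low", "moderate", "high")

#' Aggregate consumed biomass by burn-severity stratum
#'
#' Converts a per-pixel biomass difference (Mg/ha) into per-stratum
#' consumed mass: `dB_s (Tg) = sum(delta) * pixel_area_ha * 1e-6`. The
#' total row sums the *burned* strata only (low + moderate + high).
#'
#' @param delta Consumption matrix (Mg/ha).
#' @param severity Integer matrix of severity codes 0-3.
#' @param pixel_area_ha Pixel area (ha), 0.09 for a 30 m grid.
#' @return Data frame: `stratum`, `n_pixels`, `area_ha`, `dB_Tg`, with
#'   rows low, moderate, high, total_burned.
#' @export
aggregate_by_stratum <- function(delta, severity, pixel_area_ha = 0.09) {
  if (!identical(dim(delta), dim(severity)))
    stop_fc("firecarb_grid_mismatch", "delta and severity on different grids")
  if (!all(severity %in% 0:3 | is.na(severity)))
    stop_fc("firecarb_unknown_severity", "severity codes outside 0..3")
  rows <- lapply(1:3, function(s) {
    sel <- severity == s & !is.na(delta)
    data.frame(stratum = fc_severity_levels[s + 1], n_pixels = sum(sel),
               area_ha = sum(sel) * pixel_area_ha,
               dB_Tg = sum(delta[sel]) * pixel_area_ha * 1e-6)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(stratum = "total_burned", n_pixels = sum(out$n_pixels),
                        area_ha = sum(out$area_ha), dB_Tg = sum(out$dB_Tg)))
}

#' Carbon release from consumed biomass
#'
#' `C = f_c * dB` with the standard carbon fraction 0.5.
#'
#' @param dB_Tg Consumed biomass (Tg).
#' @param f_c Carbon fraction of biomass, in `[0, 1]`.
#' @return Released carbon (TgC).
#' @export
carbon_release <- function(dB_Tg, f_c = 0.5) {
  stopifnot(f_c >= 0, f_c <= 1)
  f_c * dB_Tg
}

#' CO2-equivalent mass of released carbon
#'
#' Pure CO2 stoichiometry: `CO2e = C * 44/12` (no CH4/N2O
#' global-warming-potential terms).
#'
#' @param C_TgC Released carbon (TgC).
#' @return CO2-equivalent mass (Tg).
#' @export
co2_equivalent <- function(C_TgC) C_TgC * 44 / 12

#' Combustion completeness per stratum
#'
#' `CC_s = dB_s / B_pre,s`, the fraction of the prefire stock consumed,
#' clipped to `[0, 1]` (clip count as attribute `n_clipped`). A zero
#' prefire stock leaves CC undefined (`NA` with a warning).
#'
#' @param dB Consumed biomass per stratum (any mass unit).
#' @param B_pre Prefire biomass per stratum (same unit).
#' @return Numeric vector of combustion completeness values.
#' @export
combustion_completeness <- function(dB, B_pre) {
  stopifnot(length(dB) == length(B_pre))
  cc <- dB / B_pre
  undef <- B_pre <= 0
  if (any(undef, na.rm = TRUE)) {
    warning("zero prefire stock: combustion completeness undefined")
    cc[undef] <- NA_real_
  }
  clipped <- sum(cc < 0 | cc > 1, na.rm = TRUE)
  cc <- pmin(pmax(cc, 0), 1)
  attr(cc, "n_clipped") <- clipped
  cc
}

#' Fire carbon emission (bottom-up accounting identity)
#'
#' `Cr = A * B * f_c * beta`: burned area (ha) times biomass density
#' (Mg/ha) times carbon fraction times combustion completeness.
#'
#' @param A Burned area (ha), >= 0.
#' @param B Biomass density (Mg/ha), >= 0.
#' @param f_c Carbon fraction, in `[0, 1]`.
#' @param beta Combustion completeness, in `[0, 1]`.
#' @return Released carbon (Mg C).
#' @export
seiler_crutzen <- function(A, B, f_c = 0.5, beta) {
  stopifnot(all(A >= 0), all(B >= 0), all(f_c >= 0 & f_c <= 1),
            all(beta >= 0 & beta <= 1))
  A * B * f_c * beta
}

#' Render an emission report with 2-decimal table rounding
#'
#' Internal arithmetic stays full precision; rounding happens only here.
#'
#' @param report Emission data frame (e.g. from [aggregate_by_stratum()]
#'   with carbon columns added).
#' @param digits Decimal places (default 2).
#' @return The data frame with numeric columns rounded.
#' @export
render_report <- function(report, digits = 2) {
  num <- vapply(report, is.numeric, logical(1)) & names(report) != "n_pixels"
  report[num] <- lapply(report[num], round, digits = digits)
  report
}
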