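#' Spherocylinder surface fractions
#'
#' For a rod-shaped cell idealised as a spherocylinder (cylinder of radius
#' `r` and length `l` capped by two hemispheres), the fraction of wall made
#' by the elongation machinery (cylinder) versus the division machinery
#' (poles) is computed as
#' \deqn{100\% = \frac{l}{\frac{4}{3}r + l} + \frac{\frac{4}{3}r}{\frac{4}{3}r + l}}
#' evaluated exactly as printed. Note this expression coincides with the
#' spherocylinder *volume* partition; the strict surface-*area* partition of
#' cylinder `2*pi*r*l` against caps `4*pi*r^2` would be `l/(l + 2r)`. The
#' printed formula is what is implemented and reported, and the note is
#' repeated in the returned metadata.
#'
#' @param r radius in micrometres (> 0).
#' @param l length in micrometres (>= 0).
#' @return List of class `surface_fractions`: `f_cylinder_pct`,
#'   `f_poles_pct` (summing to exactly 100), `r_um`, `l_um`, `note`.
#' @examples
#' spherocylinder_fractions(r = 0.5, l = 2)  # 75% cylinder / 25% poles
#' @export
spherocylinder_fractions <- function(r, l) {
  if (!is.numeric(r) || !is.numeric(l) || r <= 0 || l < 0)
    pg_stop("'r' must be > 0 and 'l' >= 0", "pgafm_domain_error")
  denom <- (4 / 3) * r + l
  structure(list(f_cylinder_pct = 100 * l / denom,
                 f_poles_pct = 100 * (4 / 3) * r / denom,
                 r_um = r, l_um = l,
                 note = paste("formula matches the spherocylinder volume",
                              "partition; strict area partition would be",
                              "l/(l + 2r)")),
            class = "surface_fractions")
}

#' @export
print.surface_fractions <- function(x, ...) {
  cat(sprintf("<surface_fractions> cylinder %.4g%% / poles %.4g%% (r = %g um, l = %g um)\n",
              x$f_cylinder_pct, x$f_poles_pct, x$r_um, x$l_um))
  invisible(x)
}

#' Construct a chromatogram
#'
#' @param volume strictly increasing elution volume (or time) axis.
#' @param signal non-negative detector signal (e.g. scintillation counts),
#'   same length as `volume`.
#' @return List of class `chromatogram` with `volume` and `signal`.
#' @export
chromatogram <- function(volume, signal) {
  if (length(volume) != length(signal))
    pg_stop("'volume' and 'signal' must have equal length", "pgafm_format_error")
  if (length(volume) < 2L || any(diff(volume) <= 0))
    pg_stop("'volume' must be strictly increasing", "pgafm_format_error")
  if (any(signal < 0))
    pg_stop("'signal' must be non-negative", "pgafm_format_error")
  structure(list(volume = as.numeric(volume), signal = as.numeric(signal)),
            class = "chromatogram")
}

#' Calibrate a size exclusion column from standards
#'
#' Least-squares line of `log10(MW)` against elution volume, the standard SEC
#' calibration (as with dextran standards). Larger molecules elute earlier,
#' so a sound calibration has negative slope; a non-negative slope triggers a
#' warning.
#'
#' @param standards data frame with columns `mw` (Da) and `volume`, at least
#'   two distinct standards.
#' @return List of class `sec_calibration`: `slope`, `intercept` (of
#'   log10(MW) vs volume), `residual_ss`, and the standards.
#' @seealso [predict_mw()], [predict_volume()]
#' @export
calibrate_sec <- function(standards) {
  if (!is.data.frame(standards) || !all(c("mw", "volume") %in% names(standards)))
    pg_stop("'standards' needs columns 'mw' and 'volume'", "pgafm_format_error")
  if (nrow(standards) < 2L || length(unique(standards$volume)) < 2L)
    pg_stop("need at least 2 standards with distinct volumes", "pgafm_fit_error")
  if (any(standards$mw <= 0))
    pg_stop("molecular weights must be positive", "pgafm_domain_error")
  fit <- stats::lm(log10(mw) ~ volume, data = standards)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    warning("SEC calibration slope is non-negative; larger MW should elute earlier")
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
                 residual_ss = sum(stats::residuals(fit)^2),
                 standards = standards),
            class = "sec_calibration")
}

#' Predict molecular weight from elution volume
#' @param cal a [calibrate_sec()] curve.
#' @param volume elution volume(s).
#' @return Molecular weight(s) in Da.
#' @export
predict_mw <- function(cal, volume) 10^(cal$intercept + cal$slope * volume)

#' Predict elution volume from molecular weight
#' @param cal a [calibrate_sec()] curve.
#' @param mw molecular weight(s) in Da.
#' @return Elution volume(s).
#' @export
predict_volume <- function(cal, mw) (log10(mw) - cal$intercept) / cal$slope

#' Fraction of chromatogram signal eluting before a threshold
#'
#' Trapezoidal integral of the signal up to `threshold_volume` (with linear
#' interpolation at the threshold) divided by the total integral, as a
#' percentage. Used, with a calibration, to report the mass fraction of
#' material larger than a given molecular weight standard.
#'
#' @param c a [chromatogram()].
#' @param threshold_volume volume within the axis range.
#' @return Percentage in \[0, 100\].
#' @export
fraction_before <- function(c, threshold_volume) {
  if (!inherits(c, "chromatogram"))
    pg_stop("expected a 'chromatogram'", "pgafm_format_error")
  v <- c$volume; s <- c$signal
  if (threshold_volume < v[1L] || threshold_volume > v[length(v)])
    pg_stop("'threshold_volume' outside the volume axis", "pgafm_bounds_error")
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  total <- trapz(v, s)
  if (total <= 0)
    pg_stop("chromatogram has zero total signal", "pgafm_degenerate_error")
  keep <- v <= threshold_volume
  vb <- v[keep]; sb <- s[keep]
  if (threshold_volume > max(vb)) {
    st <- stats::approx(v, s, xout = threshold_volume)$y
    vb <- c(vb, threshold_volume); sb <- c(sb, st)
  }
  before <- if (length(vb) >= 2L) trapz(vb, sb) else 0
  100 * before / total
}

#' Convert glycan molecular weight to contour length
#'
#' `length = mw / disaccharide_mass * disaccharide_rise`. The defaults take
#' the peptide-free GlcNAc-MurNAc repeating unit at ~480 Da with a rise of
#' ~1.0 nm per disaccharide along the chain; both are explicit parameters
#' because literature values vary with the retained peptide stem. The result
#' is also reported rounded to one significant figure, the precision at which
#' such conversions are usually quoted.
#'
#' @param mw molecular weight in Da (> 0).
#' @param disaccharide_mass Da per disaccharide repeat (default 480).
#' @param disaccharide_rise nm per disaccharide along the chain (default 1.0).
#' @return List of class `chain_length`: `length_nm`,
#'   `length_nm_1_sig_fig`, and the constants used.
#' @examples
#' mw_to_length(1e5)  # a 100 kDa chain is about 200 nm long
#' @export
mw_to_length <- function(mw, disaccharide_mass = 480, disaccharide_rise = 1.0) {
  if (!is.numeric(mw) || mw <= 0 || disaccharide_mass <= 0 ||
      disaccharide_rise <= 0)
    pg_stop("all inputs must be positive", "pgafm_domain_error")
  len <- mw / disaccharide_mass * disaccharide_rise
  structure(list(length_nm = len, length_nm_1_sig_fig = signif(len, 1L),
                 disaccharide_mass_da = disaccharide_mass,
                 disaccharide_rise_nm = disaccharide_rise),
            class = "chain_length")
}

#' @export
print.chain_length <- function(x, ...) {
  cat(sprintf("<chain_length> %.4g nm (~%g nm at 1 s.f.; %g Da and %g nm per disaccharide)\n",
              x$length_nm, x$length_nm_1_sig_fig, x$disaccharide_mass_da,
              x$disaccharide_rise_nm))
  invisible(x)
}
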