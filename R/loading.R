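#' Stance-phase loading construction
#'
#' Builds per-subject compartmental axial joint contact force (JCF) curves
#' over the stance phase of gait under three schemes: even 50%/50% sharing
#' of a body-weight-scaled reference curve, neural-network load sharing
#' with body-weight-scaled peaks (`LS-NN`), and neural-network load sharing
#' and peaks (`LS & Peak-NN`). The normalized JCF shape and the flexion
#' trajectory are fixed across subjects; only the peaks are individualized.
#'
#' @name loading
NULL

# analytic defaults: double-hump JCF shape (loading response ~25% stance,
# push-off ~75%, midstance trough ~0.6 of peak) and a flexion trajectory
# peaking ~15 deg near 15% stance, ~5 deg at midstance, rising at toe-off
.default_shape <- function(s) {
  0.93 * exp(-((s - 25) / 23.5)^2) + exp(-((s - 75) / 23.5)^2)
}
.default_flexion <- function(s) {
  5 + 10 * exp(-((s - 15) / 10)^2) + 15 * exp(-((s - 100) / 15)^2)
}

#' Reference gait curve
#'
#' The experimentally shaped, body-weight-normalized total JCF curve and the
#' fixed flexion-angle trajectory, on a uniform stance grid. The default
#' shape is analytic (two smooth humps with a midstance trough at about 0.6
#' of peak); both curves can be overridden from a CSV with columns
#' `stance_percent`, `normalized_jcf`, `flexion_deg`.
#'
#' @param peak_bw_multiplier Peak total JCF in body weights used to scale
#'   the shape (default 2.6, in line with instrumented-implant walking
#'   data).
#' @param n_grid Number of stance grid points (default 51, every 2%).
#' @param file Optional CSV overriding the curves.
#' @return A `reference_gait_curve`: `stance_percent`, `normalized_jcf`
#'   (maximum exactly 1 at a grid point), `flexion_deg`,
#'   `peak_bw_multiplier`.
#' @export
reference_curve <- function(peak_bw_multiplier = 2.6, n_grid = 51,
                            file = NULL) {
  stopifnot(peak_bw_multiplier > 0, n_grid >= 11)
  if (is.null(file)) {
    s <- seq(0, 100, length.out = n_grid)
    shape <- .default_shape(s)
    flex <- .default_flexion(s)
  } else {
    tb <- read.csv(file)
    req <- c("stance_percent", "normalized_jcf", "flexion_deg")
    if (!all(req %in% names(tb))) {
      stop("curve CSV must have columns: ", paste(req, collapse = ", "))
    }
    s <- tb$stance_percent
    shape <- tb$normalized_jcf
    flex <- tb$flexion_deg
    if (any(shape < 0)) stop("user-supplied JCF shape has negative values")
  }
  shape <- shape / max(shape)
  structure(list(stance_percent = s, normalized_jcf = shape,
                 flexion_deg = flex,
                 peak_bw_multiplier = peak_bw_multiplier),
            class = "reference_gait_curve")
}

#' Write a reference curve to CSV
#'
#' @param curve A `reference_gait_curve`.
#' @param path Output CSV path.
#' @export
write_reference_curve <- function(curve, path) {
  write.csv(data.frame(stance_percent = curve$stance_percent,
                       normalized_jcf = curve$normalized_jcf,
                       flexion_deg = curve$flexion_deg),
            path, row.names = FALSE)
  invisible(path)
}

.gait_loading <- function(curve, peak_medial, peak_lateral, peak_total,
                          share_medial, share_lateral, scheme,
                          contact_fraction = 1) {
  stopifnot(contact_fraction > 0, contact_fraction <= 1)
  structure(list(
    stance_percent = curve$stance_percent,
    flexion_deg = curve$flexion_deg,
    force_medial = curve$normalized_jcf * peak_medial * contact_fraction,
    force_lateral = curve$normalized_jcf * peak_lateral * contact_fraction,
    peak_total = peak_total, peak_medial = peak_medial,
    peak_lateral = peak_lateral,
    share_medial = share_medial, share_lateral = share_lateral,
    contact_fraction = contact_fraction, scheme = scheme
  ), class = "gait_loading")
}

#' Even 50%/50% compartmental loading
#'
#' Peak total JCF is `peak_bw_multiplier * mass * g` and is split evenly
#' between the compartments; each compartment's stance curve is the
#' normalized shape times its peak.
#'
#' @param subject A cohort row or list with at least `mass` (kg).
#' @param curve A [reference_curve()].
#' @param contact_fraction Fraction of the compartment JCF carried by
#'   cartilage-cartilage contact (default 1; lower values emulate meniscal
#'   load bearing).
#' @return A `gait_loading` object.
#' @export
loading_5050 <- function(subject, curve, contact_fraction = 1) {
  stopifnot(subject$mass > 0)
  peak_total <- curve$peak_bw_multiplier * subject$mass * .G
  .gait_loading(curve, peak_total / 2, peak_total / 2, peak_total,
                0.5, 0.5, "5050", contact_fraction)
}

#' Neural-network load sharing with body-weight peaks (LS-NN)
#'
#' Load sharing is the ratio of each predicted compartment peak to the
#' predicted total peak (the shares are not renormalized: the compartment
#' maxima occur at different gait instants, so their ratios need not sum
#' to one). The total peak itself comes from the body-weight-scaled
#' reference curve as in [loading_5050()].
#'
#' @inheritParams loading_5050
#' @param predictor A trained [train_peak_predictor()] model.
#' @return A `gait_loading` object.
#' @export
loading_ls_nn <- function(subject, curve, predictor, contact_fraction = 1) {
  pred <- predict_peaks(predictor, subject)
  if (pred$total <= 0) stop("predicted total peak JCF is non-positive")
  share_m <- pred$medial / pred$total
  share_l <- pred$lateral / pred$total
  peak_total <- curve$peak_bw_multiplier * subject$mass * .G
  .gait_loading(curve, share_m * peak_total, share_l * peak_total,
                peak_total, share_m, share_l, "ls_nn", contact_fraction)
}

#' Neural-network load sharing and peaks (LS & Peak-NN)
#'
#' Compartment peaks are the predicted body-weight peaks converted to
#' Newtons directly (`predicted_bw * mass * g`); the stance curves are the
#' normalized shape times each compartment peak.
#'
#' @inheritParams loading_ls_nn
#' @return A `gait_loading` object.
#' @export
loading_ls_peak_nn <- function(subject, curve, predictor,
                               contact_fraction = 1) {
  pred <- predict_peaks(predictor, subject)
  if (pred$total <= 0) stop("predicted total peak JCF is non-positive")
  peak_m <- pred$medial * subject$mass * .G
  peak_l <- pred$lateral * subject$mass * .G
  peak_total <- pred$total * subject$mass * .G
  .gait_loading(curve, peak_m, peak_l, peak_total,
                pred$medial / pred$total, pred$lateral / pred$total,
                "ls_peak_nn", contact_fraction)
}

#' Write per-compartment loading curves to CSV
#'
#' @param loading A `gait_loading`.
#' @param path Output CSV path.
#' @export
write_loading <- function(loading, path) {
  write.csv(data.frame(stance_percent = loading$stance_percent,
                       flexion_deg = loading$flexion_deg,
                       force_medial = loading$force_medial,
                       force_lateral = loading$force_lateral),
            path, row.names = FALSE)
  invisible(path)
}
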