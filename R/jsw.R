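#' Joint space width and narrowing from frontal-plane contours
#'
#' Measures the radiographic joint space width (JSW) as the vertical
#' distance between the central point of the femoral condyle surface and
#' the tibial plateau below it, computes joint space narrowing (JSN) as
#' the percentage JSW loss between baseline and follow-up, and generates
#' synthetic condyle/plateau contours with a controlled true JSN for
#' validation (a stand-in for gated radiographic data; no real images are
#' involved).
#'
#' Contours are polylines of `(z, y)` points in mm (z mediolateral,
#' y vertical, single-valued in z within each compartment's region of
#' interest).
#'
#' @name radiograph_jsw
NULL

#' Construct joint contours
#'
#' @param femoral,tibial Two-column matrices or data.frames of `(z, y)`
#'   points, mm.
#' @param roi Named list of compartment z-intervals, e.g.
#'   `list(medial = c(-30, -10), lateral = c(10, 30))`.
#' @return A `joint_contours` object.
#' @export
joint_contours <- function(femoral, tibial, roi) {
  femoral <- as.matrix(femoral)
  tibial <- as.matrix(tibial)
  stopifnot(ncol(femoral) == 2, ncol(tibial) == 2,
            all(vapply(roi, length, integer(1)) == 2))
  structure(list(femoral = femoral, tibial = tibial, roi = roi),
            class = "joint_contours")
}

.interp_contour <- function(contour, z) {
  approx(contour[, 1], contour[, 2], xout = z, rule = 1,
         ties = "ordered")$y
}

#' Measure joint space width
#'
#' The central point of the femoral condyle surface is taken at the
#' z-midpoint of the compartment's region of interest (default) or,
#' alternatively, at the lowest femoral point inside the ROI; the JSW is
#' the vertical distance from that point down to the tibial contour at the
#' same z.
#'
#' @param contours A [joint_contours()] object.
#' @param compartment Name of the ROI to measure (e.g. `"medial"`).
#' @param method `"midpoint"` (ROI z-midpoint) or `"lowest"` (lowest
#'   femoral point in the ROI).
#' @return JSW in mm.
#' @export
measure_jsw <- function(contours, compartment,
                        method = c("midpoint", "lowest")) {
  method <- match.arg(method)
  roi <- contours$roi[[compartment]]
  if (is.null(roi)) stop("unknown compartment ROI: ", compartment)
  if (method == "midpoint") {
    z0 <- mean(roi)
  } else {
    in_roi <- contours$femoral[, 1] >= roi[1] & contours$femoral[, 1] <= roi[2]
    if (!any(in_roi)) stop("ROI contains no femoral contour points")
    z0 <- contours$femoral[in_roi, 1][which.min(contours$femoral[in_roi, 2])]
  }
  yf <- .interp_contour(contours$femoral, z0)
  yt <- .interp_contour(contours$tibial, z0)
  if (is.na(yf) || is.na(yt)) {
    stop("central-point projection misses a contour in compartment ",
         compartment)
  }
  yf - yt
}

#' Joint space narrowing between two timepoints
#'
#' `100 * (jsw_baseline - jsw_followup) / jsw_baseline` percent; negative
#' values indicate widening.
#'
#' @param jsw_baseline,jsw_followup JSW values in mm (baseline > 0).
#' @return JSN in percent.
#' @examples
#' compute_jsn(5, 4) # 20
#' @export
compute_jsn <- function(jsw_baseline, jsw_followup) {
  if (any(jsw_baseline <= 0)) stop("baseline JSW must be positive")
  100 * (jsw_baseline - jsw_followup) / jsw_baseline
}

#' Generate synthetic baseline/follow-up contours
#'
#' Builds parametric circular-condyle / flat-plateau contours for both
#' compartments whose true JSW at the ROI midpoint equals the subject's
#' joint space at baseline and `js * (1 - jsn_target/100)` at follow-up,
#' with optional additive Gaussian point noise.
#'
#' @param subject_meas [anatomic_measurements()] of the subject.
#' @param jsn_target True JSN in percent (< 100); scalar or named vector
#'   with `medial`/`lateral` entries.
#' @param noise Contour point noise standard deviation, mm.
#' @param seed Integer seed for the noise.
#' @param condyle_radius Condyle circle radius, mm (default 25).
#' @return List with `baseline` and `followup` [joint_contours()].
#' @export
generate_contours <- function(subject_meas, jsn_target, noise = 0, seed = 1,
                              condyle_radius = 25) {
  if (any(jsn_target >= 100)) stop("jsn_target must be < 100 percent")
  jsn <- if (length(jsn_target) == 1) {
    c(medial = unname(jsn_target), lateral = unname(jsn_target))
  } else jsn_target
  roi <- list(medial = c(-30, -10), lateral = c(10, 30))
  js <- c(medial = subject_meas$js_medial, lateral = subject_meas$js_lateral)
  zg <- seq(-34, 34, by = 0.25)

  build <- function(js_now) {
    yf <- rep(NA_real_, length(zg))
    for (cmp in names(roi)) {
      zc <- mean(roi[[cmp]])
      span <- abs(zg - zc) <= condyle_radius * 0.79
      yf[span] <- pmax(yf[span],
        js_now[[cmp]] + condyle_radius -
          sqrt(condyle_radius^2 - (zg[span] - zc)^2), na.rm = TRUE)
    }
    keep <- !is.na(yf)
    femoral <- cbind(zg[keep], yf[keep])
    tibial <- cbind(zg, rep(0, length(zg)))
    if (noise > 0) {
      femoral[, 2] <- femoral[, 2] + rnorm(nrow(femoral), sd = noise)
      tibial[, 2] <- tibial[, 2] + rnorm(nrow(tibial), sd = noise)
    }
    joint_contours(femoral, tibial, roi)
  }
  .with_seed(seed, {
    baseline <- build(js)
    followup <- build(js * (1 - jsn[c("medial", "lateral")] / 100))
    list(baseline = baseline, followup = followup)
  })
}
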