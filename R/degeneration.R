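#' Age-dependent tensile failure thresholds and degenerated volume
#'
#' Two experimentally derived thresholds of maximum principal (tensile)
#' stress mark the onset of collagen-network degeneration: a piecewise
#' monotone-tension threshold digitized from human cartilage tensile tests
#' (Kempson-type), and a cyclic-fatigue relation linking age and number of
#' loading cycles (Weightman-type). An element counts as degenerated when
#' its stress envelope over the stance phase exceeds the threshold; the
#' degenerated volume is reported as a fraction of the central-region
#' reference volume.
#'
#' @name degeneration
NULL

#' Kempson-type monotonic tensile failure threshold
#'
#' Piecewise-linear in age (years), MPa:
#' 30 for age <= 30; `30 - (age - 30) * 20/15` on (30, 45];
#' `10 - (age - 45) * 3/20` on (45, 65]; `7 - (age - 65) * 2/100` on
#' (65, 75]; 6.8 above 75. Continuous at every breakpoint and
#' non-increasing in age.
#'
#' @param age Age(s) in years, > 0.
#' @return Threshold(s), MPa.
#' @examples
#' threshold_kempson(c(25, 45, 65, 80))
#' @export
threshold_kempson <- function(age) {
  if (any(!is.finite(age) | age <= 0)) stop("age must be positive")
  ifelse(age <= 30, 30,
  ifelse(age <= 45, 30 - (age - 30) * (20 / 15),
  ifelse(age <= 65, 10 - (age - 45) * (3 / 20),
  ifelse(age <= 75, 7 - (age - 65) * (2 / 100), 6.8))))
}

#' Weightman-type cyclic fatigue failure threshold
#'
#' `25.4 - 0.15 * age - 1.65 * log10(N)` MPa, strictly decreasing in both
#' age and the number of loading cycles `N`.
#'
#' @param age Age(s) in years, > 0.
#' @param N Number of loading cycles, >= 1 (typically 1e5, 1e6 or 1e7).
#' @return Threshold(s), MPa; an error if the relation is exhausted
#'   (non-positive value).
#' @examples
#' threshold_weightman(30, 1e6) # 11 MPa
#' @export
threshold_weightman <- function(age, N) {
  if (any(!is.finite(age) | age <= 0)) stop("age must be positive")
  if (any(!is.finite(N) | N < 1)) stop("N must be >= 1")
  value <- 25.4 - 0.15 * age - 1.65 * log10(N)
  if (any(value <= 0)) {
    bad <- which(value <= 0)[1]
    stop(sprintf(
      "fatigue threshold exhausted (<= 0 MPa) at age %.4g, N = %.4g",
      age[min(bad, length(age))], N[min(bad, length(N))]))
  }
  value
}

#' Quantify degenerated cartilage volume
#'
#' An element is degenerated when its maximum principal stress exceeds the
#' threshold at any stance frame (the envelope). Only central-region
#' elements enter the statistic; the reference volume is the total
#' central-region cartilage volume of the compartment (both tissues, so
#' the femoral and tibial fractions sum to the compartment fraction).
#'
#' @param field A `stress_field` from [simulate_stance()].
#' @param mesh The matching `compartment_mesh`.
#' @param threshold Failure threshold, MPa (> 0).
#' @param per_tissue_reference If `TRUE`, per-tissue fractions are reported
#'   against each tissue's own central-region volume instead of the shared
#'   compartment reference.
#' @return A `degeneration_result`: fractions per tissue and for the
#'   compartment, the degenerated and reference volumes (mm^3) and the
#'   threshold used.
#' @export
degenerated_volume <- function(field, mesh, threshold,
                               per_tissue_reference = FALSE) {
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be a positive stress in MPa")
  }
  if (length(field$envelope) != nrow(mesh$hexa)) {
    stop("stress field and mesh have inconsistent element counts")
  }
  vols <- element_volumes(mesh)
  central <- mesh$region == "central"
  fem <- mesh$tissue == "femoral_cartilage"
  exceed <- field$envelope > threshold
  ref_total <- sum(vols[central])
  ref_fem <- sum(vols[central & fem])
  ref_tib <- sum(vols[central & !fem])
  deg_fem <- sum(vols[central & fem & exceed])
  deg_tib <- sum(vols[central & !fem & exceed])
  denom_fem <- if (per_tissue_reference) ref_fem else ref_total
  denom_tib <- if (per_tissue_reference) ref_tib else ref_total
  structure(list(
    fraction_femoral = deg_fem / denom_fem,
    fraction_tibial = deg_tib / denom_tib,
    fraction_compartment = (deg_fem + deg_tib) / ref_total,
    degenerated_volume = deg_fem + deg_tib,
    reference_volume = ref_total,
    per_tissue_reference = per_tissue_reference,
    threshold = threshold,
    compartment = mesh$compartment
  ), class = "degeneration_result")
}

#' Combine medial and lateral results into whole-knee fractions
#'
#' The overall knee fraction is the summed degenerated volume of both
#' compartments divided by their summed reference volumes.
#'
#' @param medial,lateral `degeneration_result`s for the two compartments.
#' @return List with `fraction_overall`, the compartment fractions and
#'   volumes.
#' @export
knee_degeneration <- function(medial, lateral) {
  list(fraction_overall =
         (medial$degenerated_volume + lateral$degenerated_volume) /
         (medial$reference_volume + lateral$reference_volume),
       fraction_medial = medial$fraction_compartment,
       fraction_lateral = lateral$fraction_compartment,
       degenerated_volume = medial$degenerated_volume +
         lateral$degenerated_volume,
       reference_volume = medial$reference_volume +
         lateral$reference_volume)
}
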