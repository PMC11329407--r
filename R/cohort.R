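#' Synthetic knee osteoarthritis cohort
#'
#' Tools to generate and validate per-knee subject records (demographics,
#' gait, frontal-plane alignment, Kellgren-Lawrence grades) together with
#' the simple MRI-based anatomic measurements that drive template scaling
#' (intercondylar distance, anterior-posterior condyle extents, joint
#' spaces, femoral thickness fractions).
#'
#' The generator is calibrated so that, for large `n`, each variable's
#' sample median and interquartile range approximate the published
#' cohort-level summaries of a 97-knee osteoarthritis study population
#' (71% female, median age 58 y, mass 73.6 kg, height 166.5 cm, walking
#' speed 1.37 m/s, alignment 5.14 deg, ICD 40.6 mm, medial/lateral A-P
#' 53.05/62.59 mm, joint spaces 4.79/5.38 mm, femoral fractions 0.55/0.40).
#' Right-skewed lengths and mass use log-normal marginals; age, speed,
#' alignment and the femoral fractions use truncated normals. Height and
#' mass are coupled through a Gaussian copula.
#'
#' Follow-up KL grades are planted through a latent score
#' `effect_size * standardize(peak medial load / medial joint space) + noise`
#' so that downstream mechanics carry a recoverable association with the
#' KL outcome; `effect_size = 0` makes grades independent of mechanics.
#'
#' @name cohort
NULL

# Marginal calibration table: median and quartiles on the original scale,
# distribution family, and generous plausibility bounds for truncation.
.cohort_marginals <- list(
  age              = list(med = 58,    q25 = 53.75, q75 = 61.25, family = "normal", lo = 35,   hi = 85),
  mass             = list(med = 73.60, q25 = 64.35, q75 = 88.32, family = "lnorm",  lo = 40,   hi = 150),
  height           = list(med = 166.5, q25 = 159.9, q75 = 172.9, family = "lnorm",  lo = 140,  hi = 200),
  walking_speed    = list(med = 1.37,  q25 = 1.25,  q75 = 1.50,  family = "normal", lo = 0.6,  hi = 2.2),
  joint_alignment  = list(med = 5.14,  q25 = 2.49,  q75 = 7.21,  family = "normal", lo = -8,   hi = 18),
  icd              = list(med = 40.60, q25 = 37.80, q75 = 43.40, family = "lnorm",  lo = 30,   hi = 55),
  ap_medial        = list(med = 53.05, q25 = 51.05, q75 = 56.42, family = "lnorm",  lo = 42,   hi = 68),
  ap_lateral       = list(med = 62.59, q25 = 59.62, q75 = 65.88, family = "lnorm",  lo = 50,   hi = 80),
  js_medial        = list(med = 4.79,  q25 = 4.37,  q75 = 5.48,  family = "lnorm",  lo = 2.5,  hi = 8),
  js_lateral       = list(med = 5.38,  q25 = 4.74,  q75 = 6.20,  family = "lnorm",  lo = 2.8,  hi = 9),
  femoral_fraction_medial  = list(med = 0.55, q25 = 0.48, q75 = 0.5725, family = "normal", lo = 0.30, hi = 0.75),
  femoral_fraction_lateral = list(med = 0.40, q25 = 0.36, q75 = 0.46,   family = "normal", lo = 0.20, hi = 0.65)
)

# Quantile function of a truncated marginal, evaluated at latent standard
# normal scores so that correlated variables can share a Gaussian copula.
.marginal_from_z <- function(z, spec) {
  k <- 2 * qnorm(0.75) # IQR in sd units
  if (spec$family == "normal") {
    mu <- spec$med
    sig <- (spec$q75 - spec$q25) / k
    plo <- pnorm(spec$lo, mu, sig)
    phi <- pnorm(spec$hi, mu, sig)
    u <- plo + pnorm(z) * (phi - plo)
    qnorm(u, mu, sig)
  } else {
    mlog <- log(spec$med)
    slog <- log(spec$q75 / spec$q25) / k
    plo <- plnorm(spec$lo, mlog, slog)
    phi <- plnorm(spec$hi, mlog, slog)
    u <- plo + pnorm(z) * (phi - plo)
    qlnorm(u, mlog, slog)
  }
}

#' Assign the Kellgren-Lawrence analysis group
#'
#' Maps follow-up KL grades to the three analysis groups used throughout the
#' pipeline: grades 0-1 (remain radiographically healthy), grade 2
#' (moderate), and grades 3-4 (severe).
#'
#' @param kl_followup Integer vector of KL grades (0-4) at follow-up.
#' @return Character vector with levels `"KL01"`, `"KL2"`, `"KL34"`.
#' @examples
#' assign_kl_group(c(0, 1, 2, 3, 4))
#' @export
assign_kl_group <- function(kl_followup) {
  if (any(is.na(kl_followup)) ||
      any(kl_followup != round(kl_followup)) ||
      any(kl_followup < 0 | kl_followup > 4)) {
    stop("kl_followup must contain integer KL grades in 0-4")
  }
  ifelse(kl_followup <= 1, "KL01", ifelse(kl_followup == 2, "KL2", "KL34"))
}

#' Noise-free surrogate musculoskeletal peak joint contact forces
#'
#' A deliberately simple stand-in for a musculoskeletal model: peak total
#' joint contact force in body weights rises with walking speed (about
#' 2.6 BW at the cohort-median 1.37 m/s) and falls slightly with mass,
#' while frontal-plane (varus) alignment shifts load toward the medial
#' compartment. These noise-free values are the ground truth against which
#' noisy neural-network training targets are generated and from which the
#' cohort's planted mechanics-to-KL association is built.
#'
#' @param mass Body mass, kg.
#' @param walking_speed Self-selected walking speed, m/s.
#' @param joint_alignment Frontal-plane alignment, degrees (positive varus,
#'   medializing).
#' @return `data.frame` with columns `medial`, `lateral`, `total` (peak
#'   stance-phase joint contact forces, body weights).
#' @export
surrogate_peaks_bw <- function(mass, walking_speed, joint_alignment) {
  total <- 1.9 + 0.5 * walking_speed - 0.002 * (mass - 73.6)
  share_medial <- pmin(0.85, pmax(0.2, 0.5 + 0.022 * joint_alignment))
  data.frame(
    medial = total * share_medial,
    lateral = total * (1 - share_medial),
    total = total
  )
}

#' Generate a synthetic cohort of knees
#'
#' Draws `n` per-knee records whose marginal distributions match the
#' calibration summaries described in [cohort], couples height and mass with
#' a Gaussian copula, and assigns follow-up KL groups by thresholding a
#' latent score that mixes standardized peak medial load per unit medial
#' joint space with standard-normal noise. Group sizes follow the 29/37/31
#' split of the reference population.
#'
#' @param n Number of knees (>= 3).
#' @param seed Integer seed; identical inputs give byte-identical cohorts.
#' @param effect_size Strength of the planted mechanics-to-KL association
#'   (0 = no association; default 1.5).
#' @param rho_height_mass Gaussian-copula correlation between height and
#'   mass (default 0.5).
#' @param female_fraction,right_fraction Bernoulli rates for sex and knee
#'   side (defaults 0.71 and 0.57).
#' @param group_fractions Target KL01/KL2/KL34 proportions (default
#'   `c(29, 37, 31)/97`).
#' @return `data.frame`, one row per knee, with demographic, gait, anatomic
#'   and KL columns plus `kl_group`.
#' @examples
#' head(generate_cohort(10, seed = 1))
#' @export
generate_cohort <- function(n, seed, effect_size = 1.5, rho_height_mass = 0.5,
                            female_fraction = 0.71, right_fraction = 0.57,
                            group_fractions = c(29, 37, 31) / 97) {
  if (n < 3) stop("n must be at least 3 so that all KL groups can be filled")
  stopifnot(length(group_fractions) == 3, abs(sum(group_fractions) - 1) < 1e-8)
  .with_seed(seed, {
    m <- .cohort_marginals
    # latent normals; height/mass share a copula, the rest independent
    z <- matrix(rnorm(n * length(m)), nrow = n,
                dimnames = list(NULL, names(m)))
    z[, "mass"] <- rho_height_mass * z[, "height"] +
      sqrt(1 - rho_height_mass^2) * z[, "mass"]
    vals <- lapply(names(m), function(v) .marginal_from_z(z[, v], m[[v]]))
    names(vals) <- names(m)
    cohort <- data.frame(
      id = sprintf("K%04d", seq_len(n)),
      age = vals$age,
      sex = ifelse(runif(n) < female_fraction, "female", "male"),
      mass = vals$mass,
      height = vals$height,
      walking_speed = vals$walking_speed,
      joint_alignment = vals$joint_alignment,
      knee_side = ifelse(runif(n) < right_fraction, "right", "left"),
      icd = vals$icd,
      ap_medial = vals$ap_medial,
      ap_lateral = vals$ap_lateral,
      js_medial = vals$js_medial,
      js_lateral = vals$js_lateral,
      femoral_fraction_medial = vals$femoral_fraction_medial,
      femoral_fraction_lateral = vals$femoral_fraction_lateral,
      stringsAsFactors = FALSE
    )
    # planted outcome: peak medial load (N) per unit medial joint space (mm)
    peaks <- surrogate_peaks_bw(cohort$mass, cohort$walking_speed,
                                cohort$joint_alignment)
    score <- peaks$medial * cohort$mass * .G / cohort$js_medial
    latent <- effect_size * as.numeric(scale(score)) + rnorm(n)
    n1 <- round(n * group_fractions[1])
    n2 <- round(n * group_fractions[2])
    r <- rank(latent, ties.method = "first")
    grp <- ifelse(r <= n1, "KL01", ifelse(r <= n1 + n2, "KL2", "KL34"))
    cohort$kl_baseline <- sample(0:1, n, replace = TRUE)
    cohort$kl_followup <- ifelse(grp == "KL01", sample(0:1, n, replace = TRUE),
                          ifelse(grp == "KL2", 2L,
                                 sample(3:4, n, replace = TRUE)))
    cohort$kl_group <- assign_kl_group(cohort$kl_followup)
    cohort
  })
}

#' Validate a cohort table
#'
#' Checks the invariants of per-knee records: strictly positive age, mass,
#' height and walking speed; KL grades in 0-4; positive anatomic lengths;
#' femoral fractions strictly inside (0, 1).
#'
#' @param cohort `data.frame` as produced by [generate_cohort()] or read
#'   from a cohort CSV.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  req <- c("id", "age", "sex", "mass", "height", "walking_speed",
           "joint_alignment", "knee_side", "icd", "ap_medial", "ap_lateral",
           "js_medial", "js_lateral", "femoral_fraction_medial",
           "femoral_fraction_lateral", "kl_baseline", "kl_followup")
  missing <- setdiff(req, names(cohort))
  if (length(missing)) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  }
  pos <- c("age", "mass", "height", "walking_speed", "icd", "ap_medial",
           "ap_lateral", "js_medial", "js_lateral")
  for (v in pos) {
    if (any(!is.finite(cohort[[v]]) | cohort[[v]] <= 0)) {
      stop("cohort column '", v, "' must be strictly positive and finite")
    }
  }
  for (v in c("femoral_fraction_medial", "femoral_fraction_lateral")) {
    if (any(cohort[[v]] <= 0 | cohort[[v]] >= 1)) {
      stop("cohort column '", v, "' must lie strictly inside (0, 1)")
    }
  }
  assign_kl_group(cohort$kl_followup)
  assign_kl_group(cohort$kl_baseline)
  if (!all(cohort$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  if (!all(cohort$knee_side %in% c("left", "right"))) {
    stop("knee_side must be 'left' or 'right'")
  }
  invisible(cohort)
}

#' Extract one knee's anatomic measurements from a cohort row
#'
#' @param row A single cohort row.
#' @return An `anatomic_measurements` object (see
#'   [anatomic_measurements()]).
#' @export
cohort_measurements <- function(row) {
  stopifnot(nrow(row) == 1)
  anatomic_measurements(
    icd = row$icd,
    ap_medial = row$ap_medial, ap_lateral = row$ap_lateral,
    js_medial = row$js_medial, js_lateral = row$js_lateral,
    femoral_fraction_medial = row$femoral_fraction_medial,
    femoral_fraction_lateral = row$femoral_fraction_lateral
  )
}

#' Read or write a cohort CSV
#'
#' One row per knee; column names mirror the calibration variables.
#'
#' @param cohort Cohort `data.frame`.
#' @param path File path.
#' @return `read_cohort` returns a validated cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}
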