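#' Cartilage contact mechanics surrogate
#'
#' Computes per-element maximum principal solid stress fields over stance
#' with an instantaneous-incompressible elastic-foundation (independent
#' column) surrogate for the fibril-reinforced biphasic cartilage model.
#' The rationale: over the roughly one second of a simulated stance phase,
#' fluid exchange in cartilage is negligible, so the instantaneous
#' (incompressible) response dominates the solid stress. Each contact
#' column compresses axially; the incompressibility constraint stretches
#' the tissue in-plane and loads the tension-only collagen fibril network.
#'
#' Closed form per tissue sub-column at compressive strain `e`:
#' axial stretch `lambda = 1 - e`, in-plane stretch
#' `lambda_t = lambda^(-1/2)`, fibril Green-Lagrange strain
#' `E_f = (lambda_t^2 - 1)/2`, tension-only power-law fibril stresses
#' `sigma_p = xi_fp E_f^beta_fp`, `sigma_s = xi_fs E_f^beta_fs`, matrix
#' shear `mu = E_nf/(3 (1 + nu_nf))`, matrix in-plane deviatoric stress
#' `sigma_m = mu (lambda_t^2 - lambda^2)`; surface maximum principal
#' stress `sigma_I = sigma_p + sigma_s + sigma_m` and column pressure
#' `p = mu (1/lambda - lambda^2) + sigma_p + sigma_s`. The femoral and
#' tibial sub-columns connect in series: the column strain is partitioned
#' (thickness-weighted) so their pressures match.
#'
#' @name mechanics
NULL

#' Cartilage material properties
#'
#' Fibril-reinforced biphasic constants per tissue. `kappa0` (initial
#' permeability, 1e-15 m^4/(N s)), `M_perm` (strain-dependent permeability
#' exponent) and `phi0` (initial solid fraction) are carried for
#' full-fidelity solver-deck export and are intentionally unused by the
#' instantaneous surrogate, which involves no fluid flow.
#'
#' @param tissue `"femur"` or `"tibia"` (selects the defaults).
#' @param ... Named overrides of individual constants.
#' @return List of constants with class `cartilage_props`.
#' @export
cartilage_props <- function(tissue = c("femur", "tibia"), ...) {
  tissue <- match.arg(tissue)
  defaults <- if (tissue == "tibia") {
    list(xi_fp = 32, beta_fp = 2.6, xi_fs = 1.0, beta_fs = 2.6,
         E_nf = 0.106, nu_nf = 0.15, kappa0 = 18, M_perm = 15.24,
         phi0 = 0.2, tissue = "tibia")
  } else {
    list(xi_fp = 215, beta_fp = 2.6, xi_fs = 3.0, beta_fs = 2.6,
         E_nf = 0.215, nu_nf = 0.15, kappa0 = 6, M_perm = 45.06,
         phi0 = 0.2, tissue = "femur")
  }
  props <- modifyList(defaults, list(...))
  stopifnot(props$xi_fp >= 0, props$xi_fs >= 0, props$E_nf > 0,
            props$phi0 > 0, props$phi0 < 1)
  structure(props, class = "cartilage_props")
}

#' Default material set (femur + tibia)
#' @return Named list `femur`, `tibia` of [cartilage_props()].
#' @export
default_props <- function() {
  list(femur = cartilage_props("femur"), tibia = cartilage_props("tibia"))
}

# instantaneous-incompressible response of one tissue at compressive
# strain eps (vectorized); all stress terms are >= 0 for eps in [0, 1)
.tissue_response <- function(eps, props) {
  lam <- 1 - eps
  lamt2 <- 1 / lam # lambda_t^2 = lambda^(-1)
  Ef <- pmax(0, (lamt2 - 1) / 2)
  sp <- props$xi_fp * Ef^props$beta_fp
  ss <- props$xi_fs * Ef^props$beta_fs
  mu <- props$E_nf / (3 * (1 + props$nu_nf))
  sm <- mu * (lamt2 - lam^2)
  list(pressure = mu * (1 / lam - lam^2) + sp + ss,
       sigma_I = sp + ss + sm)
}

#' Series column response of a femoral + tibial cartilage column
#'
#' Partitions the total column compressive strain between the femoral and
#' tibial sub-columns (weighted by their thicknesses) so that the two
#' tissues carry a common pressure, and returns that pressure together
#' with each tissue's surface maximum principal stress. Strains at or
#' beyond the cap saturate at the cap value and are flagged.
#'
#' @param epsilon Total column compressive strain(s), in `[0, cap)`.
#' @param props_f,props_t Femoral and tibial [cartilage_props()].
#' @param thickness_femoral,thickness_tibial Sub-column thicknesses, mm.
#' @param cap Total-strain cap (default 0.6).
#' @return `data.frame` with `pressure` (MPa), `sigma_I_femoral`,
#'   `sigma_I_tibial` (MPa), the partitioned `eps_femoral`, `eps_tibial`,
#'   and a `saturated` flag.
#' @export
column_response <- function(epsilon, props_f, props_t,
                            thickness_femoral = 1, thickness_tibial = 1,
                            cap = 0.6) {
  stopifnot(thickness_femoral > 0, thickness_tibial > 0,
            all(epsilon >= 0))
  t_f <- thickness_femoral
  t_t <- thickness_tibial
  total <- t_f + t_t
  one <- function(eps) {
    saturated <- eps >= cap
    if (saturated) {
      warning("column strain at cap; response saturated", call. = FALSE)
      eps <- cap
    }
    if (eps == 0) {
      return(c(0, 0, 0, 0, 0, saturated))
    }
    D <- eps * total # total deformation, mm
    hi <- min(0.95, D / t_f)
    lo <- max(0, (D - 0.95 * t_t) / t_f)
    g <- function(ef) {
      et <- (D - ef * t_f) / t_t
      .tissue_response(ef, props_f)$pressure -
        .tissue_response(et, props_t)$pressure
    }
    ef <- if (g(hi) <= 0) hi else if (g(lo) >= 0) lo else {
      uniroot(g, c(lo, hi), tol = 1e-12)$root
    }
    et <- (D - ef * t_f) / t_t
    rf <- .tissue_response(ef, props_f)
    rt <- .tissue_response(et, props_t)
    p <- (rf$pressure + rt$pressure) / 2
    c(p, rf$sigma_I, rt$sigma_I, ef, et, saturated)
  }
  out <- t(vapply(epsilon, one, numeric(6)))
  data.frame(pressure = out[, 1], sigma_I_femoral = out[, 2],
             sigma_I_tibial = out[, 3], eps_femoral = out[, 4],
             eps_tibial = out[, 5], saturated = as.logical(out[, 6]))
}

# Tabulated column response for fast repeated evaluation during a stance
# simulation (thicknesses are uniform across columns of a template mesh).
# The partition depends on the thickness fraction only, so tables are
# cached across subjects sharing a femoral fraction (e.g. fixed-ratio
# scaling of one template).
.resp_cache <- new.env(parent = emptyenv())

.response_table <- function(props_f, props_t, t_f, t_t, cap = 0.6,
                            n = 161) {
  frac <- t_f / (t_f + t_t)
  pkey <- function(p) paste(p$xi_fp, p$beta_fp, p$xi_fs, p$beta_fs,
                            p$E_nf, p$nu_nf, sep = ",")
  key <- paste(signif(frac, 12), cap, n, pkey(props_f), pkey(props_t),
               sep = "|")
  hit <- .resp_cache[[key]]
  if (!is.null(hit)) return(hit)

  eps <- seq(0, cap, length.out = n)
  # thickness-weighted strain partition, common pressure: vectorized
  # bisection on the femoral strain (g is increasing in eps_f)
  et_of <- function(ef) pmax(0, (eps - ef * frac) / (1 - frac))
  g <- function(ef) {
    .tissue_response(ef, props_f)$pressure -
      .tissue_response(et_of(ef), props_t)$pressure
  }
  lo <- pmax(0, (eps - 0.95 * (1 - frac)) / frac)
  hi <- pmin(0.95, eps / frac)
  for (it in seq_len(60)) {
    mid <- (lo + hi) / 2
    up <- g(mid) > 0
    hi <- ifelse(up, mid, hi)
    lo <- ifelse(up, lo, mid)
  }
  ef <- (lo + hi) / 2
  rf <- .tissue_response(ef, props_f)
  rt <- .tissue_response(et_of(ef), props_t)
  p <- (rf$pressure + rt$pressure) / 2
  out <- list(p = approxfun(eps, p, rule = 2),
              sf = approxfun(eps, rf$sigma_I, rule = 2),
              st = approxfun(eps, rt$sigma_I, rule = 2),
              p_cap = p[n], cap = cap)
  .resp_cache[[key]] <- out
  out
}

# static per-mesh contact bookkeeping reused across stance frames
.stance_static <- function(mesh) {
  nx <- mesh$nx
  nz <- mesh$nz
  Xf <- matrix(mesh$nodes[mesh$surf_fem, 1], nx + 1, nz + 1)
  Yf <- matrix(mesh$nodes[mesh$surf_fem, 2], nx + 1, nz + 1)
  Yt <- matrix(mesh$nodes[mesh$surf_tib, 2], nx + 1, nz + 1)
  Xt <- matrix(mesh$nodes[mesh$surf_tib, 1], nx + 1, nz + 1)
  Zt <- matrix(mesh$nodes[mesh$surf_tib, 3], nx + 1, nz + 1)
  # footprint cell centroids and tibial surface height at the centroids
  xc <- (Xt[-1, 1] + Xt[-(nx + 1), 1]) / 2
  y_t_cell <- (Yt[-1, -1] + Yt[-1, -(nz + 1)] +
               Yt[-(nx + 1), -1] + Yt[-(nx + 1), -(nz + 1)]) / 4
  dx <- Xt[2, 1] - Xt[1, 1]
  dz <- Zt[1, 2] - Zt[1, 1]
  zc <- (Zt[1, -1] + Zt[1, -(nz + 1)]) / 2
  list(nx = nx, nz = nz, Xf = Xf, Yf = Yf, xc = xc, zc = zc,
       y_t = y_t_cell, area = abs(dx * dz),
       center = c(mean(Xf), mean(Yf)))
}

# vertical gaps between the flexion-rotated femoral surface and the tibial
# surface at the footprint cell centroids; NA = no opposing femoral surface
.frame_gaps <- function(static, flexion_deg) {
  phi <- flexion_deg * pi / 180
  cx <- static$center[1]
  cy <- static$center[2]
  Xr <- cx + (static$Xf - cx) * cos(phi) - (static$Yf - cy) * sin(phi)
  Yr <- cy + (static$Xf - cx) * sin(phi) + (static$Yf - cy) * cos(phi)
  nx <- static$nx
  nz <- static$nz
  # per femoral grid z-line, interpolate rotated surface height at the
  # cell-centroid x positions, then average adjacent z-lines (centroid z
  # is the midpoint between grid lines)
  y_lines <- matrix(NA_real_, nx, nz + 1)
  for (k in seq_len(nz + 1)) {
    y_lines[, k] <- approx(Xr[, k], Yr[, k], xout = static$xc,
                           rule = 1, ties = "ordered")$y
  }
  y_f <- (y_lines[, -1, drop = FALSE] + y_lines[, -(nz + 1), drop = FALSE]) / 2
  y_f - static$y_t
}

#' Build contact columns for a mesh at a given flexion angle
#'
#' Rotates the femoral articular surface about the Z axis through the
#' condyle-surface centroid by the flexion angle (positive flexion moves
#' the closest-approach point posteriorly, toward negative X) and computes
#' the vertical gap from each tibial footprint cell to the rotated femoral
#' surface.
#'
#' @param mesh A `compartment_mesh` from [build_template()] /
#'   [scale_mesh()].
#' @param flexion_deg Flexion angle, degrees.
#' @return `data.frame` of columns: `cell`, centroid `x`, `z`, `area`
#'   (mm^2), signed `gap` (mm, positive = separation), `contacting`
#'   (FALSE where no opposing femoral surface exists), and the per-tissue
#'   thicknesses as attributes.
#' @export
build_columns <- function(mesh, flexion_deg = 0) {
  static <- .stance_static(mesh)
  gaps <- .frame_gaps(static, flexion_deg)
  df <- data.frame(cell = seq_len(static$nx * static$nz),
                   x = rep(static$xc, static$nz),
                   z = rep(static$zc, each = static$nx),
                   area = static$area,
                   gap = as.vector(gaps))
  df$contacting <- !is.na(df$gap)
  attr(df, "thickness") <- mesh$thickness
  df
}

# equilibrium of one stance frame against a tabulated column response
.solve_frame <- function(gaps, area, total_thickness, force, resp,
                         frame_label = "frame") {
  ok <- !is.na(gaps)
  eps_of <- function(delta) {
    pmin(resp$cap, pmax(0, (delta - gaps[ok]) / total_thickness))
  }
  f <- function(delta) sum(resp$p(eps_of(delta)) * area)
  capacity <- sum(resp$p_cap * area * as.numeric(ok))
  if (force > capacity * (1 - 1e-9)) {
    stop(sprintf(
      "%s: applied force %.6g N exceeds column capacity %.6g N at the strain cap",
      frame_label, force, capacity))
  }
  eps <- rep(0, length(gaps))
  if (force <= 0) {
    delta <- min(gaps[ok])
  } else {
    lo <- min(gaps[ok])
    hi <- max(gaps[ok]) + resp$cap * total_thickness
    delta <- uniroot(function(d) f(d) - force, c(lo, hi),
                     tol = 1e-13 * max(1, hi))$root
    eps[ok] <- eps_of(delta)
  }
  pressure <- rep(0, length(gaps))
  pressure[ok] <- resp$p(eps[ok])
  list(delta = delta, eps = eps, pressure = pressure,
       contact_area = sum(area * (eps > 0)),
       residual = abs(sum(pressure[ok] * area) - force))
}

#' Solve one contact frame
#'
#' Finds the rigid axial approach of the femoral surface such that the
#' integrated column pressures balance the applied axial force to within a
#' relative residual of 1e-6, and reports per-column strain and pressure.
#'
#' @param columns Output of [build_columns()].
#' @param force Applied compartment axial force, N (>= 0).
#' @param props Material set, see [default_props()].
#' @param cap Total-strain cap (default 0.6).
#' @return List with `delta` (mm), per-column `eps` and `pressure` (MPa),
#'   `contact_area` (mm^2), surface `sigma_I_femoral`/`sigma_I_tibial`
#'   per column (MPa), and the equilibrium `residual` (N).
#' @export
solve_contact_frame <- function(columns, force, props = default_props(),
                                cap = 0.6) {
  stopifnot(force >= 0)
  th <- attr(columns, "thickness")
  resp <- .response_table(props$femur, props$tibia,
                          th[["femoral"]], th[["tibial"]], cap = cap)
  sol <- .solve_frame(columns$gap, columns$area[1], sum(th), force, resp)
  sol$sigma_I_femoral <- resp$sf(sol$eps)
  sol$sigma_I_tibial <- resp$st(sol$eps)
  sol$sigma_I_femoral[sol$eps <= 0] <- 0
  sol$sigma_I_tibial[sol$eps <= 0] <- 0
  sol
}

# map element layer index to the three depth bands of the weight profile
.depth_band <- function(layer, n_layers) {
  pmin(3L, pmax(1L, ceiling(3 * (layer + 1) / n_layers)))
}

#' Simulate the stance phase for one compartment
#'
#' Runs the frame equilibrium solve at every stance grid point with that
#' frame's flexion angle and compartment force, assigns per-element maximum
#' principal stress from the column's tissue surface value times a depth
#' weight profile (a stand-in for the arcade-like depth variation of the
#' collagen network), and retains both the full history and the per-element
#' envelope maximum over frames.
#'
#' @param mesh A `compartment_mesh`.
#' @param loading A `gait_loading` (see [loading_5050()] and friends); the
#'   force curve matching `mesh$compartment` is used.
#' @param props Material set, see [default_props()].
#' @param depth_weights Weights for the superficial/middle/deep thirds of
#'   each tissue (default `c(1, 0.5, 0.25)`).
#' @param cap Total-strain cap (default 0.6).
#' @param n_table Resolution of the tabulated column response.
#' @return A `stress_field`: `sigma` (elements x frames, MPa), `envelope`,
#'   `pressure` (columns x frames), `contact_area`, `delta`, `residual`
#'   and `force` per frame, plus the stance grid.
#' @export
simulate_stance <- function(mesh, loading, props = default_props(),
                            depth_weights = c(1, 0.5, 0.25), cap = 0.6,
                            n_table = 161) {
  stopifnot(length(depth_weights) == 3)
  forces <- if (mesh$compartment == "medial") loading$force_medial
            else loading$force_lateral
  flex <- loading$flexion_deg
  n_frames <- length(forces)
  stopifnot(length(flex) == n_frames)

  th <- mesh$thickness
  resp <- .response_table(props$femur, props$tibia,
                          th[["femoral"]], th[["tibial"]],
                          cap = cap, n = n_table)
  static <- .stance_static(mesh)
  m <- nrow(mesh$hexa)
  n_cols <- static$nx * static$nz
  sigma <- matrix(0, m, n_frames)
  pressure <- matrix(0, n_cols, n_frames)
  contact_area <- numeric(n_frames)
  delta <- numeric(n_frames)
  residual <- numeric(n_frames)

  is_fem <- mesh$tissue == "femoral_cartilage"
  w_elem <- depth_weights[.depth_band(mesh$layer, mesh$n_layers)]
  cell_of <- mesh$cell

  for (i in seq_len(n_frames)) {
    gaps <- as.vector(.frame_gaps(static, flex[i]))
    sol <- .solve_frame(gaps, static$area, sum(th), forces[i], resp,
                        frame_label = sprintf("stance frame %d (%.0f%%)",
                                              i, loading$stance_percent[i]))
    sf <- resp$sf(sol$eps)
    st <- resp$st(sol$eps)
    sf[sol$eps <= 0] <- 0
    st[sol$eps <= 0] <- 0
    sigma[, i] <- ifelse(is_fem, sf[cell_of], st[cell_of]) * w_elem
    pressure[, i] <- sol$pressure
    contact_area[i] <- sol$contact_area
    delta[i] <- sol$delta
    residual[i] <- sol$residual
  }
  structure(list(sigma = sigma, envelope = apply(sigma, 1, max),
                 pressure = pressure, contact_area = contact_area,
                 delta = delta, residual = residual, force = forces,
                 stance_percent = loading$stance_percent,
                 compartment = mesh$compartment),
            class = "stress_field")
}

#' Write a stress field as long-format CSV
#'
#' One row per element and stance frame.
#'
#' @param field A `stress_field`.
#' @param path Output CSV path.
#' @export
write_stress_csv <- function(field, path) {
  m <- nrow(field$sigma)
  f <- ncol(field$sigma)
  write.csv(data.frame(element = rep(seq_len(m), f),
                       frame = rep(seq_len(f), each = m),
                       stance_percent = rep(field$stance_percent, each = m),
                       sigma_I = as.vector(field$sigma)),
            path, row.names = FALSE)
  invisible(path)
}
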