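#' Anatomic measurements of one knee
#'
#' Container for the simple MRI-based measurements that drive template
#' scaling: femoral intercondylar distance (ICD), maximum femoral
#' anterior-posterior (A-P) extents of the medial and lateral condyles,
#' joint spaces (JS) measured in the same planes, and the fraction of each
#' joint space occupied by femoral cartilage.
#'
#' @param icd Intercondylar distance, mm.
#' @param ap_medial,ap_lateral Maximum A-P extents, mm.
#' @param js_medial,js_lateral Joint spaces, mm.
#' @param femoral_fraction_medial,femoral_fraction_lateral Fraction of the
#'   joint space occupied by femoral cartilage, strictly inside (0, 1).
#' @return An object of class `anatomic_measurements`.
#' @export
anatomic_measurements <- function(icd, ap_medial, ap_lateral,
                                  js_medial, js_lateral,
                                  femoral_fraction_medial,
                                  femoral_fraction_lateral) {
  lengths <- c(icd = icd, ap_medial = ap_medial, ap_lateral = ap_lateral,
               js_medial = js_medial, js_lateral = js_lateral)
  if (any(!is.finite(lengths) | lengths <= 0)) {
    stop("all anatomic lengths must be positive and finite")
  }
  fr <- c(femoral_fraction_medial, femoral_fraction_lateral)
  if (any(!is.finite(fr) | fr <= 0 | fr >= 1)) {
    stop("femoral fractions must lie strictly inside (0, 1)")
  }
  structure(list(icd = icd, ap_medial = ap_medial, ap_lateral = ap_lateral,
                 js_medial = js_medial, js_lateral = js_lateral,
                 femoral_fraction_medial = femoral_fraction_medial,
                 femoral_fraction_lateral = femoral_fraction_lateral),
            class = "anatomic_measurements")
}

#' Template geometry parameters
#'
#' Defaults place a median subject at a near-identity scaling: the template
#' carries the cohort-median measurements (ICD 40.6 mm, A-P 53.05/62.59 mm,
#' JS 4.79/5.38 mm, femoral fractions 0.55/0.40). The femoral condyle is an
#' elliptic paraboloid cap over a gently concave (medial) or flat (lateral)
#' tibial plateau; the lateral compartment is deliberately less congruent
#' (smaller condyle radii over a flatter plateau).
#'
#' @param compartment `"medial"` or `"lateral"`.
#' @return List of geometric parameters (mm): `icd`, `ap`, `width`, `js`,
#'   `femoral_fraction`, condyle radii `condyle_r_ap`/`condyle_r_ml`,
#'   tibial dish radii `tibial_r_ap`/`tibial_r_ml` (`Inf` = flat) and the
#'   nominal apex separation `gap_min`.
#' @export
template_defaults <- function(compartment = c("medial", "lateral")) {
  compartment <- match.arg(compartment)
  if (compartment == "medial") {
    list(compartment = "medial", icd = 40.6, ap = 53.05, width = 30,
         js = 4.79, femoral_fraction = 0.55,
         condyle_r_ap = 40, condyle_r_ml = 30,
         tibial_r_ap = 120, tibial_r_ml = 80, gap_min = 0.1)
  } else {
    list(compartment = "lateral", icd = 40.6, ap = 62.59, width = 30,
         js = 5.38, femoral_fraction = 0.40,
         condyle_r_ap = 32, condyle_r_ml = 24,
         tibial_r_ap = Inf, tibial_r_ml = Inf, gap_min = 0.1)
  }
}

# surface heights of the parametric template (y up; x anterior-posterior,
# z medial-lateral); apex of the joint at (0, 0)
.tibial_surface_y <- function(x, z, params) {
  x^2 / (2 * params$tibial_r_ap) + z^2 / (2 * params$tibial_r_ml)
}
.femoral_surface_y <- function(x, z, params) {
  params$gap_min + x^2 / (2 * params$condyle_r_ap) +
    z^2 / (2 * params$condyle_r_ml)
}

#' Build a layered hexahedral compartment template mesh
#'
#' Constructs the parametric template: femoral and tibial cartilage as
#' layered hexahedral grids over a common rectangular footprint. Femoral
#' cartilage extends upward (+Y) from the condyle articular surface, tibial
#' cartilage downward (-Y) from the plateau surface; thickness is measured
#' vertically. Axes: X anterior-posterior (anterior positive), Y axial
#' (loading direction), Z medial-lateral.
#'
#' @param compartment `"medial"` or `"lateral"`.
#' @param nx,nz In-plane element divisions (>= 4 each).
#' @param n_layers Element layers per tissue (>= 3).
#' @param params Geometry parameters, see [template_defaults()].
#' @param central_fraction Central-band fraction for the initial region
#'   labelling (see [partition_regions()]).
#' @return A `compartment_mesh`: nodes (N x 3, mm), `hexa` (M x 8, VTK
#'   corner order), per-element `tissue`, `layer` (0 = articular surface),
#'   `region` and footprint `cell`, the articular-surface node index grids,
#'   per-tissue `thickness`, and the template's `meas`urements.
#' @export
build_template <- function(compartment = c("medial", "lateral"),
                           nx = 16, nz = 10, n_layers = 4,
                           params = template_defaults(compartment),
                           central_fraction = 1 / 3) {
  compartment <- match.arg(compartment)
  if (nx < 4 || nz < 4 || n_layers < 3) {
    stop("degenerate resolution: need nx >= 4, nz >= 4, n_layers >= 3")
  }
  xg <- seq(-params$ap / 2, params$ap / 2, length.out = nx + 1)
  zg <- seq(-params$width / 2, params$width / 2, length.out = nz + 1)
  grid <- expand.grid(x = xg, z = zg, KEEP.OUT.ATTRS = FALSE) # x fastest
  t_f <- params$js * params$femoral_fraction
  t_t <- params$js * (1 - params$femoral_fraction)

  y_tib <- .tibial_surface_y(grid$x, grid$z, params)
  y_fem <- .femoral_surface_y(grid$x, grid$z, params)

  n_sheet <- (nx + 1) * (nz + 1)
  L <- n_layers
  sheet_fracs <- seq(0, 1, length.out = L + 1)

  # node block per tissue: sheets stacked from the articular surface
  fem_nodes <- do.call(rbind, lapply(sheet_fracs, function(f) {
    cbind(grid$x, y_fem + f * t_f, grid$z)
  }))
  tib_nodes <- do.call(rbind, lapply(sheet_fracs, function(f) {
    cbind(grid$x, y_tib - f * t_t, grid$z)
  }))
  nodes <- rbind(fem_nodes, tib_nodes)
  anchor_y <- c(rep(y_fem, L + 1), rep(y_tib, L + 1))
  node_tissue <- rep(c("femoral_cartilage", "tibial_cartilage"),
                     each = n_sheet * (L + 1))

  node_id <- function(tissue, sheet, ix, iz) {
    # ix, iz, sheet are 1-based; x runs fastest within a sheet
    base <- if (tissue == "fem") 0L else n_sheet * (L + 1)
    base + (sheet - 1L) * n_sheet + (iz - 1L) * (nx + 1L) + ix
  }

  ix <- rep(seq_len(nx), times = nz)
  iz <- rep(seq_len(nz), each = nx)
  cell <- (iz - 1L) * nx + ix # footprint cell id, 1..nx*nz

  quad <- function(tissue, sheet) {
    cbind(node_id(tissue, sheet, ix, iz),
          node_id(tissue, sheet, ix, iz + 1L),
          node_id(tissue, sheet, ix + 1L, iz + 1L),
          node_id(tissue, sheet, ix + 1L, iz))
  }

  hex_list <- vector("list", 2L * L)
  meta <- vector("list", 2L * L)
  k <- 0L
  for (il in seq_len(L)) { # femoral: bottom sheet = il (lower y)
    k <- k + 1L
    hex_list[[k]] <- cbind(quad("fem", il), quad("fem", il + 1L))
    meta[[k]] <- data.frame(tissue = "femoral_cartilage", layer = il - 1L,
                            cell = cell)
  }
  for (il in seq_len(L)) { # tibial: bottom sheet = il + 1 (lower y)
    k <- k + 1L
    hex_list[[k]] <- cbind(quad("tib", il + 1L), quad("tib", il))
    meta[[k]] <- data.frame(tissue = "tibial_cartilage", layer = il - 1L,
                            cell = cell)
  }
  hexa <- do.call(rbind, hex_list)
  storage.mode(hexa) <- "integer"
  meta <- do.call(rbind, meta)

  mesh <- structure(list(
    nodes = nodes,
    hexa = hexa,
    tissue = meta$tissue,
    layer = meta$layer,
    cell = meta$cell,
    region = rep(NA_character_, nrow(hexa)),
    compartment = compartment,
    nx = nx, nz = nz, n_layers = L,
    anchor_y = anchor_y,
    node_tissue = node_tissue,
    surf_fem = matrix(node_id("fem", 1L,
                              rep(seq_len(nx + 1L), nz + 1L),
                              rep(seq_len(nz + 1L), each = nx + 1L)),
                      nrow = nx + 1L),
    surf_tib = matrix(node_id("tib", 1L,
                              rep(seq_len(nx + 1L), nz + 1L),
                              rep(seq_len(nz + 1L), each = nx + 1L)),
                      nrow = nx + 1L),
    thickness = c(femoral = t_f, tibial = t_t),
    params = params,
    meas = list(icd = params$icd, ap = params$ap, js = params$js,
                femoral_fraction = params$femoral_fraction)
  ), class = "compartment_mesh")
  partition_regions(mesh, central_fraction)
}

#' @export
print.compartment_mesh <- function(x, ...) {
  cat(sprintf(
    "compartment_mesh: %s compartment, %d nodes, %d hexahedra\n",
    if (is.na(x$compartment)) "unlabelled" else x$compartment,
    nrow(x$nodes), nrow(x$hexa)))
  if (!is.null(x$thickness)) {
    cat(sprintf(
      "  thickness (mm): femoral %.4g, tibial %.4g; total volume %.4g mm^3\n",
      x$thickness["femoral"], x$thickness["tibial"],
      sum(element_volumes(x))))
  }
  invisible(x)
}

# signed 5-tetrahedron decomposition; exact for the planar-face triangulated
# polyhedron and linear in vertical thickness scaling
.TET5 <- matrix(c(1, 2, 3, 6,
                  1, 3, 8, 6,
                  1, 3, 4, 8,
                  1, 6, 8, 5,
                  3, 8, 6, 7), ncol = 4, byrow = TRUE)

#' Element volumes of a hexahedral mesh
#'
#' @param mesh A `compartment_mesh`.
#' @return Numeric vector of signed element volumes, mm^3 (positive for a
#'   valid mesh).
#' @export
element_volumes <- function(mesh) {
  nd <- mesh$nodes
  hx <- mesh$hexa
  vol <- numeric(nrow(hx))
  for (t in seq_len(nrow(.TET5))) {
    a <- nd[hx[, .TET5[t, 1]], , drop = FALSE]
    b <- nd[hx[, .TET5[t, 2]], , drop = FALSE]
    c_ <- nd[hx[, .TET5[t, 3]], , drop = FALSE]
    d <- nd[hx[, .TET5[t, 4]], , drop = FALSE]
    u <- b - a; v <- c_ - a; w <- d - a
    det <- u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
           u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
           u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
    vol <- vol + det / 6
  }
  vol
}

# local (i,j,k) coordinates of the 8 VTK hex corners
.HEX_IJK <- matrix(c(0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
                     0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1),
                   ncol = 3, byrow = TRUE)

#' Mesh quality summary
#'
#' Reports the aspect-ratio distribution (longest over shortest edge per
#' hexahedron), the mean edge length, and the minimum corner Jacobian over
#' all elements (positive = valid orientation everywhere).
#'
#' @param mesh A `compartment_mesh`.
#' @return List with `aspect_median`, `aspect_iqr` (25th/75th percentiles),
#'   `mean_edge_length`, `min_jacobian` and the per-element `aspect` vector.
#' @export
mesh_quality <- function(mesh) {
  nd <- mesh$nodes
  hx <- mesh$hexa
  edges <- matrix(c(1, 2, 2, 3, 3, 4, 4, 1,
                    5, 6, 6, 7, 7, 8, 8, 5,
                    1, 5, 2, 6, 3, 7, 4, 8), ncol = 2, byrow = TRUE)
  elen <- vapply(seq_len(nrow(edges)), function(e) {
    d <- nd[hx[, edges[e, 1]], , drop = FALSE] -
         nd[hx[, edges[e, 2]], , drop = FALSE]
    sqrt(rowSums(d^2))
  }, numeric(nrow(hx)))
  elen <- matrix(elen, nrow = nrow(hx))
  aspect <- apply(elen, 1, max) / apply(elen, 1, min)

  corner_idx <- function(i, j, k) {
    which(.HEX_IJK[, 1] == i & .HEX_IJK[, 2] == j & .HEX_IJK[, 3] == k)
  }
  minj <- Inf
  for (c0 in seq_len(8)) {
    ijk <- .HEX_IJK[c0, ]
    ni <- corner_idx(1 - ijk[1], ijk[2], ijk[3])
    nj <- corner_idx(ijk[1], 1 - ijk[2], ijk[3])
    nk <- corner_idx(ijk[1], ijk[2], 1 - ijk[3])
    si <- if (ijk[1] == 0) 1 else -1
    sj <- if (ijk[2] == 0) 1 else -1
    sk <- if (ijk[3] == 0) 1 else -1
    u <- (nd[hx[, ni], , drop = FALSE] - nd[hx[, c0], , drop = FALSE]) * si
    v <- (nd[hx[, nj], , drop = FALSE] - nd[hx[, c0], , drop = FALSE]) * sj
    w <- (nd[hx[, nk], , drop = FALSE] - nd[hx[, c0], , drop = FALSE]) * sk
    det <- u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
           u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
           u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
    minj <- min(minj, det)
  }
  list(aspect_median = median(aspect),
       aspect_iqr = unname(quantile(aspect, c(0.25, 0.75))),
       mean_edge_length = mean(elen),
       min_jacobian = minj,
       aspect = aspect)
}

#' Label anterior / central / posterior regions
#'
#' Elements whose centroid X lies within the central band of the tibial
#' plateau's anterior-posterior extent are labelled `central`; the band
#' covers `central_fraction` of the extent (default 1/3, mirroring the
#' MOAKS-style joint partition used for the degenerated-volume reference
#' region). Elements anterior (+X) of the band are `anterior`, the rest
#' `posterior`.
#'
#' @param mesh A `compartment_mesh`.
#' @param central_fraction Fraction of the A-P extent in the central band,
#'   in (0, 1].
#' @return The mesh with its per-element `region` labels replaced.
#' @export
partition_regions <- function(mesh, central_fraction = 1 / 3) {
  if (central_fraction <= 0 || central_fraction > 1) {
    stop("central_fraction must lie in (0, 1]")
  }
  xr <- range(mesh$nodes[, 1])
  mid <- mean(xr)
  half_band <- central_fraction * diff(xr) / 2
  cx <- rowMeans(matrix(mesh$nodes[mesh$hexa, 1], nrow = nrow(mesh$hexa)))
  mesh$region <- ifelse(abs(cx - mid) <= half_band + 1e-12, "central",
                        ifelse(cx > mid, "anterior", "posterior"))
  mesh$central_fraction <- central_fraction
  mesh
}

# Pick the compartment-specific scalars out of an anatomic_measurements
# object (or accept a pre-flattened list with ap/js/femoral_fraction).
.compartment_meas <- function(meas, compartment) {
  if (!is.null(meas$ap) && !is.null(meas$js)) {
    return(list(icd = meas$icd, ap = meas$ap, js = meas$js,
                femoral_fraction = meas$femoral_fraction))
  }
  suffix <- if (compartment == "medial") "medial" else "lateral"
  list(icd = meas$icd,
       ap = meas[[paste0("ap_", suffix)]],
       js = meas[[paste0("js_", suffix)]],
       femoral_fraction = meas[[paste0("femoral_fraction_", suffix)]])
}

#' Scale a template mesh to a subject's anatomy
#'
#' Applies the anatomic scaling of the template method: X coordinates scale
#' by the compartment A-P ratio, Z coordinates by the ICD ratio, and
#' cartilage thickness rescales so the subject's joint space is matched.
#' In `fixed_ratio` mode both cartilages scale by the joint-space ratio,
#' preserving the template's femoral-to-tibial thickness ratio; in
#' `scaled_ratio` mode the femoral thickness becomes
#' `js_subject * femoral_fraction_subject` and the tibial thickness
#' `js_subject * (1 - femoral_fraction_subject)`. Thickness offsets are
#' applied vertically from the articular-surface anchors, so connectivity,
#' labels and the articular gap are preserved and total volume transforms
#' exactly by `ap_ratio * ml_ratio * thickness_ratio` in `fixed_ratio`
#' mode.
#'
#' @param template A `compartment_mesh` built by [build_template()].
#' @param subject_meas [anatomic_measurements()] of the subject (or a list
#'   with `icd`, `ap`, `js`, `femoral_fraction`).
#' @param mode `"fixed_ratio"` or `"scaled_ratio"`.
#' @param template_meas Template measurements; defaults to the ones stored
#'   in the template.
#' @return The scaled `compartment_mesh` with updated measurements and
#'   thicknesses.
#' @export
scale_mesh <- function(template, subject_meas,
                       mode = c("fixed_ratio", "scaled_ratio"),
                       template_meas = template$meas) {
  mode <- match.arg(mode)
  if (is.null(template$anchor_y)) {
    stop("mesh lacks template column metadata; only meshes built by ",
         "build_template() can be rescaled")
  }
  sm <- .compartment_meas(subject_meas, template$compartment)
  tm <- .compartment_meas(template_meas, template$compartment)
  ap_ratio <- sm$ap / tm$ap
  ml_ratio <- sm$icd / tm$icd
  js_ratio <- sm$js / tm$js
  t_f <- template$thickness[["femoral"]]
  t_t <- template$thickness[["tibial"]]
  if (mode == "fixed_ratio") {
    t_f_new <- t_f * js_ratio
    t_t_new <- t_t * js_ratio
    ff_new <- tm$femoral_fraction
  } else {
    t_f_new <- sm$js * sm$femoral_fraction
    t_t_new <- sm$js * (1 - sm$femoral_fraction)
    ff_new <- sm$femoral_fraction
  }
  if (t_f_new <= 0 || t_t_new <= 0) {
    stop("scaling produced a non-positive cartilage thickness")
  }
  mesh <- template
  mesh$nodes[, 1] <- mesh$nodes[, 1] * ap_ratio
  mesh$nodes[, 3] <- mesh$nodes[, 3] * ml_ratio
  ratio_by_tissue <- ifelse(mesh$node_tissue == "femoral_cartilage",
                            t_f_new / t_f, t_t_new / t_t)
  mesh$nodes[, 2] <- mesh$anchor_y +
    (mesh$nodes[, 2] - mesh$anchor_y) * ratio_by_tissue
  mesh$thickness <- c(femoral = t_f_new, tibial = t_t_new)
  mesh$meas <- list(icd = sm$icd, ap = sm$ap, js = t_f_new + t_t_new,
                    femoral_fraction = ff_new)
  mesh$scaling <- list(mode = mode, ap_ratio = ap_ratio, ml_ratio = ml_ratio,
                       js_ratio = js_ratio)
  # region band boundaries move with the A-P scaling automatically
  partition_regions(mesh, mesh$central_fraction)
}
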