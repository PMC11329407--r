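#' Export a FEBio-dialect solver deck
#'
#' Writes an XML solver deck in a FEBio 3-style dialect carrying the hex
#' mesh, both tissues' full fibril-reinforced biphasic constants
#' (including the permeability constants `kappa0`, `M_perm` and the solid
#' fraction `phi0`, which the in-package instantaneous surrogate does not
#' use), the fixed bottom-of-tibia boundary condition, and the stance
#' load/flexion curves. Intended as a bridge for users who want to rerun
#' a model in a full-fidelity biphasic sliding-elastic contact solver
#' outside this package; the file is well-formed, re-parseable XML, not a
#' guaranteed turnkey solver input.
#'
#' @param mesh A `compartment_mesh`.
#' @param loading A `gait_loading`.
#' @param props Material set, see [default_props()].
#' @param path Output file path (`.feb`).
#' @return `path`, invisibly.
#' @export
export_solver_deck <- function(mesh, loading, props = default_props(),
                               path) {
  doc <- xml2::xml_new_root("febio_spec", version = "3.0")
  xml2::xml_add_child(doc, "Module", type = "biphasic")

  mat <- xml2::xml_add_child(doc, "Material")
  add_material <- function(id, name, p) {
    node <- xml2::xml_add_child(mat, "material", id = as.character(id),
                                name = name,
                                type = "biphasic fibril-reinforced")
    fields <- c(xi_fp = p$xi_fp, beta_fp = p$beta_fp, xi_fs = p$xi_fs,
                beta_fs = p$beta_fs, E_nf = p$E_nf, nu_nf = p$nu_nf,
                kappa0 = p$kappa0, M = p$M_perm, phi0 = p$phi0)
    for (nm in names(fields)) {
      xml2::xml_add_child(node, nm, format(fields[[nm]], digits = 15))
    }
  }
  add_material(1, "femoral_cartilage", props$femur)
  add_material(2, "tibial_cartilage", props$tibia)

  geo <- xml2::xml_add_child(doc, "Mesh")
  nodes_el <- xml2::xml_add_child(geo, "Nodes", name = "all")
  node_text <- apply(mesh$nodes, 1, function(v) {
    paste(format(v, digits = 15, trim = TRUE), collapse = ",")
  })
  for (i in seq_len(nrow(mesh$nodes))) {
    xml2::xml_add_child(nodes_el, "node", node_text[i],
                        id = as.character(i))
  }
  for (tis in c("femoral_cartilage", "tibial_cartilage")) {
    sel <- which(mesh$tissue == tis)
    el_block <- xml2::xml_add_child(geo, "Elements", type = "hex8",
                                    name = tis,
                                    mat = if (tis == "femoral_cartilage")
                                      "1" else "2")
    for (i in sel) {
      xml2::xml_add_child(el_block, "elem",
                          paste(mesh$hexa[i, ], collapse = ","),
                          id = as.character(i))
    }
  }

  bc <- xml2::xml_add_child(doc, "Boundary")
  xml2::xml_add_child(bc, "bc", type = "fix", node_set = "tibial_base",
                      dofs = "x,y,z")

  loads <- xml2::xml_add_child(doc, "LoadData")
  add_curve <- function(id, name, x, y) {
    lc <- xml2::xml_add_child(loads, "load_controller",
                              id = as.character(id), name = name,
                              type = "loadcurve")
    pts <- xml2::xml_add_child(lc, "points")
    for (i in seq_along(x)) {
      xml2::xml_add_child(pts, "point",
                          paste(format(c(x[i], y[i]), digits = 15,
                                       trim = TRUE), collapse = ","))
    }
  }
  force <- if (mesh$compartment == "medial") loading$force_medial
           else loading$force_lateral
  add_curve(1, "axial_jcf", loading$stance_percent, force)
  add_curve(2, "flexion_deg", loading$stance_percent, loading$flexion_deg)

  xml2::write_xml(doc, path)
  invisible(path)
}
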