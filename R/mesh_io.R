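#' Mesh input/output
#'
#' Legacy ASCII VTK unstructured-grid export/import (hexahedra with
#' tissue/layer/region cell labels) and a minimal Abaqus INP reader
#' (`*NODE`, `*ELEMENT, TYPE=C3D8`, `*ELSET`). Coordinates are mm.
#' Meshes read from disk carry geometry and labels but not the template
#' column metadata, so they support quality/volume/region queries but not
#' [scale_mesh()].
#'
#' @name mesh_io
NULL

.VTK_HEX <- 12L

#' Write a compartment mesh as a legacy VTK unstructured grid
#'
#' @param mesh A `compartment_mesh`.
#' @param path Output file path (`.vtk`).
#' @param cell_data Optional named list of additional numeric per-element
#'   vectors written as CELL_DATA scalars (e.g. a stress envelope).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$hexa)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("kneedegen %s compartment mesh", mesh$compartment),
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(format(mesh$nodes, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", m, 9L * m), con)
  writeLines(apply(cbind(8L, mesh$hexa - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(.VTK_HEX, m)), con)

  tissue_code <- as.integer(factor(mesh$tissue,
                                   c("femoral_cartilage", "tibial_cartilage")))
  region_code <- as.integer(factor(mesh$region,
                                   c("anterior", "central", "posterior")))
  scalars <- c(list(tissue = tissue_code, layer = mesh$layer,
                    region = region_code, cell = mesh$cell), cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(scalars[[nm]], digits = 17, trim = TRUE,
                      scientific = FALSE), con)
  }
  invisible(path)
}

#' Read a legacy VTK unstructured grid of hexahedra
#'
#' @param path VTK file path.
#' @return A `compartment_mesh`-like object (no template metadata).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("not a legacy VTK unstructured grid: no POINTS block")
  n <- as.integer(toks(lines[ip])[2])
  pts <- as.numeric(unlist(lapply(lines[(ip + 1):(ip + n)], toks)))
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(toks(lines[ic])[2])
  cells <- lapply(lines[(ic + 1):(ic + m)], function(s) as.integer(toks(s)))
  if (any(vapply(cells, `[`, integer(1), 1) != 8L)) {
    stop("only 8-node hexahedral cells are supported")
  }
  hexa <- do.call(rbind, lapply(cells, function(v) v[-1] + 1L))
  it <- grep("^CELL_TYPES", lines)[1]
  types <- as.integer(unlist(lapply(lines[(it + 1):(it + m)], toks)))
  if (any(types != .VTK_HEX)) stop("non-hexahedral VTK cell types found")

  scalars <- list()
  is_sc <- grep("^SCALARS", lines)
  for (i in is_sc) {
    nm <- toks(lines[i])[2]
    vals <- as.numeric(unlist(lapply(lines[(i + 2):(i + 1 + m)], toks)))
    scalars[[nm]] <- vals
  }
  tissue <- if (!is.null(scalars$tissue)) {
    c("femoral_cartilage", "tibial_cartilage")[as.integer(scalars$tissue)]
  } else rep(NA_character_, m)
  region <- if (!is.null(scalars$region)) {
    c("anterior", "central", "posterior")[as.integer(scalars$region)]
  } else rep(NA_character_, m)
  structure(list(nodes = nodes, hexa = hexa, tissue = tissue,
                 layer = if (!is.null(scalars$layer))
                   as.integer(scalars$layer) else rep(NA_integer_, m),
                 cell = if (!is.null(scalars$cell))
                   as.integer(scalars$cell) else rep(NA_integer_, m),
                 region = region, compartment = NA_character_,
                 extra_cell_data = scalars[setdiff(names(scalars),
                   c("tissue", "layer", "region", "cell"))]),
            class = "compartment_mesh")
}

#' Read an Abaqus INP hexahedral mesh
#'
#' Minimal reader for `*NODE`, `*ELEMENT, TYPE=C3D8` (one element per line)
#' and `*ELSET` blocks; element sets named like `FEMORAL*`/`TIBIAL*` set
#' the tissue label.
#'
#' @param path INP file path.
#' @return A `compartment_mesh`-like object (no template metadata).
#' @export
read_inp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\*\\*", lines)] # comments
  upper <- toupper(lines)
  nodes <- NULL
  elems <- NULL
  elem_ids <- integer()
  elsets <- list()
  i <- 1
  while (i <= length(lines)) {
    line <- upper[i]
    if (startsWith(line, "*NODE")) {
      j <- i + 1
      rows <- list()
      while (j <= length(lines) && !startsWith(upper[j], "*")) {
        v <- as.numeric(strsplit(lines[j], ",")[[1]])
        rows[[length(rows) + 1]] <- v
        j <- j + 1
      }
      tb <- do.call(rbind, rows)
      nodes <- tb[order(tb[, 1]), 2:4, drop = FALSE]
      i <- j
    } else if (startsWith(line, "*ELEMENT")) {
      if (!grepl("TYPE\\s*=\\s*C3D8", line)) {
        stop("only C3D8 element blocks are supported")
      }
      j <- i + 1
      rows <- list()
      while (j <= length(lines) && !startsWith(upper[j], "*")) {
        v <- as.integer(strsplit(lines[j], ",")[[1]])
        rows[[length(rows) + 1]] <- v
        j <- j + 1
      }
      tb <- do.call(rbind, rows)
      elem_ids <- c(elem_ids, tb[, 1])
      elems <- rbind(elems, tb[, 2:9, drop = FALSE])
      i <- j
    } else if (startsWith(line, "*ELSET")) {
      nm <- sub(".*ELSET\\s*=\\s*([^,]+).*", "\\1", line)
      j <- i + 1
      ids <- integer()
      while (j <= length(lines) && !startsWith(upper[j], "*")) {
        ids <- c(ids, as.integer(strsplit(lines[j], ",")[[1]]))
        j <- j + 1
      }
      elsets[[nm]] <- ids[!is.na(ids)]
      i <- j
    } else {
      i <- i + 1
    }
  }
  if (is.null(nodes) || is.null(elems)) {
    stop("INP file must contain *NODE and *ELEMENT blocks")
  }
  m <- nrow(elems)
  tissue <- rep(NA_character_, m)
  for (nm in names(elsets)) {
    idx <- match(elsets[[nm]], elem_ids)
    if (grepl("^FEMORAL", nm)) tissue[idx] <- "femoral_cartilage"
    if (grepl("^TIBIAL", nm)) tissue[idx] <- "tibial_cartilage"
  }
  structure(list(nodes = nodes, hexa = elems, tissue = tissue,
                 layer = rep(NA_integer_, m), cell = rep(NA_integer_, m),
                 region = rep(NA_character_, m),
                 compartment = NA_character_, elsets = elsets),
            class = "compartment_mesh")
}
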