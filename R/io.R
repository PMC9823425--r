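# Plain-text interchange: Gmsh (MSH 2.2 ASCII) meshes, legacy-VTK volume
# export of cell data, and columnar S-parameter tables.

#' Export a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Writes the node block and the tetrahedral element block (element type 4).
#'
#' @param mesh a `tet_mesh`.
#' @param path output file path.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
             con)
  writeLines(c("$EndNodes", "$Elements",
               as.character(nrow(mesh$tets))), con)
  writeLines(sprintf("%d 4 2 0 1 %d %d %d %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1L], mesh$tets[, 2L], mesh$tets[, 3L],
                     mesh$tets[, 4L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Import a tetrahedral mesh from Gmsh MSH 2.2 ASCII
#'
#' Reads nodes and type-4 (tetrahedral) elements, re-orients cells to
#' positive volume and enumerates edges and boundary faces.
#'
#' @param path input file path.
#' @return a `tet_mesh`.
#' @export
read_msh <- function(path) {
  ln <- readLines(path)
  i_nodes <- which(ln == "$Nodes")
  i_elems <- which(ln == "$Elements")
  if (!length(i_nodes) || !length(i_elems)) stop("not an MSH 2.2 file")
  n_nodes <- as.integer(ln[i_nodes + 1L])
  nd <- read.table(text = ln[(i_nodes + 2L):(i_nodes + 1L + n_nodes)])
  nodes <- as.matrix(nd[order(nd[[1L]]), 2:4])
  dimnames(nodes) <- NULL
  n_el <- as.integer(ln[i_elems + 1L])
  el_lines <- ln[(i_elems + 2L):(i_elems + 1L + n_el)]
  parts <- strsplit(el_lines, " +")
  tets <- do.call(rbind, lapply(parts, function(p) {
    p <- as.integer(p)
    if (p[2L] != 4L) return(NULL)
    ntags <- p[3L]
    p[(4L + ntags):(7L + ntags)]
  }))
  if (is.null(tets) || nrow(tets) == 0L) {
    stop("no tetrahedral elements in file")
  }
  mesh <- structure(list(nodes = nodes, tets = tets, grid = NULL),
                    class = "tet_mesh")
  mesh <- .orient_tets(mesh)
  mesh <- enumerate_edges(mesh)
  .find_boundary_faces(mesh)
}

#' Export per-cell dielectric maps as a legacy VTK unstructured grid
#'
#' ASCII legacy-VTK file with the tetrahedral grid and CELL_DATA scalars
#' (relative permittivity and conductivity), readable by standard volume
#' viewers.
#'
#' @param mesh a `tet_mesh`.
#' @param eps_r,sigma per-cell values.
#' @param path output file path.
#' @param title dataset title line.
#' @export
write_vtk_cells <- function(mesh, eps_r, sigma, path,
                            title = "csifem reconstruction") {
  I <- nrow(mesh$tets)
  stopifnot(length(eps_r) == I, length(sigma) == I)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1L],
                     mesh$nodes[, 2L], mesh$nodes[, 3L]), con)
  writeLines(sprintf("CELLS %d %d", I, 5L * I), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1L] - 1L,
                     mesh$tets[, 2L] - 1L, mesh$tets[, 3L] - 1L,
                     mesh$tets[, 4L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", I), con)
  writeLines(rep("10", I), con)
  writeLines(c(sprintf("CELL_DATA %d", I),
               "SCALARS eps_r double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.10g", eps_r), con)
  writeLines(c("SCALARS sigma double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.10g", sigma), con)
  invisible(path)
}

#' Write / read S-parameter matrices as a columnar text table
#'
#' Long format with columns `receiver`, `transmitter`, `re`, `im`
#' (transmitter = column of the matrix), tab-separated.
#'
#' @param s T x T complex matrix.
#' @param path file path.
#' @export
write_sparams <- function(s, path) {
  Tn <- nrow(s)
  df <- data.frame(receiver = rep(seq_len(Tn), times = Tn),
                   transmitter = rep(seq_len(Tn), each = Tn),
                   re = as.vector(Re(s)), im = as.vector(Im(s)))
  utils::write.table(format(df, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sparams
#' @export
read_sparams <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  Tn <- max(df$receiver)
  s <- matrix(0 + 0i, Tn, Tn)
  s[cbind(df$receiver, df$transmitter)] <- complex(real = df$re,
                                                   imaginary = df$im)
  s
}

#' Write a per-iteration convergence log
#'
#' Columnar text file with `n`, `FS`, `FD`, `FCSI` (and any extra history
#' columns).
#'
#' @param history a `csi_result` or its history data.frame.
#' @param path file path.
#' @export
write_convergence_log <- function(history, path) {
  if (inherits(history, "csi_result")) history <- history$history
  utils::write.table(format(history, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
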