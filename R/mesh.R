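# Tetrahedral meshes with global edge enumeration for lowest-order
# curl-conforming (Whitney/Nedelec first-kind) elements.
#
# Conventions used throughout the package:
#  * node coordinates in metres;
#  * every tetrahedron is stored with positive signed volume;
#  * a global edge is the unordered node pair stored as (low node, high node),
#    and the edge basis function is oriented low -> high;
#  * the six local edges of a tetrahedron follow the canonical local vertex
#    pairs (1,2), (1,3), (1,4), (2,3), (2,4), (3,4).

.local_edge_pairs <- rbind(
  c(1L, 2L), c(1L, 3L), c(1L, 4L),
  c(2L, 3L), c(2L, 4L), c(3L, 4L)
)

#' Build a structured tetrahedral mesh of a box
#'
#' Discretizes an axis-aligned box, centred at the origin, into hexahedral
#' cells that are each split into six tetrahedra by the Kuhn subdivision
#' (all six tetrahedra share the main diagonal of the cell, which makes the
#' triangulation conforming across cell faces).  The construction is fully
#' deterministic.
#'
#' @param extent numeric length-3, box side lengths in metres.
#' @param h target edge length in metres; each axis is divided into
#'   `round(extent / h)` cells (at least one), so the box is covered exactly.
#' @return an object of class `tet_mesh` with nodes, tetrahedra, global edge
#'   tables, edge-tetrahedron incidence, boundary faces, barycenters and
#'   volumes.  See [enumerate_edges()] for the edge tables.
#' @examples
#' m <- build_box_mesh(c(0.1, 0.1, 0.1), 0.05)
#' sum(m$volumes)  # = 1e-3, the box volume
#' @export
build_box_mesh <- function(extent, h) {
  stopifnot(length(extent) == 3, all(extent > 0), length(h) == 1, h > 0)
  if (h > min(extent)) stop("h must not exceed the smallest box extent")
  n <- as.integer(round(extent / h))
  if (any(n < 1L)) stop("extent/h yields zero cells along at least one axis")
  hs <- extent / n                      # realized (per-axis) cell size
  origin <- -extent / 2

  nx <- n[1L]; ny <- n[2L]; nz <- n[3L]
  npx <- nx + 1L; npy <- ny + 1L; npz <- nz + 1L

  # nodes on the regular grid, x fastest
  gx <- origin[1L] + hs[1L] * (0:nx)
  gy <- origin[2L] + hs[2L] * (0:ny)
  gz <- origin[3L] + hs[3L] * (0:nz)
  nodes <- cbind(
    rep(gx, times = npy * npz),
    rep(rep(gy, each = npx), times = npz),
    rep(gz, each = npx * npy)
  )

  node_id <- function(ix, iy, iz) 1L + ix + npx * (iy + npy * iz)

  # hexahedral cells, x fastest
  hx <- rep(0:(nx - 1L), times = ny * nz)
  hy <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  hz <- rep(0:(nz - 1L), each = nx * ny)
  corner <- function(dx, dy, dz) node_id(hx + dx, hy + dy, hz + dz)

  # Kuhn split: one tet per permutation of the axes, all sharing the main
  # diagonal c(0,0,0) -> c(1,1,1)
  perms <- rbind(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
  ex <- diag(3L)
  tet_blocks <- vector("list", 6L)
  for (j in 1:6) {
    s <- perms[j, ]
    d1 <- ex[s[1L], ]
    d2 <- ex[s[1L], ] + ex[s[2L], ]
    tet_blocks[[j]] <- cbind(
      corner(0L, 0L, 0L),
      corner(d1[1L], d1[2L], d1[3L]),
      corner(d2[1L], d2[2L], d2[3L]),
      corner(1L, 1L, 1L)
    )
  }
  tets <- do.call(rbind, tet_blocks)

  mesh <- structure(
    list(nodes = nodes, tets = tets,
         grid = list(n = n, h = hs, origin = origin,
                     n_hex = nx * ny * nz)),
    class = "tet_mesh"
  )
  mesh <- .orient_tets(mesh)
  mesh <- enumerate_edges(mesh)
  mesh <- .find_boundary_faces(mesh)
  mesh
}

# ensure positive signed volume by swapping the last two vertices where needed
.orient_tets <- function(mesh) {
  v <- .tet_signed_volumes(mesh$nodes, mesh$tets)
  flip <- v < 0
  if (any(flip)) {
    tmp <- mesh$tets[flip, 3L]
    mesh$tets[flip, 3L] <- mesh$tets[flip, 4L]
    mesh$tets[flip, 4L] <- tmp
    v[flip] <- -v[flip]
  }
  if (any(v <= 0)) {
    stop("degenerate (zero-volume) tetrahedron at index ",
         which(v <= 0)[1L])
  }
  mesh$volumes <- v
  p1 <- mesh$nodes[mesh$tets[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tets[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tets[, 3L], , drop = FALSE]
  p4 <- mesh$nodes[mesh$tets[, 4L], , drop = FALSE]
  mesh$barycenters <- (p1 + p2 + p3 + p4) / 4
  mesh
}

.tet_signed_volumes <- function(nodes, tets) {
  u <- nodes[tets[, 2L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  v <- nodes[tets[, 3L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  w <- nodes[tets[, 4L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  (u[, 1L] * (v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]) +
   u[, 2L] * (v[, 3L] * w[, 1L] - v[, 1L] * w[, 3L]) +
   u[, 3L] * (v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L])) / 6
}

#' Enumerate the global edges of a tetrahedral mesh
#'
#' Fills the edge tables of a `tet_mesh`: the unique global edges (stored with
#' the lower node index first), the per-tetrahedron local-to-global edge map
#' with orientation signs, and the edge-tetrahedron incidence in compressed
#' form (for edge `e`, the tetrahedra sharing it are
#' `edge_tets[edge_tet_ptr[e]:(edge_tet_ptr[e+1]-1)]`).
#'
#' @param mesh a `tet_mesh` with `nodes` and `tets` populated.
#' @return the mesh with fields `edges` (E x 2), `tet_edges` (I x 6 global
#'   edge ids), `tet_edge_sign` (I x 6, +1 when the canonical local pair is
#'   already low -> high), `edge_tet_ptr` and `edge_tets`.
#' @export
enumerate_edges <- function(mesh) {
  tets <- mesh$tets
  I <- nrow(tets)
  nn <- nrow(mesh$nodes)
  lp <- .local_edge_pairs
  p <- tets[, lp[, 1L]]                      # I x 6 matrices
  q <- tets[, lp[, 2L]]
  a <- pmin(p, q)
  b <- pmax(p, q)
  key <- as.numeric(a - 1L) * nn + as.numeric(b)   # exact in doubles
  ukey <- sort(unique(as.vector(key)))
  eid <- matrix(match(key, ukey), nrow = I)
  mesh$edges <- cbind(as.integer((ukey - 1) %/% nn) + 1L,
                      as.integer((ukey - 1) %% nn) + 1L)
  mesh$tet_edges <- eid
  mesh$tet_edge_sign <- matrix(ifelse(p < q, 1L, -1L), nrow = I)

  # incidence alpha(e, q): tets sharing each edge, in CSR-like layout
  ord <- order(as.vector(eid))
  mesh$edge_tets <- rep.int(seq_len(I), 6L)[ord]
  cnt <- tabulate(as.vector(eid), nbins = nrow(mesh$edges))
  mesh$edge_tet_ptr <- c(1L, cumsum(cnt) + 1L)
  mesh
}

# boundary faces: faces belonging to exactly one tetrahedron
.find_boundary_faces <- function(mesh) {
  tets <- mesh$tets
  I <- nrow(tets)
  nn <- as.numeric(nrow(mesh$nodes))
  # local faces opposite vertices 1..4
  opp <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  fnodes <- rbind(tets[, opp[1L, ]], tets[, opp[2L, ]],
                  tets[, opp[3L, ]], tets[, opp[4L, ]])
  lo <- pmin(fnodes[, 1L], fnodes[, 2L], fnodes[, 3L])
  hi <- pmax(fnodes[, 1L], fnodes[, 2L], fnodes[, 3L])
  md <- fnodes[, 1L] + fnodes[, 2L] + fnodes[, 3L] - lo - hi
  key <- (as.numeric(lo) - 1) * nn * nn + (as.numeric(md) - 1) * nn +
         as.numeric(hi)
  dupe <- key %in% key[duplicated(key)]
  bnd <- which(!dupe)
  mesh$boundary_faces <- fnodes[bnd, , drop = FALSE]
  mesh$boundary_face_tet <- ((bnd - 1L) %% I) + 1L
  mesh$boundary_face_opp <- ((bnd - 1L) %/% I) + 1L
  mesh
}

# Gradients of the four barycentric functions of every tetrahedron.
# Returns a list g[[p]] (I x 3) with sum_p g[[p]] = 0 and
# g[[p]] . (r_q - r_p) = delta_{pq} - ... (standard affine coordinates).
.tet_lambda_gradients <- function(mesh) {
  nd <- mesh$nodes; tt <- mesh$tets
  r1 <- nd[tt[, 1L], , drop = FALSE]
  u <- nd[tt[, 2L], , drop = FALSE] - r1
  v <- nd[tt[, 3L], , drop = FALSE] - r1
  w <- nd[tt[, 4L], , drop = FALSE] - r1
  det6v <- 6 * mesh$volumes
  cross_rows <- function(x, y) {
    cbind(x[, 2L] * y[, 3L] - x[, 3L] * y[, 2L],
          x[, 3L] * y[, 1L] - x[, 1L] * y[, 3L],
          x[, 1L] * y[, 2L] - x[, 2L] * y[, 1L])
  }
  g2 <- cross_rows(v, w) / det6v
  g3 <- cross_rows(w, u) / det6v
  g4 <- cross_rows(u, v) / det6v
  g1 <- -(g2 + g3 + g4)
  list(g1, g2, g3, g4)
}

# Per-tet oriented local edge vertex pairs: pa, pb (I x 6 local vertex
# indices) such that the global edge basis function on local edge k is
# lambda_pa grad(lambda_pb) - lambda_pb grad(lambda_pa).
.oriented_local_pairs <- function(mesh) {
  lp <- .local_edge_pairs
  I <- nrow(mesh$tets)
  p <- matrix(rep(lp[, 1L], each = I), nrow = I)
  q <- matrix(rep(lp[, 2L], each = I), nrow = I)
  pos <- mesh$tet_edge_sign > 0L
  list(pa = ifelse(pos, p, q), pb = ifelse(pos, q, p))
}

#' Barycentric coordinates of a point in a tetrahedron
#'
#' @param mesh a `tet_mesh`.
#' @param tet_index tetrahedron index.
#' @param point numeric length-3 position (metres).
#' @return numeric length-4 barycentric coordinates (sum to 1).
#' @export
barycentric_coords <- function(mesh, tet_index, point) {
  vid <- mesh$tets[tet_index, ]
  A <- rbind(1, t(mesh$nodes[vid, , drop = FALSE]))
  as.vector(solve(A, c(1, point)))
}

#' Evaluate a Whitney edge basis function
#'
#' Evaluates the lowest-order curl-conforming basis function of one local edge
#' of a tetrahedron at a point inside it.  The function has unit circulation
#' along its own (globally oriented) edge and zero tangential component along
#' the other five edges.
#'
#' @param mesh a `tet_mesh` with edges enumerated.
#' @param tet_index tetrahedron index.
#' @param local_edge local edge index in 1..6.
#' @param point numeric length-3 position inside the tetrahedron.
#' @return numeric length-3 vector value of the basis function.
#' @export
eval_whitney <- function(mesh, tet_index, local_edge, point) {
  lam <- barycentric_coords(mesh, tet_index, point)
  if (any(lam < -1e-9) || any(lam > 1 + 1e-9)) {
    stop("point lies outside tetrahedron ", tet_index)
  }
  g <- .single_tet_gradients(mesh, tet_index)
  lp <- .local_edge_pairs[local_edge, ]
  if (mesh$tet_edge_sign[tet_index, local_edge] > 0L) {
    a <- lp[1L]; b <- lp[2L]
  } else {
    a <- lp[2L]; b <- lp[1L]
  }
  lam[a] * g[b, ] - lam[b] * g[a, ]
}

.single_tet_gradients <- function(mesh, tet_index) {
  vid <- mesh$tets[tet_index, ]
  r1 <- mesh$nodes[vid[1L], ]
  u <- mesh$nodes[vid[2L], ] - r1
  v <- mesh$nodes[vid[3L], ] - r1
  w <- mesh$nodes[vid[4L], ] - r1
  det6v <- 6 * mesh$volumes[tet_index]
  cr <- function(x, y) c(x[2L] * y[3L] - x[3L] * y[2L],
                         x[3L] * y[1L] - x[1L] * y[3L],
                         x[1L] * y[2L] - x[2L] * y[1L])
  g2 <- cr(v, w) / det6v
  g3 <- cr(w, u) / det6v
  g4 <- cr(u, v) / det6v
  rbind(-(g2 + g3 + g4), g2, g3, g4)
}

#' Locate the tetrahedron containing a point
#'
#' Uses the structured-grid index for meshes built by [build_box_mesh()] and
#' a nearest-barycenter search otherwise.
#'
#' @param mesh a `tet_mesh`.
#' @param point numeric length-3 position.
#' @param tol barycentric tolerance for the inside test.
#' @return the tetrahedron index, or an error if the point is outside the mesh.
#' @export
locate_point <- function(mesh, point, tol = 1e-10) {
  if (!is.null(mesh$grid)) {
    g <- mesh$grid
    idx <- pmin(pmax(floor((point - g$origin) / g$h), 0), g$n - 1L)
    hexid <- 1 + idx[1L] + g$n[1L] * (idx[2L] + g$n[2L] * idx[3L])
    cand <- hexid + g$n_hex * (0:5)
  } else {
    d2 <- (mesh$barycenters[, 1L] - point[1L])^2 +
          (mesh$barycenters[, 2L] - point[2L])^2 +
          (mesh$barycenters[, 3L] - point[3L])^2
    cand <- order(d2)[seq_len(min(64L, nrow(mesh$tets)))]
  }
  for (ti in cand) {
    lam <- barycentric_coords(mesh, ti, point)
    if (all(lam >= -tol)) return(as.integer(ti))
  }
  stop("point (", paste(signif(point, 6), collapse = ", "),
       ") not inside the mesh")
}

#' Evaluate an edge-coefficient field at points
#'
#' Interpolates a field given by its `E` complex edge coefficients at one or
#' more points, by summing the six Whitney functions of each containing
#' tetrahedron.
#'
#' @param mesh a `tet_mesh`.
#' @param coeffs complex vector of length `nrow(mesh$edges)`.
#' @param points numeric matrix (n x 3) or length-3 vector.
#' @param tets optional pre-located containing tetrahedra.
#' @return complex matrix (n x 3) of field values.
#' @export
eval_field <- function(mesh, coeffs, points, tets = NULL) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  n <- nrow(points)
  out <- matrix(0i, n, 3L)
  for (k in seq_len(n)) {
    ti <- if (is.null(tets)) locate_point(mesh, points[k, ]) else tets[k]
    lam <- barycentric_coords(mesh, ti, points[k, ])
    g <- .single_tet_gradients(mesh, ti)
    for (le in 1:6) {
      lp <- .local_edge_pairs[le, ]
      if (mesh$tet_edge_sign[ti, le] > 0L) {
        a <- lp[1L]; b <- lp[2L]
      } else {
        a <- lp[2L]; b <- lp[1L]
      }
      w <- lam[a] * g[b, ] - lam[b] * g[a, ]
      out[k, ] <- out[k, ] + coeffs[mesh$tet_edges[ti, le]] * w
    }
  }
  out
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets,",
      nrow(x$edges), "edges,", nrow(x$boundary_faces), "boundary faces\n")
  bb <- apply(x$nodes, 2L, range)
  cat(sprintf("  bounding box [%g, %g] x [%g, %g] x [%g, %g] m\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}
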