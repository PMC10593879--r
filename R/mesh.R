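#' Triangulated cortical surface mesh
#'
#' A `surface_mesh` holds a closed triangulation together with the spherical
#' registration coordinates used by spin permutations, a medial-wall mask
#' (vertices that carry no cortical signal and are treated as `NaN` in every
#' vertex map) and a per-vertex hemisphere label.
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates (mm).
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @param sphere numeric V x 3 matrix of coordinates on the registration
#'   sphere; must have (near-)constant radius.
#' @param medial_wall logical vector of length V; `TRUE` marks medial-wall
#'   vertices.
#' @param hemisphere character vector of length V ("left"/"right").
#'
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces`, `sphere`, `medial_wall`, `hemisphere`.
#' @export
surface_mesh <- function(vertices, faces, sphere = vertices,
                         medial_wall = rep(FALSE, nrow(vertices)),
                         hemisphere = rep("left", nrow(vertices))) {
  vertices <- as.matrix(vertices)
  sphere <- as.matrix(sphere)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  v <- nrow(vertices)
  stopifnot(ncol(vertices) == 3L, ncol(sphere) == 3L, nrow(sphere) == v,
            length(medial_wall) == v, length(hemisphere) == v)
  if (min(faces) < 1L || max(faces) > v)
    stop("faces index vertices outside 1..V")
  rad <- sqrt(rowSums(sphere^2))
  if (diff(range(rad)) > 1e-6 * mean(rad))
    stop("sphere coordinates do not have constant radius")
  if (!all(tabulate(faces, v) > 0L))
    stop("every vertex must belong to at least one face")
  structure(list(vertices = vertices, faces = faces, sphere = sphere,
                 medial_wall = as.logical(medial_wall),
                 hemisphere = as.character(hemisphere),
                 cache = new.env(parent = emptyenv())),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %d medial-wall vertices\n",
              nrow(x$vertices), nrow(x$faces), sum(x$medial_wall)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Icosphere mesh generator
#'
#' Builds a closed geodesic sphere by iterated midpoint subdivision of a
#' regular icosahedron, giving `10 * 4^subdivisions + 2` vertices. The
#' spherical registration coordinates equal the vertex positions, so the
#' mesh can stand in for a registered cortical hemisphere in simulations.
#' A contiguous polar cap can be flagged as a synthetic medial wall.
#'
#' @param subdivisions non-negative integer; 0 gives the icosahedron.
#' @param radius sphere radius in mm.
#' @param medial_wall_frac fraction of vertices (around the -z pole) flagged
#'   as medial wall; 0 disables the mask.
#' @return A [surface_mesh].
#' @examples
#' m <- make_sphere_mesh(2)
#' nrow(m$vertices)  # 162
#' @export
make_sphere_mesh <- function(subdivisions, radius = 100,
                             medial_wall_frac = 0.05) {
  stopifnot(subdivisions >= 0, radius > 0,
            medial_wall_frac >= 0, medial_wall_frac < 1)
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(verts)
    edge_key <- function(a, b) pmin(a, b) * (nv + 1L) + pmax(a, b)
    e1 <- edge_key(faces[, 1], faces[, 2])
    e2 <- edge_key(faces[, 2], faces[, 3])
    e3 <- edge_key(faces[, 3], faces[, 1])
    keys <- unique(c(e1, e2, e3))
    ka <- keys %/% (nv + 1L); kb <- keys %% (nv + 1L)
    mid <- (verts[ka, , drop = FALSE] + verts[kb, , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    idx <- nv + match(c(e1, e2, e3), keys)
    m1 <- idx[seq_len(nrow(faces))]
    m2 <- idx[nrow(faces) + seq_len(nrow(faces))]
    m3 <- idx[2L * nrow(faces) + seq_len(nrow(faces))]
    verts <- rbind(verts, mid)
    faces <- rbind(cbind(faces[, 1], m1, m3),
                   cbind(faces[, 2], m2, m1),
                   cbind(faces[, 3], m3, m2),
                   cbind(m1, m2, m3))
  }
  verts <- verts * radius
  mw <- rep(FALSE, nrow(verts))
  if (medial_wall_frac > 0) {
    k <- max(1L, round(medial_wall_frac * nrow(verts)))
    mw[order(verts[, 3])[seq_len(k)]] <- TRUE  # contiguous cap at -z pole
  }
  surface_mesh(verts, faces, sphere = verts, medial_wall = mw)
}

#' Unique undirected edge list of a mesh
#'
#' @param mesh a [surface_mesh].
#' @return Integer E x 2 matrix, each row `a < b`.
#' @export
mesh_edges <- function(mesh) {
  .mesh_cached(mesh, "edges", {
    f <- mesh$faces
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e[!duplicated(e), , drop = FALSE]
  })
}

# derived mesh geometry is memoized in the mesh's environment (shared across
# copies, computed on first use)
.mesh_cached <- function(mesh, key, expr) {
  if (is.null(mesh$cache)) return(expr)
  if (is.null(mesh$cache[[key]])) mesh$cache[[key]] <- expr
  mesh$cache[[key]]
}

edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
    mesh$vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Sparse vertex adjacency matrix
#' @param mesh a [surface_mesh].
#' @return A symmetric sparse pattern matrix (V x V).
#' @export
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  v <- n_vertices(mesh)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(v, v))
}

face_areas <- function(mesh) {
  .mesh_cached(mesh, "face_areas", .face_areas(mesh))
}

.face_areas <- function(mesh) {
  p1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  p2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  p3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- p2 - p1; w <- p3 - p1
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-vertex Voronoi-style areas (one third of incident face area)
#' @param mesh a [surface_mesh].
#' @return Numeric vector of length V (mm^2); sums to total surface area.
#' @export
vertex_areas <- function(mesh) {
  .mesh_cached(mesh, "vertex_areas", {
    fa <- face_areas(mesh) / 3
    va <- numeric(n_vertices(mesh))
    for (k in 1:3) {
      acc <- rowsum(fa, mesh$faces[, k])
      va[as.integer(rownames(acc))] <- va[as.integer(rownames(acc))] + acc[, 1]
    }
    va
  })
}

#' Validate a vertex map against its mesh
#'
#' Vertex maps are plain numeric vectors with one value per vertex; `NaN`/`NA`
#' is allowed only on the medial wall.
#' @param values numeric vector of per-vertex values.
#' @param mesh a [surface_mesh].
#' @return `values`, invisibly, after checks.
#' @export
check_vertex_map <- function(values, mesh) {
  if (length(values) != n_vertices(mesh))
    stop("vertex map length does not match mesh vertex count")
  bad <- !is.finite(values) & !mesh$medial_wall
  if (any(bad))
    stop("non-finite values off the medial wall")
  invisible(values)
}

great_circle_dist <- function(a, b, radius = NULL) {
  # a: n x 3, b: m x 3 -> n x m geodesic distances on the common sphere
  ra <- sqrt(rowSums(a^2)); rb <- sqrt(rowSums(b^2))
  r <- if (is.null(radius)) mean(c(ra, rb)) else radius
  cosang <- tcrossprod(a / ra, b / rb)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  r * acos(cosang)
}
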