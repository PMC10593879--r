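#' Diffusion smoothing operator for a mesh
#'
#' Builds the symmetric, doubly stochastic one-step averaging operator
#' `S = I - (w / max_deg) * L` (L the graph Laplacian) restricted to valid
#' (non-masked) vertices, together with the number of iterations needed to
#' reach a target kernel FWHM. Iterating a local averaging step approximates
#' heat-kernel smoothing; the per-step spatial variance is calibrated from
#' the mesh edge lengths so that total variance matches
#' `fwhm^2 / (8 log 2)`.
#'
#' @param mesh a [surface_mesh].
#' @param fwhm target kernel full width at half maximum (mm).
#' @param mask logical vector of vertices to smooth over; defaults to the
#'   complement of the medial wall.
#' @param w_max maximal per-step neighbour weight (stability/positivity).
#' @return list with `S` (sparse operator on masked vertices), `iters`,
#'   `w`, `mask`.
#' @keywords internal
smoothing_operator <- function(mesh, fwhm, mask = !mesh$medial_wall,
                               w_max = 0.5) {
  stopifnot(fwhm >= 0)
  v <- n_vertices(mesh)
  edges <- mesh_edges(mesh)
  keep <- mask[edges[, 1]] & mask[edges[, 2]]
  edges <- edges[keep, , drop = FALSE]
  h <- edge_lengths(mesh, edges)
  idx <- which(mask)
  map <- integer(v); map[idx] <- seq_along(idx)
  i <- map[edges[, 1]]; j <- map[edges[, 2]]
  deg <- tabulate(c(i, j), length(idx))
  max_deg <- max(deg)
  # per-axis variance of one step at unit neighbour weight share
  c_step <- sum(2 * h^2) / length(idx) / (2 * max_deg)
  sigma2 <- fwhm^2 / (8 * log(2))
  if (sigma2 <= 0) {
    return(list(S = NULL, iters = 0L, w = 0, mask = mask))
  }
  iters <- max(1L, as.integer(ceiling(sigma2 / (w_max * c_step))))
  w <- sigma2 / (iters * c_step)
  off <- w / max_deg
  S <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = off,
                            dims = c(length(idx), length(idx)))
  Matrix::diag(S) <- 1 - Matrix::rowSums(S)
  list(S = S, iters = iters, w = w, mask = mask)
}

#' Smooth a vertex map (or stack) on a surface mesh
#'
#' Geodesic diffusion smoothing by iterated symmetric neighbour averaging,
#' calibrated so the accumulated kernel has the requested FWHM. Medial-wall
#' (`NaN`) vertices are excluded from all kernels and preserved as `NaN`;
#' `fwhm = 0` returns the input unchanged. The operator is doubly stochastic
#' on the valid vertex set, so constants and the map total are preserved.
#'
#' @param x numeric vector (length V) or V x k matrix of maps.
#' @param mesh a [surface_mesh].
#' @param fwhm smoothing kernel FWHM in mm (>= 0).
#' @return Smoothed object of the same shape as `x`.
#' @export
smooth_surface <- function(x, mesh, fwhm) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  stopifnot(nrow(xm) == n_vertices(mesh))
  if (fwhm == 0) return(x)
  mask <- apply(is.finite(xm), 1, all)
  op <- smoothing_operator(mesh, fwhm, mask = mask)
  y <- xm[op$mask, , drop = FALSE]
  for (k in seq_len(op$iters)) y <- as.matrix(op$S %*% y)
  out <- xm
  out[op$mask, ] <- y
  if (vec) out[, 1] else out
}

#' Aggregate a vertex map into parcels
#'
#' Per-parcel mean or median over non-`NaN` vertices (area-average style
#' aggregation). Parcels whose vertices are all `NaN` (e.g. a medial-wall
#' parcel) give `NaN`. Label 0 / `NA` marks unassigned vertices and is
#' skipped.
#'
#' @param values numeric vertex map.
#' @param labels integer per-vertex parcel labels (0/`NA` = unassigned).
#' @param stat `"mean"` or `"median"`.
#' @return Named numeric vector, one value per parcel label, sorted by label.
#' @export
parcellate <- function(values, labels, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (length(values) != length(labels))
    stop("labels and map length differ")
  keep <- !is.na(labels) & labels != 0L
  ids <- sort(unique(labels[keep]))
  f <- if (stat == "mean") mean else stats::median
  out <- vapply(ids, function(id) {
    v <- values[keep & labels == id]
    v <- v[is.finite(v)]
    if (length(v) == 0) NaN else f(v)
  }, numeric(1))
  names(out) <- ids
  out
}

#' Broadcast parcel values back to vertices
#' @param parcel_values named numeric vector (names = parcel labels).
#' @param labels per-vertex parcel labels.
#' @return Vertex map with each vertex carrying its parcel's value.
#' @export
unparcellate <- function(parcel_values, labels) {
  out <- rep(NaN, length(labels))
  m <- match(labels, as.integer(names(parcel_values)))
  ok <- !is.na(m)
  out[ok] <- parcel_values[m[ok]]
  out
}

#' Spherical centroids of parcels
#'
#' Mean of member-vertex sphere coordinates, projected back to the sphere.
#' @param mesh a [surface_mesh].
#' @param labels per-vertex parcel labels (0/`NA` = unassigned).
#' @return P x 3 matrix of centroid coordinates, rownames = parcel labels.
#' @export
parcel_centroids <- function(mesh, labels) {
  keep <- !is.na(labels) & labels != 0L
  ids <- sort(unique(labels[keep]))
  r <- mean(sqrt(rowSums(mesh$sphere^2)))
  cen <- t(vapply(ids, function(id)
    colMeans(mesh$sphere[keep & labels == id, , drop = FALSE]), numeric(3)))
  cen <- cen / sqrt(rowSums(cen^2)) * r
  rownames(cen) <- ids
  cen
}

#' Assign cortical areas to their nearest fine parcel
#'
#' Each area (given by a spherical centroid) is matched to the fine parcel
#' whose centroid is nearest in great-circle distance on the registration
#' sphere — an algorithmic surrogate for manual matching of expression
#' sampling areas to a fine surface parcellation. Ties break to the lowest
#' parcel id. Assignments can be overridden downstream via a TSV.
#'
#' @param area_centroids A x 3 matrix of area centroids on the sphere
#'   (rownames = area names).
#' @param mesh a [surface_mesh].
#' @param fine_labels per-vertex labels of the fine parcellation.
#' @return data.frame with `area`, `parcel` (fine parcel id), `distance` (mm).
#' @export
map_areas_to_parcels <- function(area_centroids, mesh, fine_labels) {
  cen <- parcel_centroids(mesh, fine_labels)
  if (nrow(cen) == 0) stop("empty fine parcellation")
  d <- great_circle_dist(as.matrix(area_centroids), cen)
  pick <- apply(d, 1, which.min)  # which.min returns first (lowest id) on ties
  data.frame(
    area = rownames(area_centroids) %||% seq_len(nrow(d)),
    parcel = as.integer(rownames(cen))[pick],
    distance = d[cbind(seq_len(nrow(d)), pick)],
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
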