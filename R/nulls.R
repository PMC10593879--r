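#' Uniform random 3D rotation matrices
#'
#' Haar-uniform rotations from normalized Gaussian quaternions.
#' @param n number of rotations.
#' @param seed integer RNG seed (`NULL` = use current RNG state).
#' @return list of 3 x 3 rotation matrices.
#' @export
random_rotations <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

# nearest original point for each original position after rotating the
# source cloud by R; ties break to the lowest index (max.col "first")
spin_assignment <- function(coords, R) {
  u <- coords / sqrt(rowSums(coords^2))
  s <- tcrossprod(u, u %*% t(R))   # <orig_i, R orig_j>
  max.col(s, ties.method = "first")
}

mirror_x <- diag(c(-1, 1, 1))

#' Spin permutations of a vertex map
#'
#' Each permutation applies a Haar-uniform rotation to the registration
#' sphere and reassigns every vertex the value of the nearest original
#' vertex under the rotation, preserving the map's spatial autocorrelation
#' while randomizing its alignment. If the mesh carries both hemispheres,
#' the right hemisphere uses the x-mirrored rotation (the standard bilateral
#' symmetry convention) and vertices are reassigned within hemisphere.
#' Medial-wall `NaN` values travel with the rotation; downstream statistics
#' exclude them pairwise.
#'
#' @param values numeric vertex map.
#' @param mesh a [surface_mesh] with sphere coordinates.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return V x n_perm matrix of permuted maps.
#' @export
spin_vertex <- function(values, mesh, n_perm = 10000, seed = 1) {
  stopifnot(length(values) == n_vertices(mesh))
  if (is.null(mesh$sphere)) stop("mesh lacks sphere coordinates")
  rots <- random_rotations(n_perm, seed)
  out <- matrix(NA_real_, length(values), n_perm)
  hemis <- unique(mesh$hemisphere)
  for (hm in hemis) {
    sel <- which(mesh$hemisphere == hm)
    coords <- mesh$sphere[sel, , drop = FALSE]
    for (k in seq_len(n_perm)) {
      R <- if (hm == "right") mirror_x %*% rots[[k]] %*% mirror_x else
        rots[[k]]
      out[sel, k] <- values[sel][spin_assignment(coords, R)]
    }
  }
  out
}

#' Spin permutations of a parcel map
#'
#' Rotates the parcel centroids on the registration sphere and reassigns
#' each parcel the value of the nearest original centroid. `NaN` parcels
#' (medial wall) travel with the rotation and are excluded pairwise from
#' any correlation computed on the permuted stack.
#'
#' @param values numeric parcel map.
#' @param centroids P x 3 matrix of parcel centroids on the sphere.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return P x n_perm matrix of permuted parcel maps.
#' @export
spin_parcel <- function(values, centroids, n_perm = 10000, seed = 1) {
  centroids <- as.matrix(centroids)
  stopifnot(length(values) == nrow(centroids))
  if (nrow(centroids) < 3) stop("need at least 3 parcels to spin")
  rots <- random_rotations(n_perm, seed)
  out <- matrix(NA_real_, length(values), n_perm)
  for (k in seq_len(n_perm))
    out[, k] <- values[spin_assignment(centroids, rots[[k]])]
  out
}

perm_pvalue <- function(observed, null_sample, tails = c("two", "one")) {
  tails <- match.arg(tails)
  null_sample <- null_sample[is.finite(null_sample)]
  n <- length(null_sample)
  hits <- if (tails == "two") sum(abs(null_sample) >= abs(observed)) else
    sum(null_sample >= observed)
  (1 + hits) / (n + 1)   # add-one rule: p is never exactly 0
}

null_result <- function(observed, null_sample, p, n_perm, tails, seed,
                        extra = list()) {
  structure(c(list(observed = observed, null_sample = null_sample, p = p,
                   n_perm = n_perm, tails = tails, seed = seed), extra),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("null_result: observed = %.4f, p = %.4g (%s-tailed, %d perms)\n",
              x$observed, x$p, x$tails, x$n_perm))
  invisible(x)
}

#' Spin permutation test of a parcel-map correlation
#'
#' Pearson correlation of two parcel maps on pairwise-complete parcels; the
#' null distribution correlates spun versions of `x` with the fixed `y`.
#' Two-tailed add-one permutation p.
#'
#' @param x,y numeric parcel maps (same atlas; `NaN` allowed).
#' @param centroids parcel centroids on the sphere.
#' @param n_perm number of spins.
#' @param seed integer RNG seed.
#' @return A `null_result` with `observed` = Pearson r.
#' @export
spin_test_correlation <- function(x, y, centroids, n_perm = 10000, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("fewer than 3 complete parcels")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance after NaN exclusion")
  obs <- stats::cor(x[ok], y[ok])
  spun <- spin_parcel(x, centroids, n_perm, seed)
  nulls <- apply(spun, 2, function(xs) {
    k <- is.finite(xs) & is.finite(y)
    if (sum(k) < 3 || stats::sd(xs[k]) == 0 || stats::sd(y[k]) == 0)
      return(NA_real_)
    stats::cor(xs[k], y[k])
  })
  p <- perm_pvalue(obs, nulls, "two")
  null_result(obs, nulls, p, n_perm, "two", seed,
              extra = list(n_units = sum(ok)))
}

#' Enrichment of a statistic map within atlas classes
#'
#' Tests whether a vertexwise statistic map is higher or lower within each
#' class of a label map (cytoarchitectural type, functional network) than
#' expected under spatial-autocorrelation-preserving spin permutations. The
#' class statistic is the within-class median (mean available); the null
#' re-evaluates it on spun maps with the labels fixed. The reported p is the
#' doubled one-sided add-one permutation p (two-tailed); no cross-class
#' multiplicity correction is applied.
#'
#' @param tmap numeric vertex map (e.g. t statistics).
#' @param class_labels integer per-vertex class labels (0/`NA` = none).
#' @param mesh a [surface_mesh].
#' @param stat `"median"` or `"mean"`.
#' @param n_perm number of spins.
#' @param seed integer RNG seed.
#' @param class_names optional names for the label dictionary.
#' @return data.frame per class: `class`, `label`, `n_vertices`, `observed`
#'   (median or mean), `sd` (within-class SD), `p_spin`.
#' @export
class_enrichment <- function(tmap, class_labels, mesh,
                             stat = c("median", "mean"),
                             n_perm = 10000, seed = 1, class_names = NULL) {
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  keep <- !is.na(class_labels) & class_labels != 0L
  ids <- sort(unique(class_labels[keep]))
  if (!length(ids)) stop("no labeled classes")
  spun <- spin_vertex(tmap, mesh, n_perm, seed)
  rows <- lapply(seq_along(ids), function(i) {
    sel <- keep & class_labels == ids[i]
    vobs <- tmap[sel]; vobs <- vobs[is.finite(vobs)]
    if (!length(vobs)) stop("class ", ids[i], " has no valid vertices")
    obs <- f(vobs)
    nulls <- apply(spun[sel, , drop = FALSE], 2, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) f(v) else NA_real_
    })
    nulls <- nulls[is.finite(nulls)]
    p_hi <- (1 + sum(nulls >= obs)) / (length(nulls) + 1)
    p_lo <- (1 + sum(nulls <= obs)) / (length(nulls) + 1)
    data.frame(class = ids[i],
               label = if (is.null(class_names)) as.character(ids[i]) else
                 class_names[ids[i]],
               n_vertices = sum(sel), observed = obs,
               sd = stats::sd(vobs), p_spin = min(1, 2 * min(p_hi, p_lo)))
  })
  do.call(rbind, rows)
}

#' Random reassignment permutation test of a correlation
#'
#' Pearson correlation of two equal-length area-level vectors with a null
#' built by uniformly permuting the labels of `x` (used where too few units
#' exist for a spherical spin, e.g. a small set of expression sampling
#' areas). Two-tailed add-one p.
#'
#' @param x,y numeric vectors (equal length >= 3).
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return A `null_result`.
#' @export
reassignment_test_correlation <- function(x, y, n_perm = 10000, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  obs <- stats::cor(x, y)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  nulls <- vapply(seq_len(n_perm), function(k)
    stats::cor(x[sample.int(length(x))], y), numeric(1))
  p <- perm_pvalue(obs, nulls, "two")
  null_result(obs, nulls, p, n_perm, "two", seed,
              extra = list(n_units = length(x)))
}

#' Moran-type spatial autocorrelation statistic along mesh edges
#'
#' Mean product of standardized values over mesh edges; used to verify that
#' spin permutations preserve spatial autocorrelation while unrestricted
#' shuffles destroy it.
#'
#' @param values numeric vertex map.
#' @param mesh a [surface_mesh].
#' @return scalar edge autocorrelation.
#' @export
edge_autocorrelation <- function(values, mesh) {
  e <- mesh_edges(mesh)
  ok <- is.finite(values)
  z <- values
  z[ok] <- (values[ok] - mean(values[ok])) / stats::sd(values[ok])
  keep <- ok[e[, 1]] & ok[e[, 2]]
  mean(z[e[keep, 1]] * z[e[keep, 2]])
}
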