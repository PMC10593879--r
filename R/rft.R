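#' Estimate residual field smoothness (FWHM) on a mesh
#'
#' Standard roughness estimator for random-field inference: residual maps
#' are normalized to unit sum of squares per vertex, the variance of the
#' normalized-residual gradient is accumulated along mesh edges
#' (`lambda = sum_j (u_j(a) - u_j(b))^2 / h_ab^2`, averaged over edges), and
#' the global FWHM follows from the Gaussian autocorrelation relation
#' `FWHM = sqrt(4 log 2 / lambda)`. Resels express the search region area in
#' units of FWHM^2.
#'
#' @param resid_maps V x J matrix of residual maps (J >= 2); medial-wall
#'   vertices may be `NaN`.
#' @param mesh a [surface_mesh].
#' @return list of class `smoothness_estimate`: `fwhm` (mm),
#'   `total_resels`, `resels_per_vertex` (vertex area / FWHM^2), `lambda`.
#' @export
estimate_fwhm <- function(resid_maps, mesh) {
  resid_maps <- as.matrix(resid_maps)
  stopifnot(nrow(resid_maps) == n_vertices(mesh), ncol(resid_maps) >= 2)
  ss <- rowSums(resid_maps^2)
  valid <- is.finite(ss) & ss > 0
  if (!any(valid)) stop("no valid residual vertices")
  if (any(is.finite(ss) & ss == 0))
    stop("constant (zero) residuals at some vertices; smoothness undefined")
  u <- resid_maps
  u[valid, ] <- resid_maps[valid, , drop = FALSE] / sqrt(ss[valid])
  edges <- mesh_edges(mesh)
  keep <- valid[edges[, 1]] & valid[edges[, 2]]
  edges <- edges[keep, , drop = FALSE]
  h <- edge_lengths(mesh, edges)
  du2 <- rowSums((u[edges[, 1], , drop = FALSE] -
                    u[edges[, 2], , drop = FALSE])^2)
  lambda <- mean(du2 / h^2)
  fwhm <- sqrt(4 * log(2) / lambda)
  va <- vertex_areas(mesh)
  rpv <- ifelse(valid, va / fwhm^2, 0)
  structure(list(fwhm = fwhm, total_resels = sum(rpv),
                 resels_per_vertex = rpv, lambda = lambda),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("smoothness_estimate: FWHM = %.3f mm, %.1f resels\n",
              x$fwhm, x$total_resels))
  invisible(x)
}

#' Extract suprathreshold clusters from a t map
#'
#' Connected components (union-find over mesh edges) of vertices exceeding
#' the primary cluster-forming threshold. `NaN` vertices never join a
#' cluster. For `sign = "two_sided"` positive and negative excursions are
#' labeled separately. Cluster area is the sum of member-vertex areas, which
#' is unbiased for the area of the continuous excursion set.
#'
#' @param tmap numeric vertex map of t statistics.
#' @param mesh a [surface_mesh].
#' @param primary_threshold positive t threshold.
#' @param sign `"positive"`, `"negative"` or `"two_sided"`.
#' @return list of class `cluster_result`: `cluster_id` (per vertex, 0 =
#'   subthreshold), `table` (data.frame: cluster, sign, n_vertices,
#'   area_mm2, peak_t, peak_vertex), `primary_threshold`, `sign`.
#' @export
extract_clusters <- function(tmap, mesh,
                             primary_threshold,
                             sign = c("positive", "negative", "two_sided")) {
  sign <- match.arg(sign)
  stopifnot(primary_threshold > 0, length(tmap) == n_vertices(mesh))
  edges <- mesh_edges(mesh)
  cluster_id <- integer(length(tmap))
  rows <- list(); next_id <- 0L
  for (sg in if (sign == "two_sided") c("positive", "negative") else sign) {
    u <- if (sg == "positive") tmap - primary_threshold else
      -tmap - primary_threshold
    supra <- is.finite(u) & u > 0
    if (!any(supra)) next
    first_id <- next_id
    comp <- connected_components(which(supra), edges)
    area <- numeric(length(comp))
    for (k in seq_along(comp)) {
      vs <- comp[[k]]
      next_id <- next_id + 1L
      cluster_id[vs] <- next_id
    }
    area <- excursion_areas(u, supra, cluster_id - first_id, mesh,
                            length(comp))
    for (k in seq_along(comp)) {
      vs <- comp[[k]]
      pk <- vs[which.max(abs(tmap[vs]))]
      rows[[first_id + k]] <- data.frame(
        cluster = first_id + k, sign = sg, n_vertices = length(vs),
        area_mm2 = area[k], peak_t = tmap[pk], peak_vertex = pk)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), sign = character(),
               n_vertices = integer(), area_mm2 = numeric(),
               peak_t = numeric(), peak_vertex = integer())
  structure(list(cluster_id = cluster_id, table = tab,
                 primary_threshold = primary_threshold, sign = sign),
            class = "cluster_result")
}

# per-cluster excursion area: sum of member-vertex areas (globally unbiased
# for the continuous excursion-set area, since each vertex is suprathreshold
# with exactly the marginal tail probability)
excursion_areas <- function(u, supra, local_id, mesh, ncl) {
  if (ncl == 0) return(numeric(0))
  va <- vertex_areas(mesh)
  out <- numeric(ncl)
  acc <- rowsum(va[supra], local_id[supra])
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

# union-find with path halving over the suprathreshold subgraph
connected_components <- function(members, edges) {
  inset <- logical(max(c(edges, members)))
  inset[members] <- TRUE
  e <- edges[inset[edges[, 1]] & inset[edges[, 2]], , drop = FALSE]
  parent <- seq_len(length(inset))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(e)) {
    for (k in seq_len(nrow(e))) {
      ra <- find(e[k, 1]); rb <- find(e[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(members, find, integer(1))
  unname(split(members, roots))
}

#' Random-field-theory cluster p-values for a t field
#'
#' Assigns each cluster a family-wise corrected p-value from the standard
#' expected-Euler-characteristic formulation for t fields on a 2D search
#' region: the expected number of clusters at the primary threshold comes
#' from the EC densities, the expected suprathreshold area (in resels) from
#' the t tail probability, and the tail of the maximal cluster extent from
#' the Poisson clumping heuristic with (approximately) exponential cluster
#' sizes,
#' `p = 1 - exp(-E[m] * exp(-k / E[n]))`
#' with `k` the cluster extent in resels. Thresholds below t ~ 2 violate the
#' high-threshold assumption and trigger a warning.
#'
#' @param clusters a `cluster_result` from [extract_clusters()].
#' @param smoothness a `smoothness_estimate` from [estimate_fwhm()].
#' @param df residual degrees of freedom of the t field.
#' @param alpha cluster-level significance level (default 0.01).
#' @param euler_chi Euler characteristic of the search region (2 for a
#'   closed sphere; 1 per simply connected hemisphere patch).
#' @return The `cluster_result` with columns `extent_resels`, `p_cluster`,
#'   `significant` added to its table, plus fields `alpha`, `expected_m`,
#'   `expected_resels_per_cluster`.
#' @export
cluster_pvalues <- function(clusters, smoothness, df, alpha = 0.01,
                            euler_chi = 2) {
  stopifnot(inherits(clusters, "cluster_result"),
            inherits(smoothness, "smoothness_estimate"))
  t0 <- clusters$primary_threshold
  if (t0 < 2)
    warning("primary threshold t = ", format(t0),
            " is low for random-field cluster inference")
  R2 <- smoothness$total_resels
  rho0 <- stats::pt(t0, df, lower.tail = FALSE)
  c_nu <- exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2)
  rho2 <- 4 * log(2) / (2 * pi)^1.5 * c_nu * t0 *
    (1 + t0^2 / df)^(-(df - 1) / 2)
  Em <- euler_chi * rho0 + R2 * rho2          # expected cluster count
  ES <- R2 * rho0                             # expected suprathreshold resels
  En <- ES / Em                               # expected extent per cluster
  n_signs <- if (clusters$sign == "two_sided") 2 else 1
  tab <- clusters$table
  if (nrow(tab)) {
    k <- tab$area_mm2 / smoothness$fwhm^2
    p_one <- 1 - exp(-Em * exp(-k / En))
    tab$extent_resels <- k
    tab$p_cluster <- pmin(1, n_signs * p_one)
    tab$significant <- tab$p_cluster <= alpha
  } else {
    tab$extent_resels <- numeric(0)
    tab$p_cluster <- numeric(0)
    tab$significant <- logical(0)
  }
  clusters$table <- tab
  clusters$alpha <- alpha
  clusters$expected_m <- Em * n_signs
  clusters$expected_resels_per_cluster <- En
  clusters
}

#' One-call RFT correction of a fitted t map
#'
#' Convenience wrapper: estimates smoothness from the fit's residual maps,
#' extracts clusters at the primary threshold (default the t quantile of
#' vertexwise p < .001 at the model df) and attaches RFT cluster p-values.
#'
#' @param fit a `glm_result`.
#' @param mesh a [surface_mesh].
#' @param primary_p vertexwise p defining the cluster-forming threshold.
#' @param sign sidedness of the excursion set (default positive).
#' @param alpha cluster-level significance level.
#' @return A `cluster_result` with p-values, plus field `smoothness`.
#' @export
rft_correct <- function(fit, mesh, primary_p = 0.001,
                        sign = c("positive", "negative", "two_sided"),
                        alpha = 0.01) {
  sign <- match.arg(sign)
  sm <- estimate_fwhm(fit$resid, mesh)
  thr <- stats::qt(primary_p, fit$df, lower.tail = FALSE)
  cl <- extract_clusters(fit$tstat, mesh, thr, sign)
  cl <- cluster_pvalues(cl, sm, fit$df, alpha = alpha)
  cl$smoothness <- sm
  cl
}
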