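test_that("white residual fields give FWHM near the closed-form constant", {
  m <- fix$mesh3
  h <- mean(polycort:::edge_lengths(m))
  set.seed(30)
  w <- matrix(rnorm(nrow(m$vertices) * 80), nrow(m$vertices), 80)
  est <- estimate_fwhm(w, m)
  # white noise sampled on edges of length h: FWHM = sqrt(2 log 2) * h
  expect_lt(abs(est$fwhm - sqrt(2 * log(2)) * h) / est$fwhm, 0.15)
})

test_that("estimated FWHM increases with applied smoothing and scales with the mesh", {
  m <- fix$mesh3
  set.seed(31)
  w <- matrix(rnorm(nrow(m$vertices) * 40), nrow(m$vertices), 40)
  ests <- vapply(c(0, 10, 20, 30), function(f) {
    x <- if (f > 0) smooth_surface(w, m, f) else w
    estimate_fwhm(x, m)$fwhm
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
  m2 <- fix$mesh3
  m2 <- surface_mesh(m2$vertices * 2, m2$faces, m2$sphere * 2,
                     m2$medial_wall, m2$hemisphere)
  expect_equal(estimate_fwhm(w, m2)$fwhm, ests[1] * 2, tolerance = 1e-9)
  expect_error(estimate_fwhm(matrix(0, nrow(m$vertices), 5), m), "residual")
})

test_that("cluster extraction matches graph components and handles signs", {
  m <- fix$mesh2
  tmap <- numeric(nrow(m$vertices))
  expect_identical(nrow(extract_clusters(tmap, m, 3)$table), 0L)
  # constructed patch of 7 contiguous vertices
  e <- mesh_edges(m)
  adj <- mesh_adjacency(m)
  seedv <- 20L  # subdivision vertex: degree 6
  patch <- c(seedv, which(adj[seedv, ] > 0)[1:6])
  tmap[patch] <- 5
  cl <- extract_clusters(tmap, m, 3)
  expect_identical(nrow(cl$table), 1L)
  expect_identical(cl$table$n_vertices, 7L)
  # random suprathreshold set: labels equal igraph components (oracle)
  skip_if_not_installed("igraph")
  set.seed(32)
  tmap2 <- rnorm(nrow(m$vertices))
  cl2 <- extract_clusters(tmap2, m, 1, sign = "two_sided")
  supra <- which(abs(tmap2) > 1)
  for (sg in c(1, -1)) {
    vs <- supra[sign(tmap2[supra]) == sg]
    sub_e <- e[e[, 1] %in% vs & e[, 2] %in% vs, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(as.character(sub_e), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g,
      length(setdiff(as.character(vs), igraph::V(g)$name)),
      name = setdiff(as.character(vs), igraph::V(g)$name))
    memb <- igraph::components(g)$membership
    ours <- cl2$cluster_id[as.integer(names(memb))]
    # same partition: label pairs agree
    expect_identical(length(unique(memb)),
                     length(unique(ours)))
    expect_true(all(tapply(ours, memb, function(z) length(unique(z))) == 1))
  }
  # NaN vertices never cluster
  tmap3 <- rep(5, nrow(m$vertices)); tmap3[1:10] <- NaN
  cl3 <- extract_clusters(tmap3, m, 3)
  expect_true(all(cl3$cluster_id[1:10] == 0L))
})

test_that("cluster p-values have the right limits, monotonicity and nesting", {
  m <- fix$mesh3
  set.seed(33)
  w <- matrix(rnorm(nrow(m$vertices) * 40), nrow(m$vertices), 40)
  sm <- estimate_fwhm(smooth_surface(w, m, 15), m)
  tmap <- rep(0, nrow(m$vertices))
  tmap[1:30] <- 4
  cl <- extract_clusters(tmap, m, 3)
  base <- cluster_pvalues(cl, sm, df = 300)
  # monotone decreasing p in extent: fabricate extents
  kk <- c(0.001, 0.1, 1, 5, 50)
  ps <- vapply(kk, function(k) {
    cc <- cl; cc$table$area_mm2 <- k * sm$fwhm^2
    cluster_pvalues(cc, sm, 300)$table$p_cluster[1]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # extent -> 0: p approaches the probability of any cluster, far from
  # significance; extent -> inf: p -> 0
  expect_gt(ps[1], 0.5)
  expect_lt(ps[5], 1e-6)
  # alpha nesting
  p01 <- cluster_pvalues(cl, sm, 300, alpha = 0.01)$table$significant
  p05 <- cluster_pvalues(cl, sm, 300, alpha = 0.05)$table$significant
  expect_true(all(!p01 | p05))
  expect_warning(cluster_pvalues(extract_clusters(tmap, m, 1.5), sm, 300),
                 "low")
})

test_that("rft_correct flags a strong focal effect and not a null field", {
  m <- fix$mesh3
  sub <- small_cohort(n = 80)
  truth <- numeric(nrow(m$vertices))
  center <- which.max(m$sphere[, 3])
  d <- polycort:::great_circle_dist(
    m$sphere, m$sphere[center, , drop = FALSE])[, 1]
  truth[d < 30] <- 0.5
  truth[m$medial_wall] <- NaN
  y <- simulate_thickness(m, sub, effect_spec(truth, noise_sd = 0.4,
                                              noise_fwhm = 15), seed = 34)
  fit <- fit_vertexwise(y, build_design(sub, design_spec()))
  cl <- rft_correct(fit, m)
  expect_gt(sum(cl$table$significant), 0)
  sig <- cl$cluster_id %in% cl$table$cluster[cl$table$significant]
  expect_gt(dice(sig, is.finite(truth) & truth > 0), 0.5)
})
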