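test_that("cohort simulation is seed-deterministic with the stated marginals", {
  spec <- cohort_spec(n_subjects = 390)
  a <- simulate_cohort(spec, seed = 3)
  b <- simulate_cohort(spec, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$age >= 3 & a$age <= 21))
  expect_identical(nrow(a), 390L)
  expect_identical(sum(grepl("^pc", names(a))), 10L)
  big <- simulate_cohort(cohort_spec(n_subjects = 1e4), seed = 4)
  expect_lt(abs(cor(big$score, big$age)), 0.03)
})

test_that("cohort spec validates its ranges", {
  expect_error(cohort_spec(n_subjects = 0))
  expect_error(cohort_spec(age_range = c(21, 3)))
  expect_error(cohort_spec(sex_ratio = 1.5))
})

test_that("noiseless thickness equals the planted effect times the score", {
  m <- fix$mesh2
  sub <- small_cohort(n = 12)
  eff <- effect_spec(rep(0.3, nrow(m$vertices)), noise_sd = 0)
  y <- simulate_thickness(m, sub, eff, seed = 1, baseline = 0)
  expect_equal(y, outer(rep(0.3, nrow(m$vertices)), sub$score),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("medial-wall vertices are NaN for every subject", {
  m <- fix$mesh3
  sub <- small_cohort(n = 8)
  eff <- effect_spec(rep(0, nrow(m$vertices)), noise_sd = 0.4,
                     noise_fwhm = 15)
  y <- simulate_thickness(m, sub, eff, seed = 2)
  expect_true(all(is.nan(y[m$medial_wall, ])))
  expect_true(all(is.finite(y[!m$medial_wall, ])))
  expect_error(simulate_thickness(fix$mesh2, sub, eff), "mesh")
})

test_that("planted residual smoothness is recovered by the FWHM estimator", {
  m <- make_sphere_mesh(4)
  sub <- small_cohort(n = 60)
  eff <- effect_spec(rep(0, nrow(m$vertices)), noise_sd = 0.5,
                     noise_fwhm = 20)
  y <- simulate_thickness(m, sub, eff, seed = 3)
  fit <- fit_vertexwise(y, build_design(sub, design_spec()))
  est <- estimate_fwhm(fit$resid, m)
  expect_lt(abs(est$fwhm - 20) / 20, 0.15)
})

test_that("expression panel recovers planted gradients and honors seeds", {
  spec <- expression_spec(specimen_noise_sd = 0)
  ex <- simulate_expression(spec, seed = 1)
  scores <- score_components(ex)
  expect_identical(dim(scores), c(11L, 6L))  # 6 components x 11 areas
  for (comp in colnames(scores)) {
    planted <- spec$component_gradients[comp, rownames(scores)]
    expect_equal(unname(cor(scores[, comp], planted)), 1, tolerance = 1e-9)
  }
  ex2 <- simulate_expression(spec, seed = 2)
  expect_false(identical(ex$panel$value, ex2$panel$value))
  expect_identical(ex$truth$gradients, ex2$truth$gradients)
})

test_that("disorder maps hit planted correlations exactly at |r| = 1", {
  m <- fix$mesh3
  labels <- fix$atlases3$parcels
  ref <- parcellate(smooth_map(m, 30, seed = 6), labels)
  maps <- simulate_disorder_maps(labels, m, c(a = -1, b = 1, c = 0.5), ref,
                                 seed = 1)
  expect_identical(colnames(maps), c("a", "b", "c"))
  ok <- is.finite(ref)
  expect_equal(unname(cor(maps[ok, "a"], ref[ok])), -1, tolerance = 1e-9)
  expect_equal(unname(cor(maps[ok, "b"], ref[ok])), 1, tolerance = 1e-9)
  expect_error(simulate_disorder_maps(labels, m, c(a = 0.5),
                                      ifelse(ok, 1, NaN), seed = 1),
               "constant")
})

test_that("zero-target disorder maps are uncorrelated in expectation", {
  m <- fix$mesh3
  labels <- fix$atlases3$parcels
  ref <- parcellate(smooth_map(m, 30, seed = 7), labels)
  ok <- is.finite(ref)
  rs <- vapply(1:200, function(s) {
    mp <- simulate_disorder_maps(labels, m, c(x = 0), ref, seed = s)
    cor(mp[ok, 1], ref[ok])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("atlas generation gives contiguous, complete, reproducible labels", {
  m <- fix$mesh3
  atl <- fix$atlases3
  valid <- !m$medial_wall
  expect_true(all(atl$parcels[valid] > 0))
  expect_true(all(atl$parcels[!valid] == 0))
  expect_identical(length(unique(atl$parcels[valid])), 64L)
  expect_identical(length(unique(atl$fine_parcels[valid])), 200L)
  expect_identical(length(unique(atl$types[valid])), 6L)
  expect_identical(length(unique(atl$networks[valid])), 7L)
  atl2 <- make_atlases(m, seed = 99)
  expect_identical(atl2$parcels, atl$parcels)
  # each coarse parcel is edge-connected
  e <- mesh_edges(m)
  for (id in c(1L, 20L, 64L)) {
    vs <- which(atl$parcels == id)
    expect_length(polycort:::connected_components(vs, e), 1L)
  }
})
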