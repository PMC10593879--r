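test_that("BH adjustment matches brute-force step-up enumeration", {
  bh_oracle <- function(p) {   # literal step-up definition
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) adj[o[i]] <- min(vapply(i:m, function(j)
      m * p[o[j]] / j, numeric(1)))
    pmin(adj, 1)
  }
  cases <- list(
    c(.001, .008, .039, .041, .042, .06),
    rep(1, 6),
    rep(.01, 6),
    c(.5, .001, .2, .9, .04, .04),
    runif(11))
  set.seed(60)
  for (p in cases)
    expect_equal(fdr_bh(p)$p_fdr, bh_oracle(p), tolerance = 1e-12)
  expect_false(any(fdr_bh(rep(1, 6))$significant))
  expect_true(all(fdr_bh(rep(.01, 6))$significant))
  expect_equal(fdr_bh(rep(.01, 6))$p_fdr, rep(.01, 6))
  expect_error(fdr_bh(numeric(0)), "empty")
  # order invariance and monotonicity
  p <- c(.03, .2, .01, .8, .05, .05)
  adj <- fdr_bh(p)$p_fdr
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(fdr_bh(p[perm])$p_fdr, adj[perm])
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("Fisher z comparison is antisymmetric and zero at equality", {
  a <- compare_correlations_independent(0.5, 103, 0.5, 103)
  expect_identical(a$z, 0)
  expect_equal(a$p, 1)
  b <- compare_correlations_independent(0.5, 50, 0.5, 500)
  expect_identical(b$z, 0)
  c1 <- compare_correlations_independent(0.6, 100, 0.2, 100)
  c2 <- compare_correlations_independent(0.2, 100, 0.6, 100)
  expect_equal(c1$z, -c2$z)
  expect_error(compare_correlations_independent(1, 10, 0.5, 10))
})

test_that("Fisher z agrees with a parametric bootstrap oracle", {
  skip_if_not_installed("MASS")
  z_formula <- compare_correlations_independent(0.6, 100, 0.2, 100)$z
  set.seed(61)
  B <- 4000
  r1 <- vapply(seq_len(B), function(b) {
    s <- MASS::mvrnorm(100, c(0, 0), matrix(c(1, .6, .6, 1), 2))
    cor(s[, 1], s[, 2])
  }, numeric(1))
  r2 <- vapply(seq_len(B), function(b) {
    s <- MASS::mvrnorm(100, c(0, 0), matrix(c(1, .2, .2, 1), 2))
    cor(s[, 1], s[, 2])
  }, numeric(1))
  z_boot <- (atanh(0.6) - atanh(0.2)) / sd(atanh(r1) - atanh(r2))
  expect_lt(abs(z_formula - z_boot), 0.05 * abs(z_formula) + 0.05)
})

test_that("Zou CI is symmetric at equal correlations and rejects bad triples", {
  cmp <- compare_correlations_dependent(0.4, 0.4, 0.3, 64)
  expect_equal(cmp$diff, 0)
  expect_true(cmp$includes_zero)
  expect_equal(cmp$ci[1], -cmp$ci[2], tolerance = 1e-10)
  expect_identical(cmp$z, 0)
  expect_error(compare_correlations_dependent(0.9, -0.9, 0.9, 64),
               "inconsistent")
})

test_that("disorder similarity recovers planted signs and applies both flags", {
  m <- fix$mesh3
  labels <- fix$atlases3$parcels
  cen <- parcel_centroids(m, labels)
  effect <- parcellate(smooth_map(m, 30, seed = 62), labels)
  targets <- c(scz = -0.9, bd = -0.85, ocd = 0, asd = 0)
  maps <- simulate_disorder_maps(labels, m, targets, effect, seed = 63)
  rep <- disorder_similarity(effect, maps, cen, n_perm = 499, seed = 64)
  expect_identical(rep$disorder, names(targets))
  expect_lt(rep$r[1], -0.6)
  expect_lt(rep$r[2], -0.6)
  expect_true(all(rep$sig_spin[1:2]))
  expect_true(all(rep$p_fdr >= rep$p_spin - 1e-12))
  # an exact negative image gives r = -1 at the minimal attainable p
  rep2 <- disorder_similarity(effect,
                              cbind(neg = -effect), cen,
                              n_perm = 199, seed = 65)
  expect_equal(rep2$r, -1)
  expect_lt(rep2$p_spin, 0.02)
})

test_that("age-group similarity handles identical and sign-flipping truths", {
  m <- fix$mesh2
  sub <- simulate_cohort(cohort_spec(n_subjects = 240, n_scanners = 2),
                         seed = 66)
  truth <- smooth_map(m, 40, seed = 67)
  truth <- 0.25 * truth / sd(truth)
  y <- simulate_thickness(m, sub, effect_spec(truth, noise_sd = 0.5,
                                              noise_fwhm = 10), seed = 68)
  groups <- fit_age_groups(y, sub)
  whole <- fit_vertexwise(y, build_design(sub, design_spec()))
  labels <- make_atlases(m, n_parcels = 32, n_fine_parcels = 64,
                         seed = 69)$parcels
  dmap <- parcellate(-truth, labels)  # disorder map = negative truth
  res <- age_group_similarity(groups, whole, dmap, labels)
  expect_identical(nrow(res$table), 3L)
  expect_length(res$comparisons, 3L)
  expect_true(all(res$table$r_disorder < 0))
  expect_true(all(res$table$r_whole > 0.5))
})
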