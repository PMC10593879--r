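test_that("design matrix has the documented column set and centering", {
  sub <- small_cohort(n = 50, n_scanners = 2)
  des <- build_design(sub, design_spec())
  expect_identical(ncol(des$X), 19L)  # 1+1+2+2+1+10+1+1
  expect_identical(colnames(des$X)[1:6],
                   c("(Intercept)", "score", "age", "age2", "score:age",
                     "score:age2"))
  expect_lt(abs(sum(des$X[, "age"])), 1e-10)  # centered at mean age
  no_int <- build_design(sub, design_spec(include_interactions = FALSE))
  expect_identical(ncol(no_int$X), 17L)
})

test_that("single-level factors drop out and the design stays full rank", {
  sub <- small_cohort(n = 50, n_scanners = 1)
  des <- build_design(sub, design_spec())
  expect_false(any(grepl("^scanner", colnames(des$X))))
  expect_identical(qr(des$X)$rank, ncol(des$X))
})

test_that("degenerate designs are rejected", {
  sub <- small_cohort(n = 50)
  sub2 <- sub; sub2$score[1] <- NA
  expect_error(build_design(sub2), "missing")
  expect_error(build_design(sub[1:15, ]), "columns than subjects")
  sub3 <- sub; sub3$brain_volume <- sub3$age  # collinear with age
  expect_error(build_design(sub3, design_spec(standardize = FALSE)),
               "rank-deficient")
})

test_that("vertexwise OLS matches an independent normal-equations solve", {
  sub <- small_cohort(n = 20)
  des <- build_design(sub, design_spec())
  set.seed(8)
  y <- matrix(rnorm(50 * 20), 50, 20)
  fit <- fit_vertexwise(y, des)
  X <- des$X
  XtXinv <- solve(t(X) %*% X)   # brute-force oracle per vertex
  cc <- which(colnames(X) == "score")
  for (v in c(1, 13, 50)) {
    b <- XtXinv %*% t(X) %*% y[v, ]
    r <- y[v, ] - X %*% b
    s2 <- sum(r^2) / (20 - ncol(X))
    expect_equal(fit$beta[v], b[cc], tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$se[v], sqrt(s2 * XtXinv[cc, cc]), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$tstat[v], b[cc] / sqrt(s2 * XtXinv[cc, cc]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_identical(fit$df, 20L - ncol(X))
})

test_that("squared t equals the F statistic of the nested comparison", {
  sub <- small_cohort(n = 30)
  des <- build_design(sub, design_spec())
  set.seed(9)
  y <- matrix(rnorm(5 * 30), 5, 30)
  fit <- fit_vertexwise(y, des)
  X1 <- des$X
  X0 <- X1[, colnames(X1) != "score"]
  for (v in 1:5) {
    rss1 <- sum(stats::lm.fit(X1, y[v, ])$residuals^2)
    rss0 <- sum(stats::lm.fit(X0, y[v, ])$residuals^2)
    Fv <- (rss0 - rss1) / (rss1 / fit$df)
    expect_equal(fit$tstat[v]^2, Fv, tolerance = 1e-8)
  }
})

test_that("row order does not affect the fit and perfect fits are flagged", {
  sub <- small_cohort(n = 25)
  des <- build_design(sub, design_spec())
  set.seed(10)
  y <- matrix(rnorm(10 * 25), 10, 25)
  fit <- fit_vertexwise(y, des)
  perm <- sample(25)
  sub_p <- sub[perm, ]
  fit_p <- fit_vertexwise(y[, perm], build_design(sub_p, design_spec()))
  expect_equal(fit_p$beta, fit$beta, tolerance = 1e-10)
  expect_equal(fit_p$tstat, fit$tstat, tolerance = 1e-10)
  # response exactly in the design span -> zero residuals -> NaN sentinel
  y2 <- y
  y2[3, ] <- des$X[, "score"]
  expect_warning(fit2 <- fit_vertexwise(y2, des), "perfect-fit")
  expect_equal(fit2$beta[3], 1, tolerance = 1e-10)
  expect_true(is.nan(fit2$tstat[3]))
})

test_that("adding a constant to brain volume changes only the intercept", {
  sub <- small_cohort(n = 30)
  set.seed(11)
  y <- matrix(rnorm(8 * 30), 8, 30)
  spec <- design_spec(standardize = FALSE)
  f1 <- fit_vertexwise(y, build_design(sub, spec))
  sub2 <- sub; sub2$brain_volume <- sub2$brain_volume + 1e5
  f2 <- fit_vertexwise(y, build_design(sub2, spec))
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_equal(f2$tstat, f1$tstat, tolerance = 1e-6)
  keep <- rownames(f1$coef) != "(Intercept)"
  expect_equal(f2$coef[keep, ], f1$coef[keep, ], tolerance = 1e-6)
})

test_that("age groups partition the cohort and center age within group", {
  m <- fix$mesh2
  sub <- simulate_cohort(cohort_spec(n_subjects = 120, n_scanners = 2),
                         seed = 12)
  eff <- effect_spec(rep(0.2, nrow(m$vertices)), noise_sd = 0.3,
                     noise_fwhm = 10)
  y <- simulate_thickness(m, sub, eff, seed = 13)
  groups <- fit_age_groups(y, sub)
  expect_identical(sum(attr(groups, "sizes")), 120L)
  for (g in groups) expect_true(is.finite(g$df) && g$df > 0)
  centers <- vapply(groups, function(g) g$age_center, numeric(1))
  bounds <- list(c(3, 9), c(10, 15), c(16, 21))
  for (i in 1:3) {
    sel <- floor(sub$age) >= bounds[[i]][1] & floor(sub$age) <= bounds[[i]][2]
    expect_equal(unname(centers[i]), mean(sub$age[sel]), tolerance = 1e-10)
  }
})

test_that("an age-constant planted effect map yields concordant group maps", {
  m <- fix$mesh2
  sub <- simulate_cohort(cohort_spec(n_subjects = 390, n_scanners = 2),
                         seed = 14)
  truth <- smooth_map(m, 40, seed = 44)
  truth <- 0.25 * truth / sd(truth)        # amplitude SD 0.25, SNR 0.5
  eff <- effect_spec(truth, noise_sd = 0.5, noise_fwhm = 10)
  y <- simulate_thickness(m, sub, eff, seed = 15)
  groups <- fit_age_groups(y, sub)
  betas <- vapply(groups, function(g) g$beta, numeric(nrow(m$vertices)))
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(cor(betas[, i], betas[, j], use = "complete.obs"), 0.8)
})

test_that("age-centering sweep obeys the reparameterization identity", {
  m <- fix$mesh2
  sub <- small_cohort(n = 60)
  set.seed(16)
  y <- matrix(rnorm(nrow(m$vertices) * 60), nrow(m$vertices), 60)
  sweep <- age_center_sweep(y, sub, centers = 3:21)
  expect_identical(ncol(sweep$beta), 19L)
  base <- sweep$fits[[1]]   # centered at 3
  c0 <- 3
  for (k in c(5, 12, 19)) {
    cc <- sweep$centers[k]
    pred <- base$coef["score", ] +
      base$coef["score:age", ] * (cc - c0) +
      base$coef["score:age2", ] * (cc - c0)^2
    expect_equal(sweep$beta[, k], unname(pred), tolerance = 1e-6)
  }
})

test_that("without interactions the sweep is constant across centers", {
  m <- fix$mesh2
  sub <- small_cohort(n = 60)
  set.seed(17)
  y <- matrix(rnorm(nrow(m$vertices) * 60), nrow(m$vertices), 60)
  sweep <- age_center_sweep(y, sub, centers = c(3, 10, 21),
                            spec = design_spec(include_interactions = FALSE))
  expect_equal(sweep$beta[, 2], sweep$beta[, 1], tolerance = 1e-10)
  expect_equal(sweep$beta[, 3], sweep$beta[, 1], tolerance = 1e-10)
})

test_that("parameter recovery: mean estimated beta approaches the truth", {
  m <- fix$mesh2
  spec <- cohort_spec(n_subjects = 390, n_scanners = 2)
  errs <- vapply(1:20, function(s) {
    sub <- simulate_cohort(spec, seed = s)
    eff <- effect_spec(rep(0.25, nrow(m$vertices)), noise_sd = 0.5,
                       noise_fwhm = 10)
    y <- simulate_thickness(m, sub, eff, seed = 1000 + s)
    fit <- fit_vertexwise(y, build_design(sub, design_spec()))
    mean(fit$beta, na.rm = TRUE) - 0.25
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02 * 0.5 / 1)  # bias < 0.02*SD(noise)/SD(score)
})

test_that("AIC utility reports all three age polynomial degrees", {
  sub <- small_cohort(n = 80)
  resp <- 2.5 - 0.01 * (sub$age - 12)^2 + rnorm(80, 0, 0.05)
  tab <- compare_age_models(resp, sub)
  expect_identical(tab$degree, 0:2)
  expect_identical(which.min(tab$aic), 3L)  # quadratic truth wins
})
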