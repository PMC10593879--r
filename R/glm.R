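#' Design specification for the vertexwise model
#'
#' Encodes the morphometry model
#' `T = b0 + b1 score + b2 age_c + b3 age_c^2 + b4 score:age_c +
#'  b5 score:age_c^2 + sex + PCs + scanner + brain volume`,
#' where `age_c = age - age_center`. Centering the age term moves the
#' developmental stage at which the score main effect is evaluated; without
#' centering the score coefficient would be the (extrapolated) effect at age
#' zero.
#'
#' @param age_center value (years) subtracted from age before the polynomial
#'   and interaction expansion; `NULL` = sample mean age.
#' @param include_interactions include score-by-age and score-by-age^2 terms.
#' @param contrast name of the coefficient to test (default `"score"`).
#' @param standardize standardize the score and continuous non-age
#'   covariates (brain volume, genetic PCs) to unit variance.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(age_center = NULL, include_interactions = TRUE,
                        contrast = "score", standardize = TRUE) {
  structure(list(age_center = age_center,
                 include_interactions = isTRUE(include_interactions),
                 contrast = contrast, standardize = isTRUE(standardize)),
            class = "design_spec")
}

#' Build the design matrix for the vertexwise model
#'
#' Deterministic column order: intercept, score, centered age, centered
#' age^2, score-by-age interactions (if enabled), sex (treatment-coded),
#' genetic PCs, scanner (treatment-coded, k-1 columns), brain volume.
#' Factors with a single level contribute no columns. A rank-deficient
#' design is an error.
#'
#' @param subjects subject table (see [simulate_cohort()] for the schema).
#' @param spec a [design_spec].
#' @return list with `X` (n x p matrix, dimnamed), `age_center`, `contrast`.
#' @export
build_design <- function(subjects, spec = design_spec()) {
  req <- c("score", "age", "sex", "scanner", "brain_volume")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) stop("subject table lacks columns: ",
                         paste(miss, collapse = ", "))
  pc_cols <- grep("^pc[0-9]+$", names(subjects), value = TRUE)
  modeled <- subjects[, c(req, pc_cols)]
  if (any(!stats::complete.cases(modeled)))
    stop("missing values in modeled columns")
  n <- nrow(subjects)
  center <- spec$age_center %||% mean(subjects$age)
  age_c <- subjects$age - center
  std <- function(x) if (spec$standardize && stats::sd(x) > 0)
    as.numeric(scale(x)) else as.numeric(x)
  score <- std(subjects$score)
  X <- cbind(`(Intercept)` = 1, score = score, age = age_c, age2 = age_c^2)
  if (spec$include_interactions)
    X <- cbind(X, `score:age` = score * age_c,
               `score:age2` = score * age_c^2)
  fac_cols <- function(f, prefix) {
    f <- droplevels(factor(f))
    if (nlevels(f) < 2) return(NULL)
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    lev <- levels(f)[-1]
    colnames(m) <- ifelse(startsWith(lev, prefix), lev, paste0(prefix, lev))
    m
  }
  sx <- fac_cols(subjects$sex, "sex")
  if (!is.null(sx)) X <- cbind(X, sx)
  if (length(pc_cols)) {
    pcs <- vapply(pc_cols, function(p) std(subjects[[p]]), numeric(n))
    X <- cbind(X, pcs)
  }
  sc <- fac_cols(subjects$scanner, "scanner")
  if (!is.null(sc)) X <- cbind(X, sc)
  X <- cbind(X, brain_volume = std(subjects$brain_volume))
  if (n <= ncol(X))
    stop("more design columns than subjects")
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix")
  if (!spec$contrast %in% colnames(X))
    stop("contrast coefficient not in design: ", spec$contrast)
  list(X = X, age_center = center, contrast = spec$contrast)
}

#' Fit the vertexwise GLM by ordinary least squares
#'
#' One OLS fit per vertex, vectorized across vertices through a single QR
#' decomposition of the shared design matrix. Vertices with any non-finite
#' response (the medial wall) return `NaN` in every output. Perfect-fit
#' vertices (zero residual variance) would give infinite t values; these are
#' returned as `NaN` with a warning so downstream random-field inference
#' always sees finite fields.
#'
#' @param y V x n matrix of per-subject vertex maps (columns = subjects,
#'   aligned with the design rows).
#' @param design output of [build_design()].
#' @param contrast coefficient to report; defaults to the design's contrast.
#' @return list of class `glm_result`: `beta` (coefficient map for the
#'   contrast), `se`, `tstat`, `df`, `coef` (p x V full coefficient matrix),
#'   `resid` (V x n residual maps), `contrast`, `age_center`, `columns`.
#' @export
fit_vertexwise <- function(y, design, contrast = design$contrast) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (ncol(y) != n) stop("map stack and design have different subject counts")
  stopifnot(contrast %in% colnames(X))
  ok <- apply(is.finite(y), 1, all)
  df <- n - p
  qrX <- qr(X)
  Yt <- t(y[ok, , drop = FALSE])          # n x Vok
  B <- qr.coef(qrX, Yt)                   # p x Vok
  E <- Yt - X %*% B                       # n x Vok residuals
  sigma2 <- colSums(E^2) / df
  # zero residual variance (up to numerical noise relative to the response
  # scale) means an infinite t; return NaN so downstream fields stay finite
  perfect <- sigma2 <= 1e-20 + 1e-16 * colMeans(Yt^2)
  xtx_inv <- chol2inv(qr.R(qrX))
  cc <- which(colnames(X) == contrast)
  se <- sqrt(sigma2 * xtx_inv[cc, cc])
  b <- B[cc, ]
  t <- ifelse(se > 0 & !perfect, b / se, NaN)
  if (any(perfect))
    warning(sum(perfect), " perfect-fit vertices; t set to NaN")
  full <- function(v) { out <- rep(NaN, length(ok)); out[ok] <- v; out }
  coef_all <- matrix(NaN, p, length(ok), dimnames = list(colnames(X), NULL))
  coef_all[, ok] <- B
  resid <- matrix(NaN, length(ok), n)
  resid[ok, ] <- t(E)
  structure(list(beta = full(b), se = full(se), tstat = full(t), df = df,
                 coef = coef_all, resid = resid, contrast = contrast,
                 age_center = design$age_center, columns = colnames(X)),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("glm_result: contrast '%s', df = %d, %d vertices (%d fitted)\n",
              x$contrast, x$df, length(x$beta), sum(is.finite(x$beta))))
  invisible(x)
}

#' Fit the model within age groups
#'
#' Splits the cohort into age bands (default: early childhood 3-9, early
#' adolescence 10-15, late adolescence 16-21), refits the vertexwise model
#' within each subset with the age term centered to the group mean age, and
#' returns one result per group. Band membership is by completed years
#' (`floor(age)` inside the inclusive bounds), so consecutive whole-year
#' bands partition a continuous age range.
#'
#' @param y V x n map stack.
#' @param subjects subject table aligned with `y` columns.
#' @param bounds list of length-2 numeric vectors (inclusive age bounds).
#' @param spec a [design_spec]; its `age_center` is overridden per group.
#' @return named list of `glm_result`, one per group, with attribute
#'   `"sizes"` (group n).
#' @export
fit_age_groups <- function(y, subjects,
                           bounds = list(c(3, 9), c(10, 15), c(16, 21)),
                           spec = design_spec()) {
  nm <- vapply(bounds, function(b) sprintf("age_%g_%g", b[1], b[2]),
               character(1))
  out <- vector("list", length(bounds)); names(out) <- nm
  sizes <- integer(length(bounds)); names(sizes) <- nm
  for (i in seq_along(bounds)) {
    b <- bounds[[i]]
    sel <- floor(subjects$age) >= b[1] & floor(subjects$age) <= b[2]
    sizes[i] <- sum(sel)
    if (sum(sel) == 0) stop("empty age group ", nm[i])
    sub <- droplevels(subjects[sel, , drop = FALSE])
    sp <- spec; sp$age_center <- mean(sub$age)
    des <- build_design(sub, sp)
    out[[i]] <- fit_vertexwise(y[, sel, drop = FALSE], des)
  }
  attr(out, "sizes") <- sizes
  out
}

#' Age-centering sweep of the score effect
#'
#' Refits the full-cohort model once per centering age (default 3..21 in
#' 1-year steps). With interactions present, the score main-effect map at
#' center c equals `b1 + b4 (c - c0) + b5 (c - c0)^2` from any single fit
#' centered at c0, so the sweep traces how the score effect varies across
#' the age range; without interactions all sweep maps coincide.
#'
#' @param y V x n map stack.
#' @param subjects subject table.
#' @param centers numeric vector of centering ages.
#' @param spec a [design_spec] (interactions enabled for a meaningful sweep).
#' @return list with `centers`, `beta` (V x length(centers)), `tstat`
#'   (same shape) and `fits` (list of `glm_result`).
#' @export
age_center_sweep <- function(y, subjects, centers = 3:21,
                             spec = design_spec()) {
  fits <- lapply(centers, function(cc) {
    sp <- spec; sp$age_center <- cc
    fit_vertexwise(y, build_design(subjects, sp))
  })
  list(centers = centers,
       beta = vapply(fits, function(f) f$beta, numeric(nrow(y))),
       tstat = vapply(fits, function(f) f$tstat, numeric(nrow(y))),
       fits = fits)
}

#' Compare age polynomial degrees by AIC
#'
#' Utility reported alongside the main model: fits the subject-level summary
#' response (e.g. mean thickness) with age polynomials of degree 0-2 plus
#' the remaining covariates, and returns the AIC table. The quadratic model
#' is the package default regardless; this is a descriptive check.
#'
#' @param response numeric vector, one value per subject.
#' @param subjects subject table.
#' @return data.frame with `degree`, `aic`, `delta_aic`.
#' @export
compare_age_models <- function(response, subjects) {
  stopifnot(length(response) == nrow(subjects))
  aics <- vapply(0:2, function(deg) {
    rhs <- c("score", if (deg >= 1) "age_c", if (deg >= 2) "I(age_c^2)",
             "sex", "scanner", "brain_volume",
             grep("^pc[0-9]+$", names(subjects), value = TRUE))
    dat <- cbind(subjects, age_c = subjects$age - mean(subjects$age),
                 .y = response)
    keep_fac <- vapply(rhs, function(tm)
      !tm %in% c("sex", "scanner") ||
        nlevels(droplevels(factor(dat[[tm]]))) > 1, logical(1))
    f <- stats::reformulate(rhs[keep_fac], response = ".y")
    stats::AIC(stats::lm(f, data = dat))
  }, numeric(1))
  data.frame(degree = 0:2, aic = aics, delta_aic = aics - min(aics))
}
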