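#' Cohort specification for synthetic subject tables
#'
#' Defaults emulate a developmental imaging-genetics cohort: 390 subjects
#' aged 3-21 years, 46.8% female, several scanners, 10 genetic principal
#' components and a standardized polygenic score drawn independently of age.
#'
#' @param n_subjects number of subjects.
#' @param age_range numeric length-2, min/max age in years.
#' @param sex_ratio proportion female.
#' @param n_scanners number of scanner sites.
#' @param n_pcs number of genetic principal components.
#' @param score_mean,score_sd moments of the simulated polygenic score.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 390, age_range = c(3, 21),
                        sex_ratio = 0.468, n_scanners = 3, n_pcs = 10,
                        score_mean = 0, score_sd = 1) {
  stopifnot(n_subjects >= 1, length(age_range) == 2,
            age_range[1] < age_range[2],
            sex_ratio >= 0, sex_ratio <= 1, n_pcs >= 0, n_scanners >= 1,
            score_sd > 0)
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 sex_ratio = sex_ratio, n_scanners = as.integer(n_scanners),
                 n_pcs = as.integer(n_pcs), score_mean = score_mean,
                 score_sd = score_sd),
            class = "cohort_spec")
}

#' Simulate a subject table
#'
#' Ages are uniform over the range (roughly flat, as in broad developmental
#' cohorts), sex and scanner are categorical draws, genetic principal
#' components and brain volume are Gaussian, and the polygenic score is
#' Gaussian and drawn independently of every covariate (population
#' correlation 0 with age by construction). Deterministic given the seed.
#'
#' @param spec a [cohort_spec].
#' @param seed integer RNG seed.
#' @return data.frame with columns `subject_id`, `score`, `age`, `sex`,
#'   `scanner`, `brain_volume`, `pc1..pcK`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  tab <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    score = stats::rnorm(n, spec$score_mean, spec$score_sd),
    age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
    sex = factor(ifelse(stats::runif(n) < spec$sex_ratio, "F", "M"),
                 levels = c("F", "M")),
    scanner = factor(paste0("scanner", sample.int(spec$n_scanners, n,
                                                  replace = TRUE))),
    brain_volume = stats::rnorm(n, 1.2e6, 1e5),
    stringsAsFactors = FALSE)
  if (spec$n_pcs > 0) {
    pcs <- matrix(stats::rnorm(n * spec$n_pcs), n, spec$n_pcs)
    colnames(pcs) <- paste0("pc", seq_len(spec$n_pcs))
    tab <- cbind(tab, as.data.frame(pcs))
  }
  tab
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Effect specification for simulated morphometry
#'
#' Houses the planted truth used by parameter-recovery tests: the per-vertex
#' true score coefficient, scalar covariate coefficients, and the residual
#' noise model (amplitude and spatial autocorrelation scale).
#'
#' @param effect_map numeric vertex map of true score coefficients
#'   (thickness units per score SD).
#' @param covariate_betas named numeric vector of true coefficients for
#'   subject covariates (applied to the standardized covariate columns);
#'   names among `age`, `age2`, `sex`, `brain_volume`, `pc*`.
#' @param noise_sd residual SD in thickness units (> 0).
#' @param noise_fwhm spatial autocorrelation FWHM of the residual field (mm).
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(effect_map, covariate_betas = c(),
                        noise_sd = 0.5, noise_fwhm = 20) {
  stopifnot(noise_sd >= 0, noise_fwhm >= 0)
  structure(list(effect_map = effect_map, covariate_betas = covariate_betas,
                 noise_sd = noise_sd, noise_fwhm = noise_fwhm),
            class = "effect_spec")
}

#' Simulate per-subject thickness maps with a planted score effect
#'
#' Each subject's vertex map is
#' `baseline + effect_map * score + covariate terms + smooth noise`, where
#' the noise field is white Gaussian smoothed on the mesh to the requested
#' FWHM and rescaled to `noise_sd` per vertex. Medial-wall vertices are
#' `NaN` for every subject.
#'
#' @param mesh a [surface_mesh].
#' @param subjects a subject table from [simulate_cohort()].
#' @param effect an [effect_spec] whose `effect_map` lives on `mesh`.
#' @param seed integer RNG seed.
#' @param baseline mean thickness (mm).
#' @return V x n matrix of thickness maps (columns = subjects).
#' @export
simulate_thickness <- function(mesh, subjects, effect, seed = 1,
                               baseline = 2.5) {
  stopifnot(inherits(effect, "effect_spec"))
  v <- n_vertices(mesh)
  if (length(effect$effect_map) != v)
    stop("effect_map is not defined on this mesh")
  n <- nrow(subjects)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  eff <- effect$effect_map
  eff[!is.finite(eff)] <- 0
  y <- baseline + outer(eff, subjects$score)
  cb <- effect$covariate_betas
  for (nm in names(cb)) {
    x <- switch(nm,
                age = subjects$age - mean(subjects$age),
                age2 = (subjects$age - mean(subjects$age))^2,
                sex = as.numeric(subjects$sex == levels(subjects$sex)[2]),
                brain_volume = as.numeric(scale(subjects$brain_volume)),
                {
                  if (!nm %in% names(subjects)) stop("unknown covariate: ", nm)
                  as.numeric(scale(subjects[[nm]]))
                })
    y <- y + cb[[nm]] * matrix(x, v, n, byrow = TRUE)
  }
  if (effect$noise_sd > 0) {
    noise <- matrix(stats::rnorm(v * n), v, n)
    if (effect$noise_fwhm > 0) {
      # white noise on a discrete mesh already has intrinsic smoothness
      # ~sqrt(2 log 2) * edge length; deconvolve so the *field* FWHM matches
      intrinsic <- sqrt(2 * log(2)) * mean(edge_lengths(mesh))
      kernel <- sqrt(max(0, effect$noise_fwhm^2 - intrinsic^2))
      if (kernel > 0) noise <- smooth_surface(noise, mesh, kernel)
    }
    # restandardize per vertex so the planted SNR is exact in amplitude
    s <- sqrt(rowMeans(noise^2) - rowMeans(noise)^2)
    s[s == 0 | !is.finite(s)] <- 1
    noise <- noise / s * effect$noise_sd
    y <- y + noise
  }
  y[mesh$medial_wall, ] <- NaN
  dimnames(y) <- list(NULL, subjects$subject_id)
  y
}

#' Expression panel specification
#'
#' Defines a synthetic gene x area x specimen expression panel in which six
#' neuropil components (astrocyte, microglia, oligodendrocyte, main_axon,
#' dendritic_tree, neuron_to_neuron_synapse) each track a planted area-level
#' gradient. Defaults use the 11 cytoarchitecturally defined neocortical
#' areas of the developmental transcriptome resource.
#'
#' @param n_genes total genes (component genes plus background).
#' @param n_specimens number of donor specimens.
#' @param areas character vector of area labels.
#' @param component_gradients 6 x n_areas matrix of true area-level
#'   component means (rownames = component names); the default is a fixed
#'   set of standardized cosine patterns, distinct per component.
#' @param specimen_noise_sd SD of specimen-level expression noise
#'   (log-expression units).
#' @return list of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 360, n_specimens = 12,
                            areas = c("A1C", "DFC", "IPC", "ITC", "M1C",
                                      "MFC", "OFC", "S1C", "STC", "V1C",
                                      "VFC"),
                            component_gradients = NULL,
                            specimen_noise_sd = 0.3) {
  stopifnot(n_specimens >= 1, n_genes >= 60, specimen_noise_sd >= 0)
  comps <- c("astrocyte", "microglia", "oligodendrocyte",
             "main_axon", "dendritic_tree", "neuron_to_neuron_synapse")
  na <- length(areas)
  if (is.null(component_gradients)) {
    a <- seq_len(na)
    g <- t(vapply(seq_along(comps), function(k)
      as.numeric(scale(cos(2 * pi * k * (a - 1) / na + k))), numeric(na)))
    rownames(g) <- comps
    component_gradients <- g
  }
  if (ncol(component_gradients) != na)
    stop("each component gradient needs one value per area")
  if (is.null(rownames(component_gradients)))
    rownames(component_gradients) <- comps
  colnames(component_gradients) <- areas
  structure(list(n_genes = as.integer(n_genes),
                 n_specimens = as.integer(n_specimens), areas = areas,
                 components = rownames(component_gradients),
                 component_gradients = component_gradients,
                 specimen_noise_sd = specimen_noise_sd),
            class = "expression_spec")
}

#' Simulate an expression panel with planted component gradients
#'
#' Genes are split evenly between the six components plus a background set.
#' A component gene's log-expression in an area is
#' `baseline_g + loading_g * gradient[component, area] + noise`, so the
#' specificity-weighted (or marker-averaged) area score recovers the planted
#' gradient up to an affine transform. Specificity weights are concentrated
#' on each component's genes; marker lists partition the genes of the three
#' neuron-compartment components.
#'
#' @param spec an [expression_spec].
#' @param seed integer RNG seed.
#' @return list with `panel` (tidy data.frame: gene, area, specimen, value),
#'   `weights` (gene, cell_type, specificity; glial cell types),
#'   `markers` (named list of gene vectors for the compartment terms),
#'   `truth` (the planted gradient matrix and gene assignment).
#' @export
simulate_expression <- function(spec = expression_spec(), seed = 1) {
  stopifnot(inherits(spec, "expression_spec"))
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  comps <- spec$components
  per <- spec$n_genes %/% (length(comps) + 2L)  # background gets ~2 shares
  gene_comp <- rep(c(comps, "background"),
                   c(rep(per, length(comps)),
                     spec$n_genes - per * length(comps)))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  loading <- stats::runif(spec$n_genes, 0.5, 1.5)
  baseline <- stats::rnorm(spec$n_genes, 5, 1)
  na <- length(spec$areas); ns <- spec$n_specimens
  grad <- spec$component_gradients
  mu <- matrix(0, spec$n_genes, na)  # gene x area mean
  for (k in seq_along(comps)) {
    rows <- gene_comp == comps[k]
    mu[rows, ] <- outer(loading[rows], grad[k, ])
  }
  mu <- mu + baseline
  val <- array(rep(mu, ns), c(spec$n_genes, na, ns))
  if (spec$specimen_noise_sd > 0)
    val <- val + array(stats::rnorm(length(val), 0, spec$specimen_noise_sd),
                       dim(val))
  panel <- data.frame(
    gene = rep(genes, times = na * ns),
    area = rep(rep(spec$areas, each = spec$n_genes), times = ns),
    specimen = rep(sprintf("spec%02d", seq_len(ns)),
                   each = spec$n_genes * na),
    value = as.vector(val),
    stringsAsFactors = FALSE)
  glial <- c("astrocyte", "microglia", "oligodendrocyte")
  weights <- do.call(rbind, lapply(glial, function(ct) {
    rows <- gene_comp == ct
    data.frame(gene = genes[rows], cell_type = ct,
               specificity = loading[rows], stringsAsFactors = FALSE)
  }))
  compartments <- c("main_axon", "dendritic_tree", "neuron_to_neuron_synapse")
  markers <- lapply(compartments, function(cc) genes[gene_comp == cc])
  names(markers) <- compartments
  list(panel = panel, weights = weights, markers = markers,
       truth = list(gradients = grad,
                    gene_component = stats::setNames(gene_comp, genes),
                    loading = stats::setNames(loading, genes)))
}

#' Simulate disorder effect-size maps with planted correlations
#'
#' Generates per-disorder parcel maps whose population correlation with a
#' reference parcel map equals the requested value, by Gram-Schmidt mixing
#' of the standardized reference with an independent spatially smooth field
#' (white vertex noise smoothed on the mesh, then parcellated).
#'
#' @param labels per-vertex parcel labels of the target atlas.
#' @param mesh a [surface_mesh].
#' @param target_r named numeric vector of target correlations, one per
#'   disorder; |r| <= 1.
#' @param reference named numeric parcel map (same atlas).
#' @param seed integer RNG seed.
#' @param noise_fwhm smoothness of the independent field (mm).
#' @return P x D matrix of disorder maps (columns named by disorder).
#' @export
simulate_disorder_maps <- function(labels, mesh, target_r, reference,
                                   seed = 1, noise_fwhm = 25) {
  stopifnot(all(abs(target_r) <= 1))
  ok <- is.finite(reference)
  if (stats::sd(reference[ok]) == 0)
    stop("reference map is constant; target correlation undefined")
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  z <- reference
  z[ok] <- as.numeric(scale(reference[ok]))
  out <- matrix(NaN, length(reference), length(target_r),
                dimnames = list(names(reference),
                                names(target_r) %||%
                                  paste0("disorder", seq_along(target_r))))
  for (d in seq_along(target_r)) {
    field <- rep(NaN, n_vertices(mesh))
    field[!mesh$medial_wall] <- stats::rnorm(sum(!mesh$medial_wall))
    if (noise_fwhm > 0) field <- smooth_surface(field, mesh, noise_fwhm)
    e <- parcellate(field, labels)[names(reference)]
    e[ok] <- e[ok] - mean(e[ok])
    e[ok] <- e[ok] - z[ok] * sum(e[ok] * z[ok]) / sum(z[ok]^2)
    if (stats::sd(e[ok]) > 0) e[ok] <- as.numeric(scale(e[ok]))
    r <- target_r[d]
    out[ok, d] <- r * z[ok] + sqrt(1 - r^2) * e[ok]
  }
  out
}

#' Generate synthetic atlas label maps on a mesh
#'
#' Emulates the label resources of surface-based contextualization analyses:
#' a small set of cytoarchitectural classes, functional networks, a coarse
#' whole-cortex parcellation and a fine parcellation. Patches are contiguous
#' spherical Voronoi cells grown from farthest-point-sampled seed vertices
#' (great-circle distance); classes with fewer levels than patches are
#' formed by cycling patches through the class labels, giving spatially
#' distributed classes as in real type/network atlases. Medial-wall vertices
#' get label 0.
#'
#' @param mesh a [surface_mesh].
#' @param n_types number of cytoarchitectural classes.
#' @param n_networks number of functional networks.
#' @param n_parcels number of coarse parcels.
#' @param n_fine_parcels number of fine parcels.
#' @param seed integer RNG seed.
#' @return list with integer per-vertex label vectors `types`, `networks`,
#'   `parcels`, `fine_parcels` and a `dictionaries` list of label names.
#' @export
make_atlases <- function(mesh, n_types = 6, n_networks = 7, n_parcels = 64,
                         n_fine_parcels = 200, seed = 1) {
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  valid <- which(!mesh$medial_wall)
  patchify <- function(k) {
    seeds <- farthest_point_sample(mesh$sphere[valid, , drop = FALSE], k)
    lab <- integer(n_vertices(mesh))
    d <- great_circle_dist(mesh$sphere[valid, , drop = FALSE],
                           mesh$sphere[valid[seeds], , drop = FALSE])
    lab[valid] <- apply(d, 1, which.min)
    lab
  }
  cyc <- function(lab, n_class) ifelse(lab == 0L, 0L, (lab - 1L) %% n_class + 1L)
  types <- cyc(patchify(3L * n_types), n_types)
  networks <- cyc(patchify(3L * n_networks), n_networks)
  parcels <- patchify(n_parcels)
  fine <- patchify(n_fine_parcels)
  dict <- list(
    types = c("agranular", "dysgranular", "eulaminate1", "eulaminate2",
              "eulaminate3", "koniocortical")[seq_len(min(n_types, 6))],
    networks = c("visual", "somatomotor", "dorsal_attention",
                 "ventral_attention", "limbic", "frontoparietal",
                 "default")[seq_len(min(n_networks, 7))],
    parcels = paste0("parcel", seq_len(n_parcels)),
    fine_parcels = paste0("fine", seq_len(n_fine_parcels)))
  if (n_types > 6) dict$types <- paste0("type", seq_len(n_types))
  if (n_networks > 7) dict$networks <- paste0("network", seq_len(n_networks))
  list(types = types, networks = networks, parcels = parcels,
       fine_parcels = fine, dictionaries = dict)
}

farthest_point_sample <- function(pts, k) {
  n <- nrow(pts)
  stopifnot(k <= n)
  sel <- integer(k)
  sel[1] <- sample.int(n, 1)
  u <- pts / sqrt(rowSums(pts^2))
  mind <- acos(pmin(1, pmax(-1, u %*% u[sel[1], ])))
  for (i in seq_len(k - 1L)) {
    sel[i + 1L] <- which.max(mind)
    d <- acos(pmin(1, pmax(-1, u %*% u[sel[i + 1L], ])))
    mind <- pmin(mind, d)
  }
  sel
}
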