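#' Default pipeline configuration
#'
#' All analysis defaults mirror the study conditions the pipeline emulates:
#' a 390-subject cohort aged 3-21 years, quadratic age model with
#' score-by-age interactions, RFT cluster correction at cluster-level
#' alpha = .01 (primary vertexwise p < .001), 10,000 permutations for every
#' null model, age groups 3-9 / 10-15 / 16-21, six disorder maps with
#' FDR across disorders. Synthetic-data settings (mesh resolution, noise
#' amplitude and smoothness, planted effect geometry) control the generated
#' inputs.
#'
#' @param ... overrides of any default (nested lists are replaced whole).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mesh = list(subdivisions = 4, radius = 100, medial_wall_frac = 0.05),
    cohort = list(n_subjects = 390, age_range = c(3, 21), sex_ratio = 0.468,
                  n_scanners = 3, n_pcs = 10),
    effect = list(snr = 0.5, patch_radius_mm = 25, noise_sd = 0.5,
                  noise_fwhm = 20, couple_expression = TRUE,
                  coupling_component = "dendritic_tree"),
    design = list(include_interactions = TRUE, contrast = "score"),
    rft = list(primary_p = 0.001, alpha = 0.01, sign = "positive"),
    nulls = list(n_perm = 10000),
    age_groups = list(bounds = list(c(3, 9), c(10, 15), c(16, 21))),
    atlases = list(n_types = 6, n_networks = 7, n_parcels = 64,
                   n_fine_parcels = 200),
    expression = list(n_genes = 360, n_specimens = 12,
                      specimen_noise_sd = 0.3),
    disorders = list(target_r = c(schizophrenia = -0.33, bipolar = -0.47,
                                  mdd = -0.54, adhd = -0.43, ocd = 0,
                                  asd = 0)),
    seed = 1)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys override [pipeline_config()] defaults.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Generate the full synthetic input bundle for a pipeline run
#'
#' Builds the mesh, atlases, cohort, planted vertexwise effect map (a focal
#' patch, optionally plus an area-level component coupled to one planted
#' expression gradient), per-subject thickness maps, expression panel and
#' disorder maps whose correlations with the true effect are planted.
#'
#' @param config a [pipeline_config].
#' @return list with all inputs plus `truth` (planted effect map, patch
#'   vertex set, planted correlations, expression gradients).
#' @export
synthesize_inputs <- function(config = pipeline_config()) {
  seed <- config$seed
  mesh <- make_sphere_mesh(config$mesh$subdivisions, config$mesh$radius,
                           config$mesh$medial_wall_frac)
  atlases <- make_atlases(mesh, config$atlases$n_types,
                          config$atlases$n_networks,
                          config$atlases$n_parcels,
                          config$atlases$n_fine_parcels, seed = seed)
  cs <- cohort_spec(n_subjects = config$cohort$n_subjects,
                    age_range = config$cohort$age_range,
                    sex_ratio = config$cohort$sex_ratio,
                    n_scanners = config$cohort$n_scanners,
                    n_pcs = config$cohort$n_pcs)
  subjects <- simulate_cohort(cs, seed = seed + 1)

  espec <- expression_spec(n_genes = config$expression$n_genes,
                           n_specimens = config$expression$n_specimens,
                           specimen_noise_sd =
                             config$expression$specimen_noise_sd)
  expr <- simulate_expression(espec, seed = seed + 2)

  # 11 expression areas placed at farthest-point seeds, mapped to the fine
  # parcellation by nearest great-circle centroid
  valid <- which(!mesh$medial_wall)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed + 3)
  area_seeds <- valid[farthest_point_sample(
    mesh$sphere[valid, , drop = FALSE], length(espec$areas))]
  area_centroids <- mesh$sphere[area_seeds, , drop = FALSE]
  rownames(area_centroids) <- espec$areas
  assignment <- map_areas_to_parcels(area_centroids, mesh,
                                     atlases$fine_parcels)

  # planted effect: focal patch, amplitude set by SNR = beta*SD(score)/noise_sd
  beta_amp <- config$effect$snr * config$effect$noise_sd /
    stats::sd(subjects$score)
  center <- valid[which.max(mesh$sphere[valid, 3])]
  d <- great_circle_dist(mesh$sphere,
                         mesh$sphere[center, , drop = FALSE])[, 1]
  patch <- d <= config$effect$patch_radius_mm & !mesh$medial_wall
  effect_map <- ifelse(patch, beta_amp, 0)
  if (isTRUE(config$effect$couple_expression)) {
    grad <- espec$component_gradients[config$effect$coupling_component, ]
    area_vals <- stats::setNames(grad[assignment$area], assignment$parcel)
    coupled <- unparcellate(area_vals, atlases$fine_parcels)
    coupled[!is.finite(coupled)] <- 0
    effect_map <- effect_map + beta_amp * coupled
  }
  effect_map[mesh$medial_wall] <- NaN

  es <- effect_spec(effect_map, noise_sd = config$effect$noise_sd,
                    noise_fwhm = config$effect$noise_fwhm)
  thickness <- simulate_thickness(mesh, subjects, es, seed = seed + 4)

  # disorder maps planted against the parcellated true effect
  ref <- parcellate(effect_map, atlases$parcels)
  disorder_maps <- simulate_disorder_maps(
    atlases$parcels, mesh, config$disorders$target_r, ref, seed = seed + 5)

  list(mesh = mesh, atlases = atlases, subjects = subjects,
       thickness = thickness, expression = expr,
       area_centroids = area_centroids, assignment = assignment,
       disorder_maps = disorder_maps,
       truth = list(effect_map = effect_map, patch = patch,
                    beta_amp = beta_amp,
                    target_r = config$disorders$target_r,
                    gradients = espec$component_gradients))
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Stages: synthesize inputs, fit the vertexwise model (whole cohort, age
#' groups, age-centering sweep summary), RFT cluster correction,
#' class-enrichment against type and network atlases, expression-component
#' correlations, disorder-map similarity, and age-group similarity. Returns
#' (and optionally writes, as JSON plus TSV/CSV intermediates) a single
#' report. Identical config and seed give an identical report.
#'
#' @param config a [pipeline_config].
#' @param out_dir optional output directory for the report and artifacts.
#' @param inputs optionally a pre-built bundle from [synthesize_inputs()]
#'   (must match the config).
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         inputs = NULL) {
  if (is.null(inputs)) inputs <- synthesize_inputs(config)
  seed <- config$seed
  n_perm <- config$nulls$n_perm
  mesh <- inputs$mesh

  spec <- design_spec(include_interactions = config$design$include_interactions,
                      contrast = config$design$contrast)
  design <- build_design(inputs$subjects, spec)
  fit <- fit_vertexwise(inputs$thickness, design)

  clusters <- rft_correct(fit, mesh, primary_p = config$rft$primary_p,
                          sign = config$rft$sign, alpha = config$rft$alpha)

  groups <- fit_age_groups(inputs$thickness, inputs$subjects,
                           bounds = config$age_groups$bounds, spec = spec)

  enrich_types <- class_enrichment(
    fit$tstat, inputs$atlases$types, mesh, n_perm = n_perm, seed = seed + 10,
    class_names = inputs$atlases$dictionaries$types)
  enrich_networks <- class_enrichment(
    fit$tstat, inputs$atlases$networks, mesh, n_perm = n_perm,
    seed = seed + 11, class_names = inputs$atlases$dictionaries$networks)

  scores <- score_components(inputs$expression)
  expr_cor <- correlate_expression_with_effect(
    scores, fit$tstat, inputs$assignment, inputs$atlases$fine_parcels,
    n_perm = n_perm, seed = seed + 12)

  effect_parcel <- parcellate(fit$tstat, inputs$atlases$parcels)
  centroids <- parcel_centroids(mesh, inputs$atlases$parcels)
  disorders <- disorder_similarity(effect_parcel, inputs$disorder_maps,
                                   centroids, n_perm = n_perm,
                                   seed = seed + 13)

  age_sim <- age_group_similarity(groups, fit,
                                  inputs$disorder_maps[, 1],
                                  inputs$atlases$parcels)

  report <- structure(list(
    config = unclass(config),
    glm = list(df = fit$df, columns = fit$columns,
               age_center = fit$age_center,
               n_vertices_fit = sum(is.finite(fit$tstat)),
               mean_t = mean(fit$tstat, na.rm = TRUE)),
    smoothness = list(fwhm = clusters$smoothness$fwhm,
                      total_resels = clusters$smoothness$total_resels),
    clusters = clusters$table,
    enrichment = list(types = enrich_types, networks = enrich_networks),
    expression = expr_cor,
    disorders = disorders,
    age_groups = list(sizes = attr(groups, "sizes"),
                      similarity = age_sim$table,
                      comparisons = lapply(age_sim$comparisons, function(cmp)
                        list(group1 = cmp$group1, group2 = cmp$group2,
                             z = cmp$comparison$z, p = cmp$comparison$p))),
    seed = seed), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mesh_obj(mesh, file.path(out_dir, "mesh.obj"))
    write_subjects_tsv(inputs$subjects, file.path(out_dir, "subjects.tsv"))
    write_maps_csv(cbind(beta = fit$beta, tstat = fit$tstat),
                   file.path(out_dir, "glm_maps.csv"))
    utils::write.table(clusters$table, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(disorders, file.path(out_dir, "disorders.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE,
                         dataframe = "rows")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  GLM: df = %d, %d vertices\n", x$glm$df, x$glm$n_vertices_fit))
  cat(sprintf("  smoothness: FWHM = %.2f mm (%.1f resels)\n",
              x$smoothness$fwhm, x$smoothness$total_resels))
  cat(sprintf("  clusters: %d (%d significant)\n", nrow(x$clusters),
              sum(x$clusters$significant)))
  cat(sprintf("  disorders significant (spin): %d of %d\n",
              sum(x$disorders$sig_spin), nrow(x$disorders)))
  invisible(x)
}

#' Dice overlap of two vertex sets
#' @param a,b logical vertex masks.
#' @return `2|a&b| / (|a|+|b|)`; `NaN` if both sets are empty.
#' @export
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
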