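# shared small fixtures, built once per test run
fix <- local({
  mesh3 <- make_sphere_mesh(3)                       # 642 vertices, 5% wall
  mesh2 <- make_sphere_mesh(2, medial_wall_frac = 0) # 162 vertices, no wall
  list(mesh3 = mesh3, mesh2 = mesh2,
       atlases3 = make_atlases(mesh3, seed = 99))
})

# small deterministic cohort reused across GLM tests
small_cohort <- function(n = 40, n_scanners = 2, seed = 5) {
  simulate_cohort(cohort_spec(n_subjects = n, n_scanners = n_scanners),
                  seed = seed)
}

# smooth random map on a mesh (NaN on medial wall)
smooth_map <- function(mesh, fwhm = 30, seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- rep(NaN, nrow(mesh$vertices))
  x[!mesh$medial_wall] <- rnorm(sum(!mesh$medial_wall))
  smooth_surface(x, mesh, fwhm)
}
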