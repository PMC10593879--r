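#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, via [stats::p.adjust()])
#' with significance flags at the chosen q.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @param q FDR level.
#' @return data.frame with `p`, `p_fdr`, `significant`.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) stop("empty p-value vector")
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_fdr = adj, significant = adj < q)
}

#' Similarity of an effect map with disorder effect-size maps
#'
#' Pearson correlation of a parcellated effect map with each disorder's
#' Cohen's d map on pairwise-complete parcels, spin-permutation two-tailed
#' p per disorder (spinning the effect map, shared spins across disorders)
#' and Benjamini-Hochberg FDR across disorders. Significance is flagged both
#' at `p_spin < .025` (two-tailed spin criterion) and `p_fdr < .05`.
#'
#' @param effect named numeric parcel map (the score-effect t map averaged
#'   into atlas parcels).
#' @param disorder_maps parcel x disorder matrix of Cohen's d maps on the
#'   same atlas.
#' @param centroids parcel centroids on the registration sphere.
#' @param n_perm number of spins.
#' @param seed integer RNG seed.
#' @param spin_alpha two-tailed spin significance threshold.
#' @param fdr_q FDR level.
#' @return data.frame per disorder: `disorder`, `r`, `p_spin`, `p_fdr`,
#'   `sig_spin`, `sig_fdr`, `n_parcels`.
#' @export
disorder_similarity <- function(effect, disorder_maps, centroids,
                                n_perm = 10000, seed = 1,
                                spin_alpha = 0.025, fdr_q = 0.05) {
  disorder_maps <- as.matrix(disorder_maps)
  if (nrow(disorder_maps) != length(effect))
    stop("effect map and disorder maps use different atlases")
  spun <- spin_parcel(effect, centroids, n_perm, seed)
  rows <- lapply(seq_len(ncol(disorder_maps)), function(j) {
    y <- disorder_maps[, j]
    ok <- is.finite(effect) & is.finite(y)
    if (sum(ok) < 3) stop("fewer than 3 complete parcels for disorder ", j)
    obs <- stats::cor(effect[ok], y[ok])
    nulls <- apply(spun, 2, function(xs) {
      k <- is.finite(xs) & is.finite(y)
      if (sum(k) < 3 || stats::sd(xs[k]) == 0) return(NA_real_)
      stats::cor(xs[k], y[k])
    })
    data.frame(disorder = colnames(disorder_maps)[j] %||% paste0("d", j),
               r = obs, p_spin = perm_pvalue(obs, nulls, "two"),
               n_parcels = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p_spin, q = fdr_q)
  out$p_fdr <- fdr$p_fdr
  out$sig_spin <- out$p_spin < spin_alpha
  out$sig_fdr <- out$p_fdr < fdr_q
  out[, c("disorder", "r", "p_spin", "p_fdr", "sig_spin", "sig_fdr",
          "n_parcels")]
}

#' Compare two dependent overlapping correlations (Zou CI and Steiger z)
#'
#' For correlations r12 and r13 sharing variable 1 and measured on the same
#' n units: Zou's 95% confidence interval for r12 - r13 (asymmetric, via
#' Fisher-z back-transformed single-correlation limits and the correlation
#' between the two estimates) and Steiger's z test (Williams modification,
#' using the mean correlation). The correlation triple must form a positive
#' semidefinite matrix.
#'
#' @param r12,r13 the two correlations being compared.
#' @param r23 correlation between variables 2 and 3.
#' @param n number of units.
#' @param conf confidence level for the Zou interval.
#' @return list of class `corr_comparison`: `method = "zou_ci+steiger"`,
#'   `diff`, `ci` (length 2), `includes_zero`, `z` (Steiger), `p`
#'   (two-tailed), `n`.
#' @export
compare_correlations_dependent <- function(r12, r13, r23, n, conf = 0.95) {
  stopifnot(abs(r12) < 1, abs(r13) < 1, abs(r23) <= 1, n >= 4)
  det3 <- 1 + 2 * r12 * r13 * r23 - r12^2 - r13^2 - r23^2
  if (det3 < -1e-12) stop("inconsistent correlation triple (not PSD)")
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  se <- 1 / sqrt(n - 3)
  lim <- function(r) tanh(atanh(r) + c(-1, 1) * zcrit * se)
  l1u1 <- lim(r12); l2u2 <- lim(r13)
  corr_rr <- ((r23 - 0.5 * r12 * r13) * (1 - r12^2 - r13^2 - r23^2) +
                r23^3) / ((1 - r12^2) * (1 - r13^2))
  dd <- r12 - r13
  L <- dd - sqrt((r12 - l1u1[1])^2 + (l2u2[2] - r13)^2 -
                   2 * corr_rr * (r12 - l1u1[1]) * (l2u2[2] - r13))
  U <- dd + sqrt((l1u1[2] - r12)^2 + (r13 - l2u2[1])^2 -
                   2 * corr_rr * (l1u1[2] - r12) * (r13 - l2u2[1]))
  rbar <- (r12 + r13) / 2
  sbar <- (r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
             (1 - 2 * rbar^2 - r23^2)) / (1 - rbar^2)^2
  z <- sqrt(n - 3) * (atanh(r12) - atanh(r13)) / sqrt(2 - 2 * sbar)
  structure(list(method = "zou_ci+steiger", r12 = r12, r13 = r13, r23 = r23,
                 n = n, diff = dd, ci = c(L, U),
                 includes_zero = L <= 0 && U >= 0, z = z,
                 p = 2 * stats::pnorm(-abs(z))),
            class = "corr_comparison")
}

#' Compare two independent correlations (Fisher z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`; both the
#' one-tailed and two-tailed p are reported. Antisymmetric in its
#' arguments.
#'
#' @param r1,r2 the correlations; |r| < 1.
#' @param n1,n2 sample sizes (>= 4).
#' @return list of class `corr_comparison`: `method = "fisher_z"`, `z`,
#'   `p` (two-tailed), `p_one_tailed`, `n`.
#' @export
compare_correlations_independent <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 >= 4, n2 >= 4)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(method = "fisher_z", r1 = r1, r2 = r2, n = c(n1, n2),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 p_one_tailed = stats::pnorm(-abs(z))),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  if (x$method == "fisher_z")
    cat(sprintf("corr_comparison (Fisher z): z = %.3f, p = %.4g\n", x$z, x$p))
  else
    cat(sprintf(
      "corr_comparison (Zou CI / Steiger): diff = %.3f, CI [%.3f, %.3f], z = %.3f, p = %.4g\n",
      x$diff, x$ci[1], x$ci[2], x$z, x$p))
  invisible(x)
}

#' Age-group map similarity and trajectory
#'
#' Correlates each age group's score-effect map with the whole-cohort map
#' and with a disorder (case-control Cohen's d) map at the parcel level,
#' then compares the group-vs-disorder correlations pairwise. The default
#' comparison is the independent Fisher z (matching the plain z/p reporting
#' style of developmental analyses); the dependent Zou/Steiger method is
#' available since group maps share parcels.
#'
#' @param group_results named list of `glm_result` from [fit_age_groups()].
#' @param whole `glm_result` for the whole cohort.
#' @param disorder_map named numeric parcel map (e.g. the schizophrenia
#'   Cohen's d map).
#' @param labels per-vertex parcel labels of the comparison atlas.
#' @param method `"fisher_z_independent"` or `"zou_steiger_dependent"` for
#'   the pairwise comparisons.
#' @return list with `table` (per group: r vs whole, r vs disorder,
#'   n_parcels) and `comparisons` (pairwise group contrasts of the
#'   disorder-map correlation).
#' @export
age_group_similarity <- function(group_results, whole, disorder_map, labels,
                                 method = c("fisher_z_independent",
                                            "zou_steiger_dependent")) {
  method <- match.arg(method)
  whole_p <- parcellate(whole$tstat, labels)
  ids <- names(whole_p)
  group_p <- lapply(group_results, function(g) parcellate(g$tstat, labels))
  dm <- disorder_map[ids]
  tab <- do.call(rbind, lapply(names(group_results), function(g) {
    gp <- group_p[[g]][ids]
    ok_w <- is.finite(gp) & is.finite(whole_p)
    ok_d <- is.finite(gp) & is.finite(dm)
    data.frame(group = g,
               r_whole = stats::cor(gp[ok_w], whole_p[ok_w]),
               r_disorder = stats::cor(gp[ok_d], dm[ok_d]),
               n_parcels = sum(ok_d), stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(nrow(tab), 2)
  comparisons <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cmp <- if (method == "fisher_z_independent") {
      compare_correlations_independent(tab$r_disorder[i], tab$n_parcels[i],
                                       tab$r_disorder[j], tab$n_parcels[j])
    } else {
      gi <- group_p[[tab$group[i]]][ids]; gj <- group_p[[tab$group[j]]][ids]
      ok <- is.finite(gi) & is.finite(gj) & is.finite(dm)
      compare_correlations_dependent(
        r12 = stats::cor(dm[ok], gi[ok]), r13 = stats::cor(dm[ok], gj[ok]),
        r23 = stats::cor(gi[ok], gj[ok]), n = sum(ok))
    }
    list(group1 = tab$group[i], group2 = tab$group[j], comparison = cmp)
  })
  list(table = tab, comparisons = comparisons)
}
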