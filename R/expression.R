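#' Cell-type specificity-weighted expression score per area
#'
#' For one cell type: weight each gene's (log-scale) expression by its
#' specificity score, average across genes within each (area, specimen)
#' cell (`sum(w_g x_gas) / sum(w_g)`), then average across specimens within
#' area. Genes with weights but absent from the panel are dropped with a
#' warning. Scaling all weights by a constant leaves scores unchanged.
#'
#' @param panel tidy expression data.frame with columns `gene`, `area`,
#'   `specimen`, `value`.
#' @param weights data.frame with columns `gene`, `cell_type`,
#'   `specificity` (non-negative).
#' @param cell_type the cell type whose weights to use.
#' @return Named numeric vector: one score per area.
#' @export
score_celltype <- function(panel, weights, cell_type) {
  w <- weights[weights$cell_type == cell_type, , drop = FALSE]
  if (!nrow(w)) stop("no weights for cell type: ", cell_type)
  if (any(w$specificity < 0)) stop("negative specificity weights")
  missing <- setdiff(w$gene, unique(panel$gene))
  if (length(missing)) {
    warning(length(missing), " weighted genes absent from panel; dropped")
    w <- w[!w$gene %in% missing, , drop = FALSE]
  }
  if (sum(w$specificity) == 0) stop("total specificity weight is zero")
  sub <- panel[panel$gene %in% w$gene, , drop = FALSE]
  sub$w <- w$specificity[match(sub$gene, w$gene)]
  num <- tapply(sub$value * sub$w, list(sub$area, sub$specimen), sum)
  den <- tapply(sub$w, list(sub$area, sub$specimen), sum)
  per_as <- num / den                      # area x specimen weighted means
  rowMeans(per_as, na.rm = TRUE)           # then mean across specimens
}

#' Marker-gene compartment expression score per area
#'
#' Unweighted mean expression of a neuron-compartment marker-gene set per
#' (area, specimen), then mean across specimens — equivalent to
#' [score_celltype()] with indicator weights on the marker set.
#'
#' @param panel tidy expression data.frame (`gene`, `area`, `specimen`,
#'   `value`).
#' @param markers character vector of marker genes (genes absent from the
#'   panel are dropped with a warning).
#' @return Named numeric vector: one score per area.
#' @export
score_compartment <- function(panel, markers) {
  if (!length(markers)) stop("empty marker set")
  w <- data.frame(gene = unique(markers), cell_type = ".markers",
                  specificity = 1, stringsAsFactors = FALSE)
  score_celltype(panel, w, ".markers")
}

#' Score all six neuropil components of a synthetic expression bundle
#'
#' Convenience wrapper over [score_celltype()] (glial cell types from the
#' specificity table) and [score_compartment()] (neuron compartments from
#' the marker lists).
#'
#' @param expr a list with `panel`, `weights`, `markers` as produced by
#'   [simulate_expression()] (or assembled from files).
#' @return area x component matrix of scores.
#' @export
score_components <- function(expr) {
  cts <- unique(expr$weights$cell_type)
  s1 <- lapply(cts, function(ct) score_celltype(expr$panel, expr$weights, ct))
  s2 <- lapply(expr$markers, function(g) score_compartment(expr$panel, g))
  out <- do.call(cbind, c(s1, s2))
  colnames(out) <- c(cts, names(expr$markers))
  out
}

#' Correlate component expression scores with an effect map
#'
#' Extracts area-average effect values via the area-to-fine-parcel
#' assignment, correlates them with each component's per-area expression
#' score (product-moment), and assesses significance with random
#' reassignment permutation tests (spins are unavailable at a handful of
#' areas).
#'
#' @param scores area x component matrix from [score_components()].
#' @param tmap vertexwise effect (t) map.
#' @param assignment data.frame from [map_areas_to_parcels()] (`area`,
#'   `parcel`).
#' @param fine_labels per-vertex labels of the fine parcellation.
#' @param n_perm permutations for the reassignment test.
#' @param seed integer RNG seed.
#' @return data.frame per component: `component`, `r`, `p_perm`, `n_areas`;
#'   attribute `"area_effect"` holds the per-area effect vector.
#' @export
correlate_expression_with_effect <- function(scores, tmap, assignment,
                                             fine_labels, n_perm = 10000,
                                             seed = 1) {
  pm <- parcellate(tmap, fine_labels, stat = "mean")
  eff <- pm[as.character(assignment$parcel)]
  names(eff) <- assignment$area
  if (sum(is.finite(eff)) < 3) stop("fewer than 3 areas with valid effect")
  if (stats::sd(eff[is.finite(eff)]) == 0)
    stop("effect map constant across areas; correlation undefined")
  scores <- scores[assignment$area, , drop = FALSE]
  rows <- lapply(colnames(scores), function(comp) {
    res <- reassignment_test_correlation(scores[, comp], eff,
                                         n_perm = n_perm, seed = seed)
    data.frame(component = comp, r = res$observed, p_perm = res$p,
               n_areas = res$n_units, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "area_effect") <- eff
  out
}
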