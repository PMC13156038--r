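#' Dominance analysis of a regional map
#'
#' Decomposes the R-squared of an ordinary least squares regression of
#' `y` on all predictors into per-predictor total dominances: for every
#' one of the `2^p - 1` nonempty predictor subsets the subset R-squared
#' is computed, and a predictor's total dominance is the average, over
#' subset sizes, of its mean R-squared increment when added to subsets
#' lacking it. Total dominances are nonnegative for well-posed designs
#' and sum exactly to the full-model R-squared, so dividing by that sum
#' gives each predictor's relative contribution in percent. This equals
#' the Shapley decomposition of the full-model R-squared over
#' predictors.
#'
#' Subset R-squared values are obtained by sweeping a single precomputed
#' cross-product matrix of `[X y]` rather than refitting from raw data,
#' which keeps the exhaustive enumeration fast enough for 16 predictors
#' and dozens of targets.
#'
#' @param X Predictors (a [regional_matrix] or plain matrix), `p <=
#'   max_predictors` columns, full column rank, `n > p + 1` rows.
#' @param y Response map (one-column [regional_matrix] or vector).
#' @param max_predictors Guard on the exhaustive `2^p` enumeration.
#' @return An object of class `dominance_result` with fields
#'   `predictors`, `total_dominance`, `relative_contribution` (percent),
#'   `full_r2`, `adjusted_r2` and `n_submodels`.
#' @export
dominance_analysis <- function(X, y, max_predictors = 20) {
  xm <- rm_values(X)
  yv <- rm_map(y)
  reject_missing(xm, "X")
  reject_missing(yv, "y")
  p <- ncol(xm)
  n <- nrow(xm)
  if (p > max_predictors) {
    stop("p = ", p, " exceeds the exhaustive-enumeration bound (",
         max_predictors, "); raise `max_predictors` deliberately if the ",
         "2^p cost is acceptable", call. = FALSE)
  }
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  if (is.null(colnames(xm))) colnames(xm) <- paste0("x", seq_len(p))
  r2 <- subset_r2(xm, matrix(yv, ncol = 1))[, 1]
  build_dominance_result(r2, colnames(xm), n)
}

# R-squared of every predictor subset for one or more targets, from the
# cross-product matrix of centered [X Y]. Returns a (2^p) x q matrix
# indexed by subset bitmask + 1 (row 1 = empty model, R^2 = 0).
subset_r2 <- function(xm, ym) {
  p <- ncol(xm)
  q <- ncol(ym)
  xc <- sweep(xm, 2, colMeans(xm))
  yc <- sweep(ym, 2, colMeans(ym))
  cxx <- crossprod(xc)
  cxy <- crossprod(xc, yc)
  cyy <- colSums(yc^2)
  if (any(cyy == 0)) stop("a target has zero variance", call. = FALSE)
  full_chol <- tryCatch(chol(cxx), error = function(e) {
    stop("rank-deficient full design: ", conditionMessage(e),
         call. = FALSE)
  })
  n_masks <- bitwShiftL(1L, p)
  r2 <- matrix(0, n_masks, q)
  bit_vals <- bitwShiftL(1L, 0:(p - 1))
  for (mask in seq_len(n_masks - 1)) {
    idx <- which(bitwAnd(mask, bit_vals) > 0L)
    b <- solve(cxx[idx, idx, drop = FALSE], cxy[idx, , drop = FALSE])
    r2[mask + 1L, ] <- colSums(cxy[idx, , drop = FALSE] * b) / cyy
  }
  r2
}

build_dominance_result <- function(r2, predictors, n) {
  p <- length(predictors)
  n_masks <- length(r2)
  bit_vals <- bitwShiftL(1L, 0:(p - 1))
  masks <- 0:(n_masks - 1)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bit_vals) > 0L),
                  integer(1))
  total <- numeric(p)
  for (k in seq_len(p)) {
    without <- masks[bitwAnd(masks, bit_vals[k]) == 0L]
    inc <- r2[without + bit_vals[k] + 1L] - r2[without + 1L]
    per_size <- tapply(inc, sizes[without + 1L], mean)
    total[k] <- mean(per_size)
  }
  full_r2 <- r2[n_masks]
  adj_r2 <- 1 - (1 - full_r2) * (n - 1) / (n - p - 1)
  structure(list(predictors = predictors,
                 total_dominance = stats::setNames(total, predictors),
                 relative_contribution =
                   stats::setNames(100 * total / full_r2, predictors),
                 full_r2 = full_r2,
                 adjusted_r2 = adj_r2,
                 n_submodels = n_masks - 1L,
                 n = n),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("<dominance_result> %d predictors, R2 = %.3f (adj %.3f), %d submodels\n",
              length(x$predictors), x$full_r2, x$adjusted_r2,
              x$n_submodels))
  print(round(x$relative_contribution, 2))
  invisible(x)
}

#' Colocalization table: one dominance analysis per target map
#'
#' Runs [dominance_analysis()] of every neuropeptide receptor map on the
#' shared set of neurotransmitter receptor maps. The subset R-squared
#' sweep is shared across targets (the predictor set is identical), so
#' the whole table costs little more than a single dominance run. Rows
#' are sorted by adjusted R-squared, descending.
#'
#' @param neurotransmitter_maps Predictor maps (regions x p).
#' @param neuropeptide_maps Target maps (regions x q), same regions.
#' @param max_predictors Passed to the enumeration guard.
#' @return An object of class `colocalization_table`: a data frame with
#'   columns `target`, `full_r2`, `adjusted_r2` and one relative
#'   contribution column (percent) per predictor; the per-target
#'   [dominance_analysis] results are in `attr(, "results")`.
#' @export
colocalization_table <- function(neurotransmitter_maps, neuropeptide_maps,
                                 max_predictors = 20) {
  xm <- rm_values(neurotransmitter_maps)
  ym <- rm_values(neuropeptide_maps)
  reject_missing(xm, "neurotransmitter maps")
  reject_missing(ym, "neuropeptide maps")
  if (nrow(xm) != nrow(ym)) {
    stop("predictor and target maps must share regions", call. = FALSE)
  }
  p <- ncol(xm)
  if (p > max_predictors) {
    stop("p = ", p, " exceeds the enumeration bound", call. = FALSE)
  }
  if (is.null(colnames(xm))) colnames(xm) <- paste0("x", seq_len(p))
  if (is.null(colnames(ym))) colnames(ym) <- paste0("y", seq_len(ncol(ym)))
  r2 <- subset_r2(xm, ym)
  results <- lapply(seq_len(ncol(ym)), function(j) {
    build_dominance_result(r2[, j], colnames(xm), nrow(xm))
  })
  names(results) <- colnames(ym)
  tab <- data.frame(
    target = colnames(ym),
    full_r2 = vapply(results, `[[`, numeric(1), "full_r2"),
    adjusted_r2 = vapply(results, `[[`, numeric(1), "adjusted_r2"),
    t(vapply(results, `[[`, numeric(p), "relative_contribution")),
    check.names = FALSE, row.names = NULL)
  ord <- order(tab$adjusted_r2, decreasing = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, results = results[ord],
            class = c("colocalization_table", "data.frame"))
}

#' Ionotropic versus metabotropic colocalization contrast
#'
#' For each target row of a [colocalization_table()], averages the
#' relative contributions of the predictors within each receptor class,
#' then compares the two resulting per-target vectors with an unpaired
#' two-sample two-tailed t-test (pooled variance, `df = 2k - 2` for `k`
#' targets). A paired alternative is available behind `paired = TRUE`.
#'
#' @param table A `colocalization_table`.
#' @param labels Named character vector mapping every predictor to
#'   `"ionotropic"` or `"metabotropic"`.
#' @param paired Use a paired t-test instead of the default unpaired.
#' @return List with `t`, `df`, `p`, and the per-class mean
#'   contribution vectors `ionotropic` and `metabotropic`. The sign of
#'   `t` is `mean(ionotropic) - mean(metabotropic)`.
#' @export
class_contrast <- function(table, labels, paired = FALSE) {
  stopifnot(inherits(table, "colocalization_table"))
  results <- attr(table, "results")
  predictors <- results[[1]]$predictors
  missing_lab <- setdiff(predictors, names(labels))
  if (length(missing_lab) > 0) {
    stop("unlabeled predictor(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  }
  labels <- labels[predictors]
  bad <- setdiff(unique(labels), c("ionotropic", "metabotropic"))
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (cls in c("ionotropic", "metabotropic")) {
    if (!any(labels == cls)) {
      stop("no predictors labeled `", cls, "`", call. = FALSE)
    }
  }
  if (nrow(table) < 2) stop("need at least two target rows", call. = FALSE)
  class_mean <- function(cls) {
    vapply(results, function(r) {
      mean(r$relative_contribution[labels == cls])
    }, numeric(1))
  }
  ion <- class_mean("ionotropic")
  met <- class_mean("metabotropic")
  tt <- stats::t.test(ion, met, paired = paired, var.equal = !paired)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ionotropic = ion, metabotropic = met)
}

#' Map-map correlation with a spatial-autocorrelation-preserving null
#'
#' Spearman rank correlation between two regional maps, with a p-value
#' from the empirical null distribution of correlations between `map_b`
#' and variogram-matched surrogates of `map_a` (two-sided, add-one
#' estimator). Because the statistic is a rank correlation it is
#' invariant to strictly monotone transforms of either map.
#'
#' @param map_a,map_b One-column maps on the same atlas.
#' @param dist Distance matrix.
#' @param n_surrogates Number of surrogate maps for the null.
#' @param seed Integer seed.
#' @param engine Optional precomputed variogram engine (shared across
#'   calls on the same distance matrix).
#' @return List with `rho`, `p`, and the vector of `null_rhos`.
#' @export
corr_with_null <- function(map_a, map_b, dist, n_surrogates = 1000,
                           seed = 1, engine = NULL) {
  a <- rm_map(map_a)
  b <- rm_map(map_b)
  rho <- stats::cor(a, b, method = "spearman")
  ens <- variogram_surrogates(a, dist, n = n_surrogates, seed = seed,
                              engine = engine)
  null_rhos <- drop(stats::cor(ens$members, b, method = "spearman"))
  list(rho = rho,
       p = empirical_pvalue(rho, null_rhos, tail = "two_sided"),
       null_rhos = null_rhos)
}

#' Map-map correlation with a matched-gene null
#'
#' Companion to [corr_with_null()] using the matched-gene null instead:
#' the observed Spearman correlation between a target gene's map and
#' `map_b` is compared with correlations between `map_b` and matched
#' null genes drawn by [matched_gene_nulls()].
#'
#' @inheritParams matched_gene_nulls
#' @param map_b The fixed comparison map.
#' @return List with `rho`, `p`, and `null_rhos`.
#' @export
corr_with_gene_nulls <- function(target_gene, pool, map_b, dist,
                                 n_draws = 1000,
                                 candidates_per_draw = 100, seed = 1,
                                 exclude = character(), scheme = "knn",
                                 k = 10) {
  v <- rm_values(pool)
  b <- rm_map(map_b)
  ens <- matched_gene_nulls(target_gene, pool, exclude = exclude,
                            n_draws = n_draws,
                            candidates_per_draw = candidates_per_draw,
                            dist = dist, seed = seed, scheme = scheme,
                            k = k)
  rho <- stats::cor(v[, target_gene], b, method = "spearman")
  null_rhos <- drop(stats::cor(v[, ens$members, drop = FALSE], b,
                               method = "spearman"))
  list(rho = rho,
       p = empirical_pvalue(rho, null_rhos, tail = "two_sided"),
       null_rhos = null_rhos)
}
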