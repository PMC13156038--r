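#' Spatial weight matrices
#'
#' Row-normalized spatial weights used by Moran's I. The default scheme
#' links every region to its `k` nearest neighbours by centroid
#' distance; `"inverse_distance"` weights all other regions by `1/d`.
#' The choice of scheme is a modelling decision that the matched-gene
#' ranking inherits, so it is exposed rather than hidden.
#'
#' @param dist Symmetric distance matrix (see [pairwise_distances()]).
#' @param scheme Weight scheme.
#' @param k Number of nearest neighbours for the `"knn"` scheme.
#' @return Row-normalized `n x n` weight matrix with zero diagonal.
#' @export
spatial_weights <- function(dist, scheme = c("knn", "inverse_distance"),
                            k = 10) {
  scheme <- match.arg(scheme)
  n <- nrow(dist)
  if (n < 2) stop("need at least two regions", call. = FALSE)
  w <- matrix(0, n, n)
  if (scheme == "knn") {
    k <- check_count(k, "k", min = 1)
    if (k >= n) stop("k must be smaller than the number of regions",
                     call. = FALSE)
    for (i in seq_len(n)) {
      nb <- order(dist[i, -i])[seq_len(k)]
      nb <- seq_len(n)[-i][nb]
      w[i, nb] <- 1
    }
  } else {
    w <- 1 / dist
    diag(w) <- 0
    w[!is.finite(w)] <- 0
  }
  rs <- rowSums(w)
  if (any(rs == 0)) stop("empty neighborhood for some region",
                         call. = FALSE)
  w / rs
}

#' Moran's I spatial autocorrelation
#'
#' Global Moran's I of a regional map under row-normalized spatial
#' weights: `I = sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' map. Values near `-1/(n-1)` indicate no spatial structure.
#'
#' @param map A one-column [regional_matrix] or numeric vector.
#' @param dist Distance matrix, or a precomputed weight matrix via
#'   `weights`.
#' @param scheme,k Passed to [spatial_weights()].
#' @param weights Optional precomputed row-normalized weight matrix;
#'   overrides `dist`/`scheme`/`k`.
#' @return Moran's I, approximately in `[-1, 1]`.
#' @export
morans_i <- function(map, dist = NULL, scheme = c("knn",
                                                  "inverse_distance"),
                     k = 10, weights = NULL) {
  x <- rm_map(map)
  reject_missing(x, "map")
  if (stats::sd(x) == 0) stop("map has zero variance", call. = FALSE)
  if (is.null(weights)) {
    if (is.null(dist)) stop("supply `dist` or `weights`", call. = FALSE)
    weights <- spatial_weights(dist, match.arg(scheme), k)
  }
  z <- x - mean(x)
  sum(weights * tcrossprod(z)) / sum(z^2)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Sup-norm distance between the empirical distribution functions of two
#' samples; the distribution-matching criterion of the matched-gene null.
#'
#' @param x,y Nonempty numeric samples.
#' @return A value in `[0, 1]`.
#' @export
ks_statistic <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  sx <- sort(x)
  sy <- sort(y)
  grid <- c(sx, sy)
  max(abs(findInterval(grid, sx) / length(x) -
            findInterval(grid, sy) / length(y)))
}

#' Empirical p-value against a null sample
#'
#' Add-one estimator `p = (k + 1) / (m + 1)` where `k` counts null
#' statistics at least as extreme as the observed one, so `p = 0` is
#' impossible and the smallest attainable value is `1/(m + 1)`. The
#' default two-sided rule measures extremity as absolute deviation from
#' the null mean; `two_sided = "doubled_tail"` instead doubles the
#' smaller one-sided p (capped at 1).
#'
#' @param observed Observed statistic.
#' @param nulls Nonempty numeric vector of null statistics.
#' @param tail `"two_sided"`, `"greater"` or `"less"`.
#' @param two_sided Extremity rule for the two-sided case.
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, nulls,
                             tail = c("two_sided", "greater", "less"),
                             two_sided = c("mean_deviation",
                                           "doubled_tail")) {
  tail <- match.arg(tail)
  two_sided <- match.arg(two_sided)
  m <- length(nulls)
  if (m == 0) stop("`nulls` must be nonempty", call. = FALSE)
  if (tail == "greater") {
    (sum(nulls >= observed) + 1) / (m + 1)
  } else if (tail == "less") {
    (sum(nulls <= observed) + 1) / (m + 1)
  } else if (two_sided == "mean_deviation") {
    mu <- mean(nulls)
    (sum(abs(nulls - mu) >= abs(observed - mu)) + 1) / (m + 1)
  } else {
    p_hi <- (sum(nulls >= observed) + 1) / (m + 1)
    p_lo <- (sum(nulls <= observed) + 1) / (m + 1)
    min(1, 2 * min(p_hi, p_lo))
  }
}

#' Smoothed empirical variogram
#'
#' Kernel-smoothed semivariance `gamma(h)` of a regional map as a
#' function of inter-centroid distance: pairwise half squared
#' differences are averaged with Gaussian kernel weights centred on
#' `n_lags` equally spaced lags up to the `max_quantile` quantile of
#' pairwise distances (long-lag pairs are sparse and noisy, so the tail
#' is not fitted).
#'
#' @param map One-column [regional_matrix] or numeric vector with
#'   nonzero variance.
#' @param dist Distance matrix.
#' @param n_lags Number of evaluation lags (`>= 2`).
#' @param bandwidth Gaussian kernel bandwidth in millimetres; defaults
#'   to three times the lag spacing.
#' @param max_quantile Distance quantile bounding the largest lag.
#' @return An object of class `variogram` with fields `lags`, `gamma`,
#'   `smoothing_bandwidth` and `n_lags`.
#' @export
empirical_variogram <- function(map, dist, n_lags = 25, bandwidth = NULL,
                                max_quantile = 0.25) {
  x <- rm_map(map)
  reject_missing(x, "map")
  if (stats::sd(x) == 0) stop("map has zero variance", call. = FALSE)
  eng <- variogram_engine(dist, n_lags = n_lags, bandwidth = bandwidth,
                          max_quantile = max_quantile)
  structure(list(lags = eng$lags,
                 gamma = engine_variogram(eng, x),
                 smoothing_bandwidth = eng$bandwidth,
                 n_lags = eng$n_lags),
            class = "variogram")
}

# Precomputes everything about a distance matrix that surrogate
# generation reuses across maps and draws: pair indices, the lag-kernel
# weight matrix, and row-normalized Gaussian smoothing operators at the
# candidate scales. Building this once makes large ensembles cheap.
variogram_engine <- function(dist, n_lags = 25, bandwidth = NULL,
                             max_quantile = 0.25, scales = NULL,
                             n_scales = 8) {
  n_lags <- check_count(n_lags, "n_lags", min = 2)
  n <- nrow(dist)
  ut <- which(upper.tri(dist))
  dv <- dist[ut]
  d_pos <- dv[dv > 0]
  if (length(d_pos) == 0) stop("all centroids coincide", call. = FALSE)
  lag_max <- stats::quantile(dv, max_quantile, names = FALSE)
  lags <- seq(min(d_pos), max(lag_max, min(d_pos) * 1.01),
              length.out = n_lags)
  # a bandwidth of several lag spacings keeps single-realization
  # variogram estimates smooth enough to fit surrogates against
  if (is.null(bandwidth)) bandwidth <- 3 * (lags[2] - lags[1])
  if (bandwidth <= 0) bandwidth <- max(min(d_pos) / 2, 1e-8)
  w <- exp(-0.5 * ((matrix(dv, n_lags, length(dv), byrow = TRUE) -
                      lags) / bandwidth)^2)
  w <- w / rowSums(w)
  if (is.null(scales)) {
    scales <- exp(seq(log(min(d_pos)),
                      log(max(max(dv) / 3, min(d_pos) * 2)),
                      length.out = n_scales))
  }
  smoothers <- lapply(scales, function(s) {
    sm <- exp(-0.5 * (dist / s)^2)
    sm / rowSums(sm)
  })
  pr <- arrayInd(ut, dim(dist))
  list(n = n, pair_i = pr[, 1], pair_j = pr[, 2], lags = lags,
       bandwidth = bandwidth, n_lags = n_lags, lag_weights = w,
       scales = scales, smoothers = smoothers,
       smoother_stack = do.call(rbind, smoothers))
}

# Batched variogram: columns of `xs` are maps, result n_lags x ncol.
engine_variogram_multi <- function(eng, xs) {
  sq <- 0.5 * (xs[eng$pair_i, , drop = FALSE] -
                 xs[eng$pair_j, , drop = FALSE])^2
  eng$lag_weights %*% sq
}

engine_variogram <- function(eng, x) {
  sq <- 0.5 * (x[eng$pair_i] - x[eng$pair_j])^2
  drop(eng$lag_weights %*% sq)
}

#' Variogram-matched surrogate maps
#'
#' Generates surrogate maps preserving both the value distribution and
#' the spatial autocorrelation of a target map. Each surrogate is built
#' by (1) randomly permuting the target values, (2) smoothing the
#' permutation with a Gaussian kernel at several candidate scales and
#' mixing it with independent white noise, choosing the scale and mixing
#' ratios by least squares between the candidate's variogram and the
#' target's, and (3) re-ranking the result onto the original value
#' distribution so the surrogate is an exact permutation of the target
#' values.
#'
#' @param map Target map (one-column [regional_matrix] or vector).
#' @param dist Distance matrix.
#' @param n Number of surrogates (`>= 1`).
#' @param seed Integer seed.
#' @param n_lags,bandwidth,max_quantile,scales Variogram and smoothing
#'   controls (see [empirical_variogram()] and `variogram_engine`).
#' @param engine Optional precomputed engine (internal use) to share
#'   across many calls on the same distance matrix.
#' @return A `null_ensemble` whose `members` is an `n_regions x n`
#'   matrix of surrogate maps.
#' @export
variogram_surrogates <- function(map, dist, n, seed = 1, n_lags = 25,
                                 bandwidth = NULL, max_quantile = 0.25,
                                 scales = NULL, engine = NULL) {
  x <- rm_map(map)
  reject_missing(x, "map")
  if (stats::sd(x) == 0) stop("map has zero variance", call. = FALSE)
  n <- check_count(n, "n", min = 1)
  if (is.null(engine)) {
    engine <- variogram_engine(dist, n_lags = n_lags,
                               bandwidth = bandwidth,
                               max_quantile = max_quantile,
                               scales = scales)
  }
  gamma_t <- engine_variogram(engine, x)
  sorted_x <- sort(x)
  members <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      surrogate_draw_one(x, engine, gamma_t, sorted_x)
    }, numeric(engine$n))
  })
  null_ensemble("surrogate_maps", members, seed = seed,
                params = list(n_lags = engine$n_lags,
                              bandwidth = engine$bandwidth,
                              scales = engine$scales))
}

# One surrogate draw under the caller's RNG state: permute the target
# values, smooth the permutation at each candidate scale, mix with white
# noise using the variance-constrained least-squares ratios, re-rank
# each candidate onto the target's value distribution, and keep the
# (scale, mixing) whose finished candidate's variogram best matches the
# target's. The scale comparison shares one probe noise vector so it
# compares scales rather than noise realizations; the returned surrogate
# is then regenerated with fresh noise, so its spatial statistics are
# not selected on their own randomness (selecting the probe candidate
# itself would narrow the null, visibly so for unstructured targets).
surrogate_draw_one <- function(x, engine,
                               gamma_t = engine_variogram(engine, x),
                               sorted_x = sort(x)) {
  n <- engine$n
  n_sc <- length(engine$scales)
  perm <- sample(x)
  noise <- stats::rnorm(n)
  v_x <- stats::var(x)
  sm_all <- matrix(engine$smoother_stack %*% perm, n, n_sc)
  v_sm <- apply(sm_all, 2, stats::var)
  ok <- which(v_sm > 0)
  if (length(ok) == 0) {
    return(sorted_x[rank(noise, ties.method = "first")])
  }
  g_sm <- engine_variogram_multi(engine, sm_all[, ok, drop = FALSE])
  fits <- vector("list", length(ok))
  cands <- matrix(0, n, length(ok))
  for (ii in seq_along(ok)) {
    fits[[ii]] <- fit_variogram_mix(gamma_t, g_sm[, ii], v_sm[ok[ii]],
                                    v_x)
    cands[, ii] <- sorted_x[rank(sqrt(fits[[ii]]$a) * sm_all[, ok[ii]] +
                                   sqrt(fits[[ii]]$b) * noise,
                                 ties.method = "first")]
  }
  g_cand <- engine_variogram_multi(engine, cands)
  best <- which.min(colSums((g_cand - gamma_t)^2))
  f <- fits[[best]]
  sorted_x[rank(sqrt(f$a) * sm_all[, ok[best]] +
                  sqrt(f$b) * stats::rnorm(n),
                ties.method = "first")]
}

# Least squares fit gamma_t ~ a * gamma_sm + b with a, b >= 0, under the
# constraint a * var(sm) + b = var(x): adding independent noise of
# variance b raises the semivariance by a constant, and pinning the
# mixture's total variance to the target's keeps the subsequent
# re-ranking (a monotone, variance-restoring transform) from distorting
# the matched variogram.
fit_variogram_mix <- function(gamma_t, gamma_sm, v_sm, v_x) {
  gs <- gamma_sm - v_sm
  gt <- gamma_t - v_x
  denom <- sum(gs^2)
  a <- if (denom > 0) max(sum(gs * gt) / denom, 0) else 0
  b <- v_x - a * v_sm
  if (b < 0) {
    b <- 0
    a <- if (v_sm > 0) v_x / v_sm else 0
  }
  resid <- gamma_t - a * gamma_sm - b
  list(a = a, b = b, sse = sum(resid^2))
}

#' Null ensembles
#'
#' Container for a set of surrogate maps or matched null genes together
#' with full provenance (method, seed, parameters).
#'
#' @param kind `"surrogate_maps"` or `"matched_genes"`.
#' @param members Surrogate matrix (regions x draws) or character vector
#'   of gene symbols.
#' @param seed Seed used to generate the ensemble.
#' @param params Named list of generation parameters.
#' @return An object of class `null_ensemble`.
#' @export
null_ensemble <- function(kind = c("surrogate_maps", "matched_genes"),
                          members, seed, params = list()) {
  kind <- match.arg(kind)
  structure(list(kind = kind, members = members, seed = seed,
                 params = params), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  n <- if (is.matrix(x$members)) ncol(x$members) else length(x$members)
  cat(sprintf("<null_ensemble> kind=%s, %d members, seed=%s\n",
              x$kind, n, format(x$seed)))
  invisible(x)
}

#' Matched-gene null sets
#'
#' Draws null genes matched to a target gene on two criteria: spatial
#' autocorrelation (absolute difference in Moran's I) and value
#' distribution (two-sample Kolmogorov-Smirnov statistic). Per draw,
#' `candidates_per_draw` genes are sampled without replacement from the
#' pool (never the target or excluded genes); candidates are ranked on
#' each criterion (ascending) and the candidate with the best mean rank
#' is selected, ties broken by smaller Moran's I difference, then by
#' gene symbol. Repeats across draws are allowed.
#'
#' @param target_gene Symbol of the target gene; must be a column of
#'   `pool`.
#' @param pool A [regional_matrix] of candidate gene maps.
#' @param exclude Gene symbols never to sample (precursors etc.).
#' @param n_draws Number of null genes to select.
#' @param candidates_per_draw Candidates sampled per draw (100 is the
#'   conventional choice).
#' @param dist Distance matrix for Moran's I.
#' @param seed Integer seed.
#' @param scheme,k Weight scheme for Moran's I (see [spatial_weights()]).
#' @return A `null_ensemble` with `members` a character vector of
#'   `n_draws` selected gene symbols.
#' @export
matched_gene_nulls <- function(target_gene, pool, exclude = character(),
                               n_draws, candidates_per_draw = 100,
                               dist = NULL, seed = 1,
                               scheme = "knn", k = 10) {
  v <- rm_values(pool)
  reject_missing(v, "gene pool")
  if (!target_gene %in% colnames(v)) {
    stop("target gene `", target_gene, "` not found in pool",
         call. = FALSE)
  }
  n_draws <- check_count(n_draws, "n_draws", min = 1)
  candidates_per_draw <- check_count(candidates_per_draw,
                                     "candidates_per_draw", min = 1)
  keep <- setdiff(colnames(v), c(target_gene, exclude))
  if (length(keep) < candidates_per_draw) {
    stop("pool (", length(keep), " genes after exclusions) smaller than ",
         "candidates_per_draw (", candidates_per_draw, ")", call. = FALSE)
  }
  if (is.null(dist)) stop("`dist` is required for Moran's I",
                          call. = FALSE)
  w <- spatial_weights(dist, scheme, k)
  target <- v[, target_gene]
  i_target <- morans_i(target, weights = w)
  # Per-pool-gene statistics are fixed across draws: compute once.
  i_pool <- vapply(keep, function(g) morans_i(v[, g], weights = w),
                   numeric(1))
  ks_pool <- vapply(keep, function(g) ks_statistic(target, v[, g]),
                    numeric(1))
  di_pool <- abs(i_pool - i_target)
  members <- with_seed(seed, {
    vapply(seq_len(n_draws), function(dr) {
      matched_rank_select(sample(keep, candidates_per_draw),
                          di_pool, ks_pool)
    }, character(1))
  })
  null_ensemble("matched_genes", members, seed = seed,
                params = list(target_gene = target_gene,
                              candidates_per_draw = candidates_per_draw,
                              scheme = scheme, k = k,
                              exclude = exclude))
}

# Best-mean-rank selection among sampled candidates; ties broken by
# smaller Moran's I difference, then gene symbol.
matched_rank_select <- function(cand, di_pool, ks_pool) {
  r_i <- rank(di_pool[cand], ties.method = "average")
  r_ks <- rank(ks_pool[cand], ties.method = "average")
  mean_rank <- (r_i + r_ks) / 2
  cand[order(mean_rank, di_pool[cand], cand)[1]]
}
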