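#' Partial least squares correlation
#'
#' Finds paired latent variables maximizing the shared covariance
#' between two column-standardized data blocks observed over the same
#' regions. Both blocks are centered and scaled to unit column variance,
#' the cross-covariance matrix `X'Y` is decomposed by SVD, and each
#' latent variable's covariance-explained share is its squared singular
#' value over the sum of squares. Scores are the standardized data
#' projected onto the weights; loadings are the Pearson correlations of
#' each original column with its side's score. Signs follow a
#' deterministic convention: per latent variable, the weight-vector side
#' with the larger largest-magnitude entry has that entry made positive,
#' and both sides are flipped together.
#'
#' @param X,Y [regional_matrix] objects (or plain matrices) over the
#'   same regions; every column must have nonzero variance.
#' @return An object of class `plsc_result` with fields
#'   `singular_values`, `covariance_explained` (percent, summing to
#'   100), `x_weights`, `y_weights` (orthonormal columns), `x_scores`,
#'   `y_scores`, `x_loadings`, `y_loadings`.
#' @export
plsc_fit <- function(X, Y) {
  xs <- standardize_block(X, "X")
  ys <- standardize_block(Y, "Y")
  if (nrow(xs) != nrow(ys)) {
    stop("X and Y must share regions", call. = FALSE)
  }
  cc <- crossprod(xs, ys) / (nrow(xs) - 1)
  sv <- svd(cc)
  r <- length(sv$d)
  u <- sv$u
  v <- sv$v
  for (kk in seq_len(r)) {
    iu <- which.max(abs(u[, kk]))
    iv <- which.max(abs(v[, kk]))
    lead <- if (abs(u[iu, kk]) >= abs(v[iv, kk])) u[iu, kk] else v[iv, kk]
    if (lead < 0) {
      u[, kk] <- -u[, kk]
      v[, kk] <- -v[, kk]
    }
  }
  x_scores <- xs %*% u
  y_scores <- ys %*% v
  lv_names <- paste0("LV", seq_len(r))
  dimnames(u) <- list(colnames(xs), lv_names)
  dimnames(v) <- list(colnames(ys), lv_names)
  dimnames(x_scores) <- list(rownames(xs), lv_names)
  dimnames(y_scores) <- list(rownames(ys), lv_names)
  structure(list(
    singular_values = stats::setNames(sv$d, lv_names),
    covariance_explained =
      stats::setNames(100 * sv$d^2 / sum(sv$d^2), lv_names),
    x_weights = u, y_weights = v,
    x_scores = x_scores, y_scores = y_scores,
    x_loadings = stats::cor(xs, x_scores),
    y_loadings = stats::cor(ys, y_scores)),
    class = "plsc_result")
}

standardize_block <- function(m, what) {
  v <- rm_values(m)
  reject_missing(v, what)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    stop(what, " has zero-variance column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  }
  scale(v, center = TRUE, scale = sds)
}

#' @export
print.plsc_result <- function(x, ...) {
  cat(sprintf("<plsc_result> %d latent variables; LV1 explains %.2f%% of covariance\n",
              length(x$singular_values), x$covariance_explained[1]))
  invisible(x)
}

#' Permutation test for PLSC latent variables
#'
#' Rebuilds the `Y` block under a spatial null `n_perm` times and
#' compares singular values. With `null_kind = "surrogate_maps"` every
#' `Y` column is replaced by a variogram-matched surrogate of itself;
#' with `"matched_genes"` every `Y` column is replaced by the map of a
#' matched null gene drawn independently per column from a gene pool.
#' By default each null singular value is the sorted singular value of
#' the permuted cross-covariance, compared with the empirical one of
#' the same rank — a like-with-like comparison that keeps p-values
#' uniform under the global null. `align = TRUE` instead projects the
#' permuted cross-covariance onto the empirical latent basis
#' (`||C_perm v_k||`); this measures null covariance along the
#' empirical directions but is anticonservative for the first latent
#' variable under the null (the empirical value is maximized over
#' directions, the projected null is not), so it is not the default.
#' Per-latent-variable p-values use the add-one estimator with a
#' greater tail.
#'
#' @param X,Y Data blocks as in [plsc_fit()].
#' @param null_kind `"surrogate_maps"` or `"matched_genes"`.
#' @param n_perm Number of permutations (`>= 100`).
#' @param seed Integer seed.
#' @param dist Distance matrix (required for surrogate maps).
#' @param pool Gene pool [regional_matrix] (required for matched genes).
#' @param candidates_per_draw,exclude,scheme,k Matched-gene controls.
#' @param align Align null singular values to the empirical basis.
#' @param engine Optional shared variogram engine.
#' @return List with `perm_p` (per LV), `null_singular_values`
#'   (`n_perm x r`), and the empirical `fit`.
#' @export
plsc_permutation <- function(X, Y,
                             null_kind = c("surrogate_maps",
                                           "matched_genes"),
                             n_perm = 1000, seed = 1, dist = NULL,
                             pool = NULL, candidates_per_draw = 100,
                             exclude = character(), scheme = "knn",
                             k = 10, align = FALSE, engine = NULL) {
  null_kind <- match.arg(null_kind)
  n_perm <- check_count(n_perm, "n_perm", min = 100)
  fit <- plsc_fit(X, Y)
  xs <- standardize_block(X, "X")
  yv <- rm_values(Y)
  n <- nrow(xs)
  r <- length(fit$singular_values)
  if (null_kind == "surrogate_maps") {
    if (is.null(dist)) {
      stop("surrogate-map null requires `dist`", call. = FALSE)
    }
    if (is.null(engine)) engine <- variogram_engine(dist)
    gamma_t <- apply(yv, 2, function(col) engine_variogram(engine, col))
    sorted_y <- apply(yv, 2, sort)
  } else {
    if (is.null(pool)) {
      stop("matched-gene null requires `pool`", call. = FALSE)
    }
    if (is.null(dist)) {
      stop("matched-gene null requires `dist` for Moran's I",
           call. = FALSE)
    }
    pv <- rm_values(pool)
    w <- spatial_weights(dist, scheme, k)
    keep <- setdiff(colnames(pv), exclude)
    if (length(keep) < candidates_per_draw) {
      stop("pool smaller than candidates_per_draw", call. = FALSE)
    }
    i_pool <- vapply(keep, function(g) morans_i(pv[, g], weights = w),
                     numeric(1))
    col_stats <- lapply(seq_len(ncol(yv)), function(j) {
      target <- yv[, j]
      list(di = abs(i_pool - morans_i(target, weights = w)),
           ks = vapply(keep, function(g) ks_statistic(target, pv[, g]),
                       numeric(1)))
    })
  }
  null_sv <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      y_null <- if (null_kind == "surrogate_maps") {
        vapply(seq_len(ncol(yv)), function(j) {
          surrogate_draw_one(yv[, j], engine, gamma_t[, j], sorted_y[, j])
        }, numeric(n))
      } else {
        vapply(seq_len(ncol(yv)), function(j) {
          g <- matched_rank_select(sample(keep, candidates_per_draw),
                                   col_stats[[j]]$di, col_stats[[j]]$ks)
          pv[, g]
        }, numeric(n))
      }
      sds <- apply(y_null, 2, stats::sd)
      sds[sds == 0] <- 1
      yn <- scale(y_null, center = TRUE, scale = sds)
      cc <- crossprod(xs, yn) / (n - 1)
      if (align) {
        sqrt(colSums((cc %*% fit$y_weights)^2))
      } else {
        sort(svd(cc, nu = 0, nv = 0)$d, decreasing = TRUE)[seq_len(r)]
      }
    }, numeric(r)))
  })
  perm_p <- vapply(seq_len(r), function(kk) {
    empirical_pvalue(fit$singular_values[kk], null_sv[, kk],
                     tail = "greater")
  }, numeric(1))
  list(perm_p = stats::setNames(perm_p, names(fit$singular_values)),
       null_singular_values = null_sv, fit = fit)
}

#' Bootstrap confidence intervals for PLSC loadings
#'
#' Resamples regions with replacement, refits the decomposition, aligns
#' each bootstrap latent variable's sign to the empirical one (by the
#' dot product of the weight vectors), and reports percentile 95%
#' intervals over the bootstrap loadings. A resample in which some
#' column has zero variance is redrawn; the number of redraws is
#' reported.
#'
#' @param X,Y Data blocks as in [plsc_fit()].
#' @param n_boot Number of bootstrap resamples (`>= 100`).
#' @param seed Integer seed.
#' @param conf Interval coverage (default 0.95).
#' @return List with arrays `x_lower`, `x_upper`, `y_lower`, `y_upper`
#'   (variables x LVs), the empirical `fit`, and `n_redraws`.
#' @export
plsc_bootstrap <- function(X, Y, n_boot = 1000, seed = 1, conf = 0.95) {
  n_boot <- check_count(n_boot, "n_boot", min = 100)
  fit <- plsc_fit(X, Y)
  xv <- rm_values(X)
  yv <- rm_values(Y)
  n <- nrow(xv)
  r <- length(fit$singular_values)
  redraws <- 0L
  alpha <- (1 - conf) / 2
  boots_x <- array(NA_real_, c(ncol(xv), r, n_boot))
  boots_y <- array(NA_real_, c(ncol(yv), r, n_boot))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        ok <- all(apply(xv[idx, , drop = FALSE], 2, stats::sd) > 0) &&
          all(apply(yv[idx, , drop = FALSE], 2, stats::sd) > 0)
        if (ok) break
        redraws <- redraws + 1L
      }
      bf <- plsc_fit(xv[idx, , drop = FALSE], yv[idx, , drop = FALSE])
      flip <- sign(colSums(bf$x_weights * fit$x_weights) +
                     colSums(bf$y_weights * fit$y_weights))
      flip[flip == 0] <- 1
      boots_x[, , b] <- sweep(bf$x_loadings, 2, flip, `*`)
      boots_y[, , b] <- sweep(bf$y_loadings, 2, flip, `*`)
    }
  })
  qd <- function(a, pr) apply(a, c(1, 2), stats::quantile, probs = pr)
  dn_x <- dimnames(fit$x_loadings)
  dn_y <- dimnames(fit$y_loadings)
  out <- list(x_lower = qd(boots_x, alpha), x_upper = qd(boots_x, 1 - alpha),
              y_lower = qd(boots_y, alpha), y_upper = qd(boots_y, 1 - alpha),
              fit = fit, n_redraws = redraws)
  for (nm in c("x_lower", "x_upper")) dimnames(out[[nm]]) <- dn_x
  for (nm in c("y_lower", "y_upper")) dimnames(out[[nm]]) <- dn_y
  out
}

#' Train/test cross-validation of the first latent variable
#'
#' Randomly splits regions into training and test sets `n_splits`
#' times. Standardization parameters and the decomposition are learned
#' on the training rows only; test rows are standardized with the
#' training parameters, projected with the training weights, and the
#' Pearson correlation between the test-side scores of the first latent
#' variable is recorded.
#'
#' @param X,Y Data blocks as in [plsc_fit()].
#' @param train_frac Training fraction in (0, 1); the training set size
#'   is `floor(train_frac * n)`.
#' @param n_splits Number of random splits (`>= 1`).
#' @param seed Integer seed.
#' @return List with `correlations` (per split, test set), `mean_r`,
#'   and `train_correlations` (per split, training set).
#' @export
plsc_crossval <- function(X, Y, train_frac = 0.7, n_splits = 1000,
                          seed = 1) {
  if (!(train_frac > 0 && train_frac < 1)) {
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  }
  n_splits <- check_count(n_splits, "n_splits", min = 1)
  xv <- rm_values(X)
  yv <- rm_values(Y)
  reject_missing(xv, "X")
  reject_missing(yv, "Y")
  n <- nrow(xv)
  n_train <- floor(train_frac * n)
  if (n - n_train < 3) stop("test set smaller than 3 regions",
                            call. = FALSE)
  res <- with_seed(seed, {
    vapply(seq_len(n_splits), function(s) {
      tr <- sample.int(n, n_train)
      te <- setdiff(seq_len(n), tr)
      sc <- function(m, idx) {
        mu <- colMeans(m[idx, , drop = FALSE])
        sd_ <- apply(m[idx, , drop = FALSE], 2, stats::sd)
        sd_[sd_ == 0] <- 1
        list(mu = mu, sd = sd_)
      }
      px <- sc(xv, tr); py <- sc(yv, tr)
      xtr <- scale(xv[tr, , drop = FALSE], px$mu, px$sd)
      ytr <- scale(yv[tr, , drop = FALSE], py$mu, py$sd)
      sv <- svd(crossprod(xtr, ytr) / (n_train - 1), nu = 1, nv = 1)
      xte <- scale(xv[te, , drop = FALSE], px$mu, px$sd)
      yte <- scale(yv[te, , drop = FALSE], py$mu, py$sd)
      c(test = stats::cor(xte %*% sv$u, yte %*% sv$v)[1, 1],
        train = stats::cor(xtr %*% sv$u, ytr %*% sv$v)[1, 1])
    }, numeric(2))
  })
  list(correlations = unname(res["test", ]),
       mean_r = mean(res["test", ]),
       train_correlations = unname(res["train", ]),
       n_train = n_train, n_test = n - n_train)
}

#' Principal component profile of an expression matrix
#'
#' Column-centered principal component analysis via SVD, for profiling
#' small observation sets such as receptor expression over hypothalamic
#' nuclei. Variance-explained percentages are non-increasing and sum to
#' 100 over the full rank.
#'
#' @param x Observations x variables numeric matrix (`>= 2` rows).
#' @return An object of class `pca_result` with `scores`, `loadings`
#'   and `variance_explained` (percent).
#' @export
pca_profile <- function(x) {
  v <- rm_values(x)
  reject_missing(v, "matrix")
  if (nrow(v) < 2) stop("need at least 2 observations", call. = FALSE)
  vc <- sweep(v, 2, colMeans(v))
  sv <- svd(vc)
  keep <- seq_len(min(nrow(v) - 1, ncol(v)))
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(keep))
  pc_names <- paste0("PC", keep)
  dimnames(scores) <- list(rownames(v), pc_names)
  loadings <- sv$v[, keep, drop = FALSE]
  dimnames(loadings) <- list(colnames(v), pc_names)
  structure(list(
    scores = scores,
    loadings = loadings,
    variance_explained =
      stats::setNames(100 * d^2 / sum(sv$d^2), pc_names)),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("<pca_result> %d components; PC1 %.2f%%, PC2 %s%%\n",
              length(ve), ve[1],
              if (length(ve) > 1) sprintf("%.2f", ve[2]) else "-"))
  invisible(x)
}
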