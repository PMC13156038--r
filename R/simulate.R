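#' Spatial autocorrelation parameters
#'
#' Parameters of the exponential-covariance Gaussian random field used by
#' all map generators: covariance between regions at distance `d` is
#' `sill * ((1 - nugget) * exp(-d / corr_range) + nugget * 1[d = 0])`.
#' `corr_range` is the e-folding distance of the spatial correlation in
#' millimetres (0 gives spatially white maps), `nugget` the fraction of
#' variance that is spatially unstructured, and `sill` the total variance.
#'
#' @param corr_range Correlation range in millimetres, `>= 0`.
#' @param nugget Nugget fraction in `[0, 1]`.
#' @param sill Total variance, `> 0`.
#' @return An object of class `sa_params`.
#' @export
sa_params <- function(corr_range, nugget = 0, sill = 1) {
  if (!is.numeric(corr_range) || length(corr_range) != 1 ||
      !is.finite(corr_range) || corr_range < 0) {
    stop("`corr_range` must be a single finite value >= 0", call. = FALSE)
  }
  nugget <- check_fraction(nugget, "nugget")
  if (!is.numeric(sill) || length(sill) != 1 || !is.finite(sill) ||
      sill <= 0) {
    stop("`sill` must be a single value > 0", call. = FALSE)
  }
  structure(list(corr_range = as.double(corr_range), nugget = nugget,
                 sill = as.double(sill)), class = "sa_params")
}

# Exponential covariance matrix for a distance matrix; corr_range = 0
# degenerates to (sill * identity), the white-noise limit.
exp_covariance <- function(dist, params, jitter = 1e-10) {
  if (params$corr_range == 0) {
    k <- diag(params$sill, nrow(dist))
  } else {
    k <- params$sill * (1 - params$nugget) * exp(-dist / params$corr_range)
    diag(k) <- params$sill
  }
  diag(k) <- diag(k) + jitter
  k
}

# Draw `n_draws` zero-mean Gaussian random fields sharing one covariance;
# one Cholesky factorization serves all draws.
grf_draws <- function(dist, params, n_draws) {
  k <- exp_covariance(dist, params)
  r <- tryCatch(chol(k), error = function(e) {
    stop("covariance matrix is not positive definite after jitter: ",
         conditionMessage(e), call. = FALSE)
  })
  z <- matrix(stats::rnorm(nrow(dist) * n_draws), nrow(dist), n_draws)
  crossprod(r, z)
}

#' Generate a synthetic region atlas
#'
#' Builds an atlas whose centroids occupy two disjoint spatial blocks —
#' a cortical shell (radius 60-80 mm) and a subcortical core (radius
#' below 30 mm) — so cortex-subcortex contrasts in downstream analyses
#' are geometrically meaningful. Cortical regions are assigned cyclically
#' to seven intrinsic networks, subcortical regions to seven anatomical
#' structures; an optional single midline hypothalamus region sits below
#' the core. Deterministic given `seed`.
#'
#' @param n_cortex,n_subcortex Region counts, `>= 0` (not both zero
#'   unless the hypothalamus is included).
#' @param include_hypothalamus Add one midline hypothalamus region?
#' @param seed Integer seed.
#' @return A [region_atlas].
#' @examples
#' atl <- make_atlas(400, 54, include_hypothalamus = TRUE, seed = 1)
#' structure_counts(atl)   # 400 / 54 / 1 regions
#' @export
make_atlas <- function(n_cortex, n_subcortex, include_hypothalamus = TRUE,
                       seed = 1) {
  n_cortex <- check_count(n_cortex, "n_cortex")
  n_subcortex <- check_count(n_subcortex, "n_subcortex")
  n_total <- n_cortex + n_subcortex + as.integer(include_hypothalamus)
  if (n_total == 0) stop("atlas would be empty", call. = FALSE)
  networks <- c("visual", "somatomotor", "dorsal attention",
                "ventral attention", "limbic", "frontoparietal",
                "default mode")
  structures <- c("amygdala", "caudate", "globus pallidus", "hippocampus",
                  "nucleus accumbens", "putamen", "thalamus")
  with_seed(seed, {
    shell <- function(n, r_min, r_max) {
      if (n == 0) return(matrix(0, 0, 3))
      u <- matrix(stats::rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      u * stats::runif(n, r_min, r_max)
    }
    ctx <- shell(n_cortex, 60, 80)
    sub <- shell(n_subcortex, 5, 30)
    rows <- list()
    if (n_cortex > 0) {
      rows$ctx <- data.frame(
        name = sprintf("cortex_%03d", seq_len(n_cortex)),
        structure = "cortex",
        stratum = rep_len(networks, n_cortex),
        hemisphere = ifelse(ctx[, 1] < 0, "L", "R"),
        x = ctx[, 1], y = ctx[, 2], z = ctx[, 3])
    }
    if (n_subcortex > 0) {
      rows$sub <- data.frame(
        name = sprintf("subcortex_%02d", seq_len(n_subcortex)),
        structure = "subcortex",
        stratum = rep_len(structures, n_subcortex),
        hemisphere = ifelse(sub[, 1] < 0, "L", "R"),
        x = sub[, 1], y = sub[, 2], z = sub[, 3])
    }
    if (include_hypothalamus) {
      rows$hyp <- data.frame(name = "hypothalamus", structure = "hypothalamus",
                             stratum = "hypothalamus", hemisphere = "M",
                             x = 0, y = 2, z = -12)
    }
    tab <- do.call(rbind, rows)
    tab <- cbind(region_id = seq_len(nrow(tab)), tab)
    region_atlas(tab)
  })
}

#' Sample a spatially autocorrelated regional map
#'
#' Draws one map from a zero-mean Gaussian random field with exponential
#' covariance over the atlas centroids (see [sa_params]). Serves as the
#' synthetic stand-in for receptor, PET-density and meta-analytic term
#' maps.
#'
#' @param atlas A [region_atlas].
#' @param params An [sa_params].
#' @param seed Integer seed; the draw is a pure function of
#'   `(atlas, params, seed)`.
#' @return A one-column [regional_matrix] named `"map"`.
#' @export
sample_sa_map <- function(atlas, params, seed = 1) {
  stopifnot(inherits(atlas, "region_atlas"), inherits(params, "sa_params"))
  d <- pairwise_distances(atlas)
  x <- with_seed(seed, grf_draws(d, params, 1))
  colnames(x) <- "map"
  regional_matrix(x, atlas)
}

#' Generate a gene pool with heterogeneous spatial autocorrelation
#'
#' Each column is an independent Gaussian random field whose correlation
#' range is drawn uniformly in `[range_low, range_high]`; the per-column
#' true ranges are recorded in the `"corr_range"` attribute. This pool
#' plays the role of the transcriptome-wide gene background from which
#' matched null genes are sampled.
#'
#' @param atlas A [region_atlas].
#' @param n_genes Number of genes, `>= 1`.
#' @param range_low,range_high Correlation-range bounds in millimetres.
#' @param seed Integer seed.
#' @return A [regional_matrix] with columns `gene_0001 ...` and attribute
#'   `corr_range` (named numeric vector of the planted ranges).
#' @export
make_gene_pool <- function(atlas, n_genes, range_low, range_high, seed = 1) {
  stopifnot(inherits(atlas, "region_atlas"))
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  if (!(range_low >= 0 && range_low <= range_high)) {
    stop("need 0 <= range_low <= range_high", call. = FALSE)
  }
  d <- pairwise_distances(atlas)
  with_seed(seed, {
    ranges <- stats::runif(n_genes, range_low, range_high)
    cols <- vapply(ranges, function(rho) {
      drop(grf_draws(d, sa_params(rho), 1))
    }, numeric(nrow(d)))
    colnames(cols) <- sprintf("gene_%04d", seq_len(n_genes))
    out <- regional_matrix(cols, atlas)
    attr(out, "corr_range") <- stats::setNames(ranges, colnames(cols))
    out
  })
}

#' Planted latent ground truth for paired map sets
#'
#' Describes the shared latent dimension planted by
#' [make_planted_latent()]: unit-norm weight vectors on each side, the
#' fraction `latent_share` of squared-singular-value mass of the
#' cross-covariance carried by the latent dimension, and the noise scale.
#'
#' @param x_weights,y_weights Unit-norm numeric weight vectors.
#' @param latent_share Fraction in `[0, 1]`.
#' @param noise_sd Noise standard deviation, `>= 0`.
#' @return An object of class `planted_latent_truth`.
#' @export
planted_latent_truth <- function(x_weights, y_weights, latent_share,
                                 noise_sd = 1) {
  latent_share <- check_fraction(latent_share, "latent_share")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  for (w in list(x_weights, y_weights)) {
    if (abs(sqrt(sum(w^2)) - 1) > 1e-8) {
      stop("weight vectors must have unit norm", call. = FALSE)
    }
  }
  structure(list(x_weights = as.double(x_weights),
                 y_weights = as.double(y_weights),
                 latent_share = latent_share,
                 noise_sd = as.double(noise_sd)),
            class = "planted_latent_truth")
}

#' Generate paired map sets with a planted shared latent dimension
#'
#' Builds matrices `X` (regions x n_x) and `Y` (regions x n_y) sharing a
#' single spatially smooth latent score vector (a Gaussian random field
#' with correlation range = atlas diameter / 4, so spatial null models
#' face a realistic challenge) that loads through the truth's weight
#' vectors, plus independent Gaussian noise. The signal amplitude is set
#' so that the planted dimension carries approximately `latent_share` of
#' the squared-singular-value mass of the expected cross-covariance.
#'
#' @param atlas A [region_atlas].
#' @param n_x,n_y Column counts, `>= 2`; must match the truth's weight
#'   lengths.
#' @param truth A [planted_latent_truth].
#' @param seed Integer seed.
#' @return A list with fields `X`, `Y` (both [regional_matrix]) and
#'   `truth` (echoed unchanged).
#' @export
make_planted_latent <- function(atlas, n_x, n_y, truth, seed = 1) {
  stopifnot(inherits(atlas, "region_atlas"),
            inherits(truth, "planted_latent_truth"))
  n_x <- check_count(n_x, "n_x", min = 2)
  n_y <- check_count(n_y, "n_y", min = 2)
  if (length(truth$x_weights) != n_x || length(truth$y_weights) != n_y) {
    stop("truth weight lengths must equal n_x and n_y", call. = FALSE)
  }
  share <- truth$latent_share
  if (share < 1 && truth$noise_sd == 0) {
    stop("degenerate design: latent_share < 1 requires noise_sd > 0",
         call. = FALSE)
  }
  n <- nrow(atlas)
  d <- pairwise_distances(atlas)
  rho <- max(d) / 4
  with_seed(seed, {
    s <- drop(grf_draws(d, sa_params(rho), 1))
    s <- (s - mean(s)) / stats::sd(s)
    if (share >= 1) {
      a <- 1; b <- 0
    } else if (share <= 0) {
      a <- 0; b <- 1
    } else {
      # expected squared mass of the noise part of X'Y/n is
      # n_x * n_y * noise_sd^4 / n; solve a^4 / (a^4 + that) = share
      a <- (share / (1 - share) * n_x * n_y * truth$noise_sd^4 / n)^(1 / 4)
      b <- 1
    }
    x <- a * tcrossprod(s, truth$x_weights) +
      b * truth$noise_sd * matrix(stats::rnorm(n * n_x), n, n_x)
    y <- a * tcrossprod(s, truth$y_weights) +
      b * truth$noise_sd * matrix(stats::rnorm(n * n_y), n, n_y)
    colnames(x) <- sprintf("x_%03d", seq_len(n_x))
    colnames(y) <- sprintf("y_%03d", seq_len(n_y))
    list(X = regional_matrix(x, atlas), Y = regional_matrix(y, atlas),
         truth = truth)
  })
}

#' Generate a regression design with planted predictor contributions
#'
#' Builds predictors from spatially smooth fields and a response whose
#' population R-squared share attributable to predictor `k` equals
#' `contributions[k]`. With `orthogonal = TRUE` the raw fields are
#' orthonormalized before mixing, so each predictor's total dominance
#' equals its squared correlation with the response in the population.
#'
#' @param atlas A [region_atlas].
#' @param contributions Nonnegative fractions summing to at most 1; one
#'   per predictor.
#' @param noise_sd Residual noise standard deviation; defaults to
#'   `sqrt(1 - sum(contributions))` so that the full-model population
#'   R-squared equals `sum(contributions)`.
#' @param orthogonal Orthonormalize predictors before mixing?
#' @param seed Integer seed.
#' @return A list with `X` ([regional_matrix]), `y` (one-column
#'   [regional_matrix]) and `truth` (contributions, noise_sd, orthogonal).
#' @export
make_dominance_design <- function(atlas, contributions, noise_sd = NULL,
                                  orthogonal = TRUE, seed = 1) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (any(contributions < 0)) {
    stop("contributions must be nonnegative", call. = FALSE)
  }
  if (sum(contributions) > 1 + 1e-12) {
    stop("contributions must sum to at most 1", call. = FALSE)
  }
  if (is.null(noise_sd)) noise_sd <- sqrt(max(0, 1 - sum(contributions)))
  p <- length(contributions)
  n <- nrow(atlas)
  if (n <= p + 1) stop("atlas too small for ", p, " predictors",
                       call. = FALSE)
  d <- pairwise_distances(atlas)
  rho <- max(d) / 4
  with_seed(seed, {
    raw <- grf_draws(d, sa_params(rho), p)
    raw <- sweep(raw, 2, colMeans(raw))
    if (orthogonal) {
      q <- qr.Q(qr(raw))
      x <- q * sqrt(n)              # unit sample variance, orthogonal
    } else {
      x <- sweep(raw, 2, apply(raw, 2, stats::sd), "/")
    }
    colnames(x) <- sprintf("pred_%02d", seq_len(p))
    y <- drop(x %*% sqrt(contributions)) + noise_sd * stats::rnorm(n)
    list(X = regional_matrix(x, atlas),
         y = regional_matrix(matrix(y, dimnames = list(NULL, "y")), atlas),
         truth = list(contributions = as.double(contributions),
                      noise_sd = as.double(noise_sd),
                      orthogonal = orthogonal))
  })
}

#' Generate a multi-donor expression stack with known reliability
#'
#' Each donor's matrix mixes a common per-gene spatially smooth signal
#' (weight `sqrt(reliability)`) with donor-specific white noise, so the
#' expected inter-donor correlation of every gene's regional profile is
#' `reliability` and [differential_stability()] recovers it.
#'
#' @param atlas A [region_atlas].
#' @param n_donors Number of donors, `>= 2`.
#' @param n_genes Number of shared gene columns, `>= 1`.
#' @param reliability Planted inter-donor correlation in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list of `n_donors` [regional_matrix] objects sharing column
#'   names `gene_0001 ...`.
#' @export
make_donor_stack <- function(atlas, n_donors, n_genes, reliability,
                             seed = 1) {
  stopifnot(inherits(atlas, "region_atlas"))
  n_donors <- check_count(n_donors, "n_donors", min = 2)
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  reliability <- check_fraction(reliability, "reliability")
  n <- nrow(atlas)
  d <- pairwise_distances(atlas)
  rho <- max(d) / 4
  with_seed(seed, {
    # both components are standardized to unit sample variance across
    # regions: a spatially smooth signal has sample variance below its
    # marginal variance (neighbouring regions co-vary), which would
    # otherwise attenuate the realized inter-donor correlation below
    # the requested reliability
    shared <- scale_cols(grf_draws(d, sa_params(rho), n_genes))
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    lapply(seq_len(n_donors), function(i) {
      noise <- scale_cols(matrix(stats::rnorm(n * n_genes), n, n_genes))
      m <- sqrt(reliability) * shared + sqrt(1 - reliability) * noise
      colnames(m) <- genes
      regional_matrix(m, atlas)
    })
  })
}
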