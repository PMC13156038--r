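#' Quality-control thresholds for receptor annotations
#'
#' Thresholds applied to the three per-gene microarray quality metrics:
#' mean probe intensity, correlation of the selected probe with RNA-seq,
#' and differential stability across donors. All three are unitless
#' values in `[0, 1]`. With `inclusive = TRUE` (the default) a metric
#' equal to its threshold passes: annotation tables are printed at two
#' decimals, so a table value equal to the threshold reflects an
#' underlying value that met a strict rule before rounding.
#'
#' @param min_intensity,min_rnaseq_corr,min_diff_stability Thresholds in
#'   `[0, 1]`.
#' @param inclusive Compare with `>=` rather than `>`.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_intensity = 0.2, min_rnaseq_corr = 0.2,
                          min_diff_stability = 0.1, inclusive = TRUE) {
  for (v in c(min_intensity, min_rnaseq_corr, min_diff_stability)) {
    check_fraction(v, "threshold")
  }
  structure(list(min_intensity = min_intensity,
                 min_rnaseq_corr = min_rnaseq_corr,
                 min_diff_stability = min_diff_stability,
                 inclusive = isTRUE(inclusive)),
            class = "qc_thresholds")
}

#' Filter receptor genes by quality-control metrics
#'
#' Keeps genes whose mean intensity, RNA-seq correlation and differential
#' stability all pass their thresholds. Raising any threshold can only
#' remove genes (monotone filter); input order is preserved.
#'
#' @param annotation A data frame with columns `gene`, `mean_intensity`,
#'   `rnaseq_correlation` and `differential_stability` (see
#'   [receptor_annotation()] for the packaged table).
#' @param thresholds A [qc_thresholds].
#' @return Character vector of passing gene symbols, in input order.
#' @examples
#' ann <- receptor_annotation()
#' length(qc_filter(ann, qc_thresholds()))   # 38
#' @export
qc_filter <- function(annotation, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(annotation), inherits(thresholds, "qc_thresholds"))
  metrics <- c("mean_intensity", "rnaseq_correlation",
               "differential_stability")
  missing_cols <- setdiff(c("gene", metrics), names(annotation))
  if (length(missing_cols) > 0) {
    stop("annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (m in metrics) {
    bad <- which(is.na(annotation[[m]]))
    if (length(bad) > 0) {
      stop(sprintf("gene %s has missing metric `%s`",
                   annotation$gene[bad[1]], m), call. = FALSE)
    }
  }
  cmp <- if (thresholds$inclusive) `>=` else `>`
  keep <- cmp(annotation$mean_intensity, thresholds$min_intensity) &
    cmp(annotation$rnaseq_correlation, thresholds$min_rnaseq_corr) &
    cmp(annotation$differential_stability, thresholds$min_diff_stability)
  annotation$gene[keep]
}

#' Robust sigmoid normalization
#'
#' Normalizes each slice (gene column or region row) with an
#' outlier-resistant logistic transform,
#' `x' = 1 / (1 + exp(-(x - median) / (IQR / 1.35)))`, followed by
#' min-max rescaling of the slice to `[0, 1]`. The scale `IQR / 1.35`
#' makes the denominator consistent with the standard deviation under
#' normality. The transform is invariant to positive affine changes of a
#' slice and preserves within-slice order.
#'
#' @param x A [regional_matrix] or plain numeric matrix; no missing
#'   values.
#' @param axis `"within_gene"` normalizes each column across regions;
#'   `"within_region"` each row across genes.
#' @param zero_iqr Policy when a slice has zero interquartile range:
#'   `"error"` (default) or `"constant"` (slice mapped to 0.5).
#' @return Same shape as the input, values in `[0, 1]`.
#' @export
robust_sigmoid_normalize <- function(x,
                                     axis = c("within_gene",
                                              "within_region"),
                                     zero_iqr = c("error", "constant")) {
  axis <- match.arg(axis)
  zero_iqr <- match.arg(zero_iqr)
  v <- rm_values(x)
  reject_missing(v, "expression matrix")
  norm_slice <- function(s) {
    iqr <- stats::IQR(s)
    if (iqr == 0) {
      if (zero_iqr == "error") {
        stop("slice has zero interquartile range; set zero_iqr = ",
             "\"constant\" to map it to 0.5", call. = FALSE)
      }
      return(rep(0.5, length(s)))
    }
    z <- 1 / (1 + exp(-(s - stats::median(s)) / (iqr / 1.35)))
    (z - min(z)) / (max(z) - min(z))
  }
  out <- if (axis == "within_gene") {
    apply(v, 2, norm_slice)
  } else {
    t(apply(v, 1, norm_slice))
  }
  dimnames(out) <- dimnames(v)
  if (inherits(x, "regional_matrix")) regional_matrix(out, x$atlas) else out
}

#' Differential stability across donors
#'
#' Per-gene consistency of the regional expression profile across
#' donors: the mean over all donor pairs of the Pearson correlation of
#' the gene's regional values. Donor pairs where the gene has zero
#' variance in either donor are skipped with a warning; if every pair is
#' skipped the gene's value is `NA`.
#'
#' @param donors A list of at least two [regional_matrix] objects
#'   sharing atlas and gene columns.
#' @return Named numeric vector in `[-1, 1]`, one value per gene.
#' @export
differential_stability <- function(donors) {
  check_donor_stack(donors)
  mats <- lapply(donors, rm_values)
  genes <- colnames(mats[[1]])
  pairs <- utils::combn(length(mats), 2)
  ds <- vapply(seq_along(genes), function(j) {
    cors <- apply(pairs, 2, function(pr) {
      a <- mats[[pr[1]]][, j]
      b <- mats[[pr[2]]][, j]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    })
    if (anyNA(cors)) {
      warning(sprintf("gene %s: %d donor pair(s) skipped (zero variance)",
                      genes[j], sum(is.na(cors))), call. = FALSE)
    }
    if (all(is.na(cors))) NA_real_ else mean(cors, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(ds, genes)
}

check_donor_stack <- function(donors) {
  if (!is.list(donors) || length(donors) < 2) {
    stop("need a list of at least two donor matrices", call. = FALSE)
  }
  ref <- rm_values(donors[[1]])
  for (i in seq_along(donors)[-1]) {
    m <- rm_values(donors[[i]])
    if (!identical(dim(m), dim(ref)) ||
        !identical(colnames(m), colnames(ref))) {
      stop("donor matrices must share shape and gene columns",
           call. = FALSE)
    }
  }
  invisible(donors)
}

#' Average expression matrices across donors
#'
#' Elementwise mean over donors, ignoring explicitly missing cells; a
#' cell missing in every donor stays missing.
#'
#' @inheritParams differential_stability
#' @return A single matrix of the shared shape (a [regional_matrix] if
#'   the inputs are).
#' @export
aggregate_donors <- function(donors) {
  if (!is.list(donors) || length(donors) < 1) {
    stop("need a nonempty list of donor matrices", call. = FALSE)
  }
  if (length(donors) == 1) return(donors[[1]])
  check_donor_stack(donors)
  mats <- lapply(donors, rm_values)
  sums <- Reduce(`+`, lapply(mats, function(m) ifelse(is.na(m), 0, m)))
  counts <- Reduce(`+`, lapply(mats, function(m) !is.na(m)))
  out <- sums / counts            # 0/0 -> NaN where all donors missing
  out[counts == 0] <- NA
  dimnames(out) <- dimnames(mats[[1]])
  if (inherits(donors[[1]], "regional_matrix")) {
    regional_matrix(out, donors[[1]]$atlas)
  } else {
    out
  }
}

#' Stratified summary of a regional matrix
#'
#' Per-variable mean within each stratum (intrinsic network, anatomical
#' structure or nucleus), per-variable median within each structure
#' class, and a hierarchical-clustering order over variables (average
#' linkage on Euclidean distances between stratum-mean profiles), the
#' ordering used to display receptors side by side.
#'
#' @param x A [regional_matrix] (or plain matrix aligned to `atlas`).
#' @param atlas The matching [region_atlas].
#' @return A list with `stratum_means` (strata x variables),
#'   `structure_medians` (structure classes x variables) and `order`
#'   (integer permutation of the variables).
#' @export
stratified_summary <- function(x, atlas = x$atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  v <- rm_values(x)
  if (nrow(v) != nrow(atlas)) {
    stop("matrix rows must match atlas regions", call. = FALSE)
  }
  reject_missing(v, "matrix")
  strata <- unique(atlas$stratum)
  by_group <- function(groups, fun) {
    rows <- lapply(groups, fun)
    out <- do.call(rbind, rows)
    dimnames(out) <- list(groups, colnames(v))
    out
  }
  stratum_means <- by_group(strata, function(s) {
    colMeans(v[atlas$stratum == s, , drop = FALSE])
  })
  present <- atlas_structures()[atlas_structures() %in% atlas$structure]
  absent <- setdiff(atlas_structures(), present)
  if (length(absent) > 0) {
    warning("no regions in structure class(es): ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  structure_medians <- by_group(present, function(s) {
    apply(v[atlas$structure == s, , drop = FALSE], 2, stats::median)
  })
  ord <- if (ncol(v) > 2) {
    stats::hclust(stats::dist(t(stratum_means)), method = "average")$order
  } else {
    seq_len(ncol(v))
  }
  list(stratum_means = stratum_means,
       structure_medians = structure_medians,
       order = ord)
}

#' Probe-level filtering and selection
#'
#' Region-level pipelines receive expression that has already been
#' summarized from microarray probes; these two helpers document that
#' upstream contract on probe-by-sample tables. `filter_probes()` drops
#' probes by how often they fall below background noise. The usual
#' statement of this rule in the literature is ambiguous, so both
#' readings are available:
#' `"below_in_more"` (default; exclude probes below background in more
#' than `frac` of samples, keeping reliably detected probes) and
#' `"below_in_less"` (the literal converse). `select_probes()` then
#' keeps, for each gene with several probes, the probe whose
#' across-sample profile has the highest Pearson correlation with an
#' RNA-seq reference profile for that gene.
#'
#' @param intensity Probes x samples numeric matrix.
#' @param background Probes x samples matrix of background-noise levels
#'   (same shape), or a single threshold.
#' @param frac Fraction of samples in `[0, 1]`.
#' @param reading Which reading of the exclusion rule to apply.
#' @return `filter_probes()`: character vector of retained probe names.
#' @export
filter_probes <- function(intensity, background, frac = 0.2,
                          reading = c("below_in_more", "below_in_less")) {
  reading <- match.arg(reading)
  frac <- check_fraction(frac, "frac")
  intensity <- as.matrix(intensity)
  if (length(background) == 1) {
    background <- matrix(background, nrow(intensity), ncol(intensity))
  }
  stopifnot(identical(dim(as.matrix(background)), dim(intensity)))
  below_frac <- rowMeans(intensity < as.matrix(background))
  drop_probe <- if (reading == "below_in_more") {
    below_frac > frac
  } else {
    below_frac < frac
  }
  rownames(intensity)[!drop_probe]
}

#' @rdname filter_probes
#' @param probe_gene Named character vector mapping probe name to gene
#'   symbol.
#' @param rnaseq_ref Genes x samples RNA-seq reference matrix with gene
#'   row names and the same sample columns as `intensity`.
#' @return `select_probes()`: named character vector, gene -> selected
#'   probe.
#' @export
select_probes <- function(intensity, probe_gene, rnaseq_ref) {
  intensity <- as.matrix(intensity)
  rnaseq_ref <- as.matrix(rnaseq_ref)
  stopifnot(!is.null(rownames(intensity)), !is.null(rownames(rnaseq_ref)),
            ncol(intensity) == ncol(rnaseq_ref))
  probes <- intersect(rownames(intensity), names(probe_gene))
  genes <- intersect(unique(probe_gene[probes]), rownames(rnaseq_ref))
  sel <- vapply(genes, function(g) {
    cand <- probes[probe_gene[probes] == g]
    cors <- vapply(cand, function(p) {
      stats::cor(intensity[p, ], rnaseq_ref[g, ])
    }, numeric(1))
    cand[which.max(cors)]
  }, character(1))
  stats::setNames(sel, genes)
}
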