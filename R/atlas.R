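#' Region atlas objects
#'
#' A region atlas is the canonical index for all regional data handled by
#' this package: one row per brain region carrying an integer `region_id`
#' (the join key used everywhere), a free-text `name`, a `structure` label
#' from the closed set `cortex` / `subcortex` / `hypothalamus`, a free-text
#' `stratum` (an intrinsic functional network for cortical regions, an
#' anatomical structure for subcortical ones, a nucleus for hypothalamic
#' ones), a `hemisphere` code (`L`, `R` or `M` for midline) and a 3-D
#' centroid in millimetres. Every regional matrix in the package shares the
#' row order of its atlas.
#'
#' @param regions A data frame with columns `region_id`, `name`,
#'   `structure`, `stratum`, `hemisphere`, `x`, `y`, `z`.
#' @return An object of class `region_atlas` (a validated data frame).
#' @examples
#' atl <- region_atlas(data.frame(
#'   region_id = 1:2, name = c("a", "b"),
#'   structure = c("cortex", "subcortex"),
#'   stratum = c("visual", "thalamus"), hemisphere = c("L", "R"),
#'   x = c(0, 3), y = c(0, 4), z = c(0, 0)))
#' structure_counts(atl)
#' @export
region_atlas <- function(regions) {
  required <- c("region_id", "name", "structure", "stratum", "hemisphere",
                "x", "y", "z")
  if (!is.data.frame(regions)) {
    stop("`regions` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    stop("atlas table lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(regions) == 0) {
    stop("atlas table is empty: at least one region is required",
         call. = FALSE)
  }
  regions <- regions[, required]
  regions$region_id <- as.integer(regions$region_id)
  if (anyNA(regions$region_id)) {
    stop("region_id must be integer-valued and non-missing", call. = FALSE)
  }
  dup <- unique(regions$region_id[duplicated(regions$region_id)])
  if (length(dup) > 0) {
    stop("duplicate region_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_structure <- setdiff(unique(regions$structure), atlas_structures())
  if (length(bad_structure) > 0) {
    stop("unknown structure label(s): ",
         paste(bad_structure, collapse = ", "),
         "; allowed: ", paste(atlas_structures(), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(trimws(as.character(regions$stratum))))) {
    stop("stratum labels must be non-empty", call. = FALSE)
  }
  bad_hemi <- setdiff(unique(regions$hemisphere), c("L", "R", "M"))
  if (length(bad_hemi) > 0) {
    stop("unknown hemisphere label(s): ", paste(bad_hemi, collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(regions[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  if (any(!is.finite(xyz))) {
    stop("all centroid coordinates must be finite", call. = FALSE)
  }
  regions[, c("x", "y", "z")] <- xyz
  rownames(regions) <- NULL
  class(regions) <- c("region_atlas", "data.frame")
  regions
}

#' @rdname region_atlas
#' @export
atlas_structures <- function() c("cortex", "subcortex", "hypothalamus")

#' @rdname region_atlas
#' @param atlas A `region_atlas`.
#' @export
structure_counts <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  counts <- table(factor(atlas$structure, levels = atlas_structures()))
  stats::setNames(as.integer(counts), names(counts))
}

#' @export
print.region_atlas <- function(x, ...) {
  cnt <- structure_counts(x)
  cat(sprintf("<region_atlas> %d regions (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", ")))
  invisible(x)
}

#' Read a region atlas from a delimited table
#'
#' Atlas tables are UTF-8 tab-delimited files with a mandatory header row
#' and columns `region_id`, `name`, `structure`, `stratum`, `hemisphere`,
#' `x`, `y`, `z`.
#'
#' @param path Path to the TSV file.
#' @param sep Field separator; tab by default.
#' @return A validated [region_atlas].
#' @export
load_region_atlas <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", fileEncoding = "UTF-8")
  region_atlas(tab)
}

#' @rdname load_region_atlas
#' @param atlas A `region_atlas` to write.
#' @export
write_region_atlas <- function(atlas, path, sep = "\t") {
  stopifnot(inherits(atlas, "region_atlas"))
  utils::write.table(atlas, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Euclidean distances between region centroids
#'
#' The substrate for variograms, Moran's I and the surrogate machinery.
#' Straight-line distance between centroids is used throughout; surface
#' geodesics are out of scope.
#'
#' @param atlas A [region_atlas].
#' @return A symmetric `n x n` matrix of distances in millimetres with a
#'   zero diagonal, with region ids as dimnames.
#' @export
pairwise_distances <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  xyz <- as.matrix(atlas[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite centroid", call. = FALSE)
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(atlas$region_id, atlas$region_id)
  d
}
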