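#' Regional data matrices
#'
#' A regional matrix couples a regions-by-variables numeric matrix to its
#' [region_atlas]: row `i` of the values always describes row `i` of the
#' atlas. Columns hold receptor maps, PET densities, meta-analytic term
#' maps or gene expression profiles. Missingness is explicit: `NA` cells
#' are allowed only where an operation documents that it accepts them;
#' by default operations reject masked input.
#'
#' @param values Numeric matrix (or something coercible), one row per
#'   atlas region, with column names.
#' @param atlas A [region_atlas] with `nrow(values)` regions.
#' @return An object of class `regional_matrix` with fields `values` and
#'   `atlas`.
#' @export
regional_matrix <- function(values, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(atlas)) {
    stop(sprintf("values have %d rows but atlas has %d regions",
                 nrow(values), nrow(atlas)), call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  }
  rownames(values) <- atlas$region_id
  structure(list(values = values, atlas = atlas),
            class = "regional_matrix")
}

#' @export
print.regional_matrix <- function(x, ...) {
  cat(sprintf("<regional_matrix> %d regions x %d variables (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.regional_matrix <- function(x) dim(x$values)

# Accepts a regional_matrix, plain matrix or numeric vector and returns a
# plain double matrix. Vectors become one-column maps.
rm_values <- function(x) {
  if (inherits(x, "regional_matrix")) return(x$values)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# A "map" is a one-column regional matrix; return it as a bare vector.
rm_map <- function(x) {
  v <- rm_values(x)
  if (ncol(v) != 1) {
    stop("expected a single-column regional map, got ", ncol(v),
         " columns", call. = FALSE)
  }
  drop(v)
}

reject_missing <- function(x, what = "input") {
  v <- rm_values(x)
  if (anyNA(v)) {
    stop(what, " contains missing values; this operation requires ",
         "complete data", call. = FALSE)
  }
  invisible(v)
}

#' Read and write regional matrices
#'
#' Regional matrix tables are tab-delimited with a header row; the first
#' column must be `region_id` and must cover the atlas exactly. Rows are
#' re-ordered to atlas order on load, so files may be stored in any row
#' order. Missing values are encoded as empty cells on disk.
#'
#' @param path Path to the delimited file.
#' @param atlas The [region_atlas] the matrix belongs to.
#' @param sep Field separator; tab by default.
#' @return [load_matrix()] returns a [regional_matrix].
#' @export
load_matrix <- function(path, atlas, sep = "\t") {
  stopifnot(inherits(atlas, "region_atlas"))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", fileEncoding = "UTF-8",
                           na.strings = "", check.names = FALSE)
  if (names(tab)[1] != "region_id") {
    stop("first column must be `region_id`, found `", names(tab)[1], "`",
         call. = FALSE)
  }
  ids <- as.integer(tab$region_id)
  missing <- setdiff(atlas$region_id, ids)
  if (length(missing) > 0) {
    stop("file is missing atlas region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(ids, atlas$region_id)
  if (length(extra) > 0) {
    stop("file contains region(s) absent from the atlas: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric cell at row %d (region_id %d), column `%s`",
                     bad[1], ids[bad[1]], names(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  vals <- as.matrix(vals)
  vals <- vals[match(atlas$region_id, ids), , drop = FALSE]
  regional_matrix(vals, atlas)
}

#' @rdname load_matrix
#' @param x A [regional_matrix] to write.
#' @param digits Number of significant digits written; the round trip is
#'   exact at this precision.
#' @export
write_matrix <- function(x, path, sep = "\t", digits = 15) {
  stopifnot(inherits(x, "regional_matrix"))
  out <- data.frame(region_id = x$atlas$region_id,
                    signif(x$values, digits), check.names = FALSE)
  colnames(out) <- c("region_id", colnames(x$values))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
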