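#' Pairwise percent identity of aligned amino-acid sequences
#'
#' For every pair of sequences in a multiple alignment, the percentage
#' of matching positions among columns where both sequences have a
#' residue (gap columns are excluded pairwise; `-` and `.` count as
#' gaps). The matrix is symmetric with a diagonal of 100. A pair with
#' no comparable columns yields `NA` with a warning.
#'
#' @param aligned A path to an aligned FASTA file, a
#'   `Biostrings::AAStringSet`, or a named character vector of aligned
#'   sequences of equal length.
#' @return Symmetric numeric matrix of percent identities.
#' @export
percent_identity <- function(aligned) {
  seqs <- as_aligned_chars(aligned)
  n <- length(seqs)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    stop("sequences are not aligned: lengths differ (",
         paste(range(lens), collapse = "-"), ")", call. = FALSE)
  }
  gap <- c("-", ".")
  out <- matrix(NA_real_, n, n,
                dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    out[i, i] <- 100
    for (j in setdiff(seq_len(n), seq_len(i))) {
      comparable <- !(seqs[[i]] %in% gap) & !(seqs[[j]] %in% gap)
      if (!any(comparable)) {
        warning(sprintf("no comparable columns between %s and %s",
                        names(seqs)[i], names(seqs)[j]), call. = FALSE)
        next
      }
      pid <- 100 * mean(seqs[[i]][comparable] == seqs[[j]][comparable])
      out[i, j] <- pid
      out[j, i] <- pid
    }
  }
  out
}

as_aligned_chars <- function(aligned) {
  if (is.character(aligned) && length(aligned) == 1 &&
      file.exists(aligned)) {
    aligned <- Biostrings::readAAStringSet(aligned)
  }
  if (inherits(aligned, "XStringSet")) {
    aligned <- stats::setNames(as.character(aligned), names(aligned))
  }
  if (!is.character(aligned) || length(aligned) < 2) {
    stop("need at least two aligned sequences", call. = FALSE)
  }
  if (is.null(names(aligned))) {
    names(aligned) <- paste0("seq", seq_along(aligned))
  }
  lapply(stats::setNames(strsplit(toupper(aligned), ""), names(aligned)),
         identity)
}

#' Friedman test with Kendall's W effect size
#'
#' Nonparametric test for a signaling-category effect on per-branch
#' substitution rates: rows are phylogenetic branches (repeated
#' measures), columns are categories. Values are ranked within rows
#' with mid-ranks for ties, and the Friedman chi-squared statistic with
#' `k - 1` degrees of freedom is computed; because the test is a rank
#' statistic it is invariant to strictly monotone within-row transforms
#' (log-transforming rates changes nothing). The concordance effect
#' size is Kendall's `W = chi2 / (n * (k - 1))` in `[0, 1]`. By default
#' no tie-correction term is applied; `tie_correction = TRUE` divides
#' the statistic by the standard tie-correction factor.
#'
#' @param rates Complete numeric matrix or data frame, branches x
#'   categories (`n >= 2`, `k >= 2`), no missing cells.
#' @param tie_correction Apply the tie-correction divisor.
#' @return List with `chi2`, `df`, `p`, `kendalls_w`, `n`, `k`.
#' @examples
#' # concordance implied by a reported chi-squared:
#' kendalls_w_from_chisq(7.54, n = 13, k = 3)   # 0.29
#' @export
friedman_kendall <- function(rates, tie_correction = FALSE) {
  m <- as.matrix(rates)
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    stop("rate table has missing cells; the test requires complete blocks",
         call. = FALSE)
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("need n >= 2 rows and k >= 2 columns",
                           call. = FALSE)
  ranks <- t(apply(m, 1, rank))      # mid-ranks for ties
  rj <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  if (tie_correction) {
    ties <- apply(m, 1, function(row) {
      tt <- table(row)
      sum(tt^3 - tt)
    })
    corr <- 1 - sum(ties) / (n * k * (k^2 - 1))
    if (corr > 0) chi2 <- chi2 / corr
  }
  list(chi2 = chi2, df = k - 1,
       p = stats::pchisq(chi2, k - 1, lower.tail = FALSE),
       kendalls_w = kendalls_w_from_chisq(chi2, n, k),
       n = n, k = k)
}

#' @rdname friedman_kendall
#' @param chi2 Friedman chi-squared statistic.
#' @param n Number of rows (branches).
#' @param k Number of columns (categories).
#' @export
kendalls_w_from_chisq <- function(chi2, n, k) {
  chi2 / (n * (k - 1))
}

#' Read a branches-by-categories substitution-rate table
#'
#' Rates are per-branch dn/ds values produced upstream; all must be
#' strictly positive (log transforms are applied downstream of this
#' reader, and ranks are unaffected either way).
#'
#' @param path TSV file with a header of category names and a first
#'   column of branch labels.
#' @param sep Field separator.
#' @return Numeric matrix with branch row names.
#' @export
load_rate_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("rate table has missing cells", call. = FALSE)
  if (any(m <= 0)) stop("substitution rates must be > 0", call. = FALSE)
  m
}
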