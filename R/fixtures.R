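#' Packaged reference tables
#'
#' Small machine-readable reference tables shipped with the package.
#'
#' `receptor_annotation()` returns the neuropeptide receptor overview
#' table: 38 receptor-encoding genes with their neuropeptide family and
#' the three microarray quality-control metrics (mean intensity,
#' correlation with RNA-seq, differential stability) plus mean
#' normalized expression in cortex, hypothalamus and subcortex, all
#' printed at two decimals.
#'
#' `signaling_gene_sets()` returns the receptor gene symbols used to
#' contextualize the evolutionary analysis, labeled by signaling class
#' (13 ionotropic and 23 metabotropic neurotransmitter receptor genes).
#'
#' `example_atlas()` returns a packaged 455-region whole-brain atlas
#' (400 cortical regions over seven intrinsic networks, 54 subcortical
#' regions over seven structures, one hypothalamus region) with
#' synthetic centroids laid out as a cortical shell around a
#' subcortical core.
#'
#' @return A data frame ([receptor_annotation()],
#'   [signaling_gene_sets()]) or a [region_atlas] ([example_atlas()]).
#' @examples
#' nrow(receptor_annotation())            # 38
#' table(signaling_gene_sets()$class)     # 13 ionotropic, 23 metabotropic
#' @export
receptor_annotation <- function() {
  path <- system.file("extdata", "receptor_annotation.tsv",
                      package = "neuropepmap", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "",
                    fileEncoding = "UTF-8")
}

#' @rdname receptor_annotation
#' @export
signaling_gene_sets <- function() {
  path <- system.file("extdata", "signaling_gene_sets.tsv",
                      package = "neuropepmap", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "",
                    fileEncoding = "UTF-8")
}

#' @rdname receptor_annotation
#' @export
example_atlas <- function() {
  path <- system.file("extdata", "atlas_455.tsv",
                      package = "neuropepmap", mustWork = TRUE)
  load_region_atlas(path)
}
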