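#' PairedExpression: matched transcriptome/translatome profiles
#'
#' An S4 container for genes x samples log2 expression measured at two
#' levels in the same samples: total cytoplasmic mRNA (transcriptome) and
#' polysome-associated mRNA (translatome). It extends
#' [SummarizedExperiment::SummarizedExperiment] with two mandatory assays,
#' `"transcriptome"` and `"translatome"`, sharing gene and sample indices.
#' Optional per-cell QC flag assays (`"above_background"`, `"good_spot"`,
#' `"saturated"`, `"outlier"`) may be carried alongside for probe filtering.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [PairedExpression()] (constructor), [transcriptome()],
#'   [translatome()], [teMatrix()]
#' @export
setClass("PairedExpression", contains = "SummarizedExperiment")

setValidity("PairedExpression", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("transcriptome", "translatome") %in% an))
    return("assays must include 'transcriptome' and 'translatome'")
  tc <- SummarizedExperiment::assay(object, "transcriptome")
  tl <- SummarizedExperiment::assay(object, "translatome")
  if (!identical(dim(tc), dim(tl)))
    return("transcriptome and translatome assays must share dimensions")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("gene (row) names must be present and unique")
  TRUE
})

#' Construct a PairedExpression object
#'
#' @param transcriptome,translatome numeric genes x samples matrices of log2
#'   intensities with identical dimnames. Missing values are allowed and are
#'   excluded pairwise by downstream statistics.
#' @param rowRanges optional [GenomicRanges::GRanges] of gene loci (as
#'   returned by [readAnnotation()] or [simulateAnnotation()]), matched to
#'   rows by `gene_id`.
#' @param colData optional per-sample `DataFrame`.
#' @param ... further assays (e.g. QC flag matrices of the same shape).
#'
#' @return a [PairedExpression-class] object.
#' @examples
#' tc <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("A", "B")))
#' pe <- PairedExpression(tc, tc + 1)
#' teMatrix(pe)
#' @export
PairedExpression <- function(transcriptome, translatome, rowRanges = NULL,
                             colData = NULL, ...) {
  transcriptome <- as.matrix(transcriptome)
  translatome <- as.matrix(translatome)
  if (!identical(dimnames(transcriptome), dimnames(translatome)))
    stop("transcriptome and translatome must share gene and sample names")
  assays <- c(list(transcriptome = transcriptome, translatome = translatome),
              list(...))
  args <- list(assays = assays)
  if (!is.null(colData)) args$colData <- colData
  if (!is.null(rowRanges)) {
    idx <- match(rownames(transcriptome), rowRanges$gene_id)
    if (anyNA(idx))
      stop("rowRanges is missing gene_id for: ",
           paste(utils::head(rownames(transcriptome)[is.na(idx)], 3),
                 collapse = ", "))
    args$rowRanges <- rowRanges[idx]
  }
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  methods::new("PairedExpression", se)
}

#' @describeIn PairedExpression transcriptome (total mRNA) assay
#' @param x a `PairedExpression`
#' @export
transcriptome <- function(x) SummarizedExperiment::assay(x, "transcriptome")

#' @describeIn PairedExpression translatome (polysomal mRNA) assay
#' @export
translatome <- function(x) SummarizedExperiment::assay(x, "translatome")

setMethod("show", "PairedExpression", function(object) {
  cat("PairedExpression:", nrow(object), "genes x", ncol(object),
      "samples (transcriptome + translatome)\n")
  methods::callNextMethod()
})
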