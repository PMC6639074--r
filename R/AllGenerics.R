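#' @include AllClasses.R
NULL

#' Panel accessors
#'
#' Small accessors shared by [PanelDesign-class], [CountMatrix-class] and
#' [IntensityMatrix-class]: sample identifiers, bait identifiers, the number
#' of baits `K`, the replicate samples of one bait, and (for matrices) the
#' embedded design.
#'
#' @param x a `PanelDesign`, `CountMatrix` or `IntensityMatrix`.
#' @param bait a single bait identifier.
#' @return `sampleIds`/`baitIds`: character vectors; `nBaits`: integer K;
#'   `replicateSamples`: character vector of that bait's sample IDs in
#'   design order; `panelDesign`: the [PanelDesign-class].
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname panel-accessors
#' @export
setGeneric("baitIds", function(x) standardGeneric("baitIds"))
#' @rdname panel-accessors
#' @export
setGeneric("nBaits", function(x) standardGeneric("nBaits"))
#' @rdname panel-accessors
#' @export
setGeneric("replicateSamples", function(x, bait) standardGeneric("replicateSamples"))
#' @rdname panel-accessors
#' @export
setGeneric("panelDesign", function(x) standardGeneric("panelDesign"))

#' @rdname panel-accessors
#' @export
setMethod("sampleIds", "PanelDesign", function(x) x@design$sample_id)
#' @rdname panel-accessors
#' @export
setMethod("baitIds", "PanelDesign", function(x) unique(x@design$bait_id))
#' @rdname panel-accessors
#' @export
setMethod("nBaits", "PanelDesign", function(x) length(unique(x@design$bait_id)))
#' @rdname panel-accessors
#' @export
setMethod("replicateSamples", "PanelDesign", function(x, bait) {
    d <- x@design
    d$sample_id[d$bait_id == bait]
})

.designFromColData <- function(x) {
    cd <- as.data.frame(colData(x))
    PanelDesign(data.frame(sample_id = colnames(x),
                           bait_id = cd$bait_id,
                           gtpase_name = cd$gtpase_name,
                           nucleotide_state = cd$nucleotide_state,
                           stringsAsFactors = FALSE))
}

#' @rdname panel-accessors
#' @export
setMethod("panelDesign", "SummarizedExperiment", .designFromColData)
#' @rdname panel-accessors
#' @export
setMethod("sampleIds", "SummarizedExperiment", function(x) colnames(x))
#' @rdname panel-accessors
#' @export
setMethod("baitIds", "SummarizedExperiment",
          function(x) unique(colData(x)$bait_id))
#' @rdname panel-accessors
#' @export
setMethod("nBaits", "SummarizedExperiment",
          function(x) length(unique(colData(x)$bait_id)))
#' @rdname panel-accessors
#' @export
setMethod("replicateSamples", "SummarizedExperiment", function(x, bait) {
    colnames(x)[colData(x)$bait_id == bait]
})

## bait-level lookup tables used across modules
.baitInfo <- function(design) {
    unique(design@design[, c("bait_id", "gtpase_name", "nucleotide_state")])
}

#' @rdname collapseDuplicateGenes
#' @export
setGeneric("collapseDuplicateGenes",
           function(x, ...) standardGeneric("collapseDuplicateGenes"))

#' @rdname logTransform
#' @export
setGeneric("logTransform", function(x, ...) standardGeneric("logTransform"))

#' @rdname filterMinValid
#' @export
setGeneric("filterMinValid",
           function(x, minValid = 2L, ...) standardGeneric("filterMinValid"))

#' @rdname imputeDownshift
#' @export
setGeneric("imputeDownshift",
           function(x, width = 0.3, downshift = 1.8, seed = NULL, ...)
               standardGeneric("imputeDownshift"))
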