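#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData rowData<-
NULL

.VALID_STATES <- c("GTP", "GDP", "NONE")

#' Bait panel design
#'
#' Maps every replicate sample of a proximity-biotinylation panel to a bait:
#' a GTPase locked in one nucleotide state, or a ligase-only control. The
#' design is the backbone of the panel-comparative statistics: the number of
#' baits `K` sets the scale of the D/WD specificity scores, and the nucleotide
#' state of each bait determines which samples form the pooled negative-state
#' background of the enrichment branch.
#'
#' @slot design a `data.frame` with one row per sample and columns
#'   `sample_id`, `bait_id`, `gtpase_name`, `nucleotide_state`
#'   (`"GTP"`, `"GDP"` or `"NONE"`). Row order fixes replicate order.
#'
#' @aliases PanelDesign
#' @export
setClass("PanelDesign", slots = c(design = "data.frame"))

.validPanelDesign <- function(object) {
    d <- object@design
    msg <- character()
    need <- c("sample_id", "bait_id", "gtpase_name", "nucleotide_state")
    if (!all(need %in% names(d)))
        return(paste("design must have columns:", paste(need, collapse = ", ")))
    if (nrow(d) == 0L)
        msg <- c(msg, "design has no samples")
    dup <- unique(d$sample_id[duplicated(d$sample_id)])
    if (length(dup))
        msg <- c(msg, paste0("duplicate sample_id(s): ",
                             paste(dup, collapse = ", ")))
    bad <- setdiff(unique(d$nucleotide_state), .VALID_STATES)
    if (length(bad))
        msg <- c(msg, paste0("unknown nucleotide_state value(s): ",
                             paste(bad, collapse = ", ")))
    ## one (gtpase_name, state) per bait_id
    per <- unique(d[, c("bait_id", "gtpase_name", "nucleotide_state")])
    if (anyDuplicated(per$bait_id))
        msg <- c(msg, "a bait_id maps to more than one gtpase_name/state")
    ctrl <- per$gtpase_name == "control"
    none <- per$nucleotide_state == "NONE"
    if (any(ctrl != none))
        msg <- c(msg, "nucleotide_state must be NONE iff gtpase_name is 'control'")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
}
setValidity("PanelDesign", .validPanelDesign)

#' Construct a PanelDesign
#'
#' @param design data.frame with columns `sample_id`, `bait_id`,
#'   `gtpase_name`, `nucleotide_state`.
#' @return a validated [PanelDesign-class] object.
#' @examples
#' d <- data.frame(
#'   sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
#'   bait_id = rep(c("RAB5A_GTP", "RAB5A_GDP"), each = 3),
#'   gtpase_name = "RAB5A",
#'   nucleotide_state = rep(c("GTP", "GDP"), each = 3))
#' PanelDesign(d)
#' @export
PanelDesign <- function(design) {
    design <- as.data.frame(design, stringsAsFactors = FALSE)
    for (col in intersect(names(design),
                          c("sample_id", "bait_id", "gtpase_name",
                            "nucleotide_state")))
        design[[col]] <- as.character(design[[col]])
    new("PanelDesign", design = design)
}

#' Spectral-count layer of a bait panel
#'
#' A `SummarizedExperiment` holding preys x samples total spectral counts
#' (assay `"counts"`, non-negative integers) with the panel design carried in
#' `colData` (`bait_id`, `gtpase_name`, `nucleotide_state`).
#'
#' @aliases CountMatrix
#' @export
setClass("CountMatrix", contains = "SummarizedExperiment")

setValidity("CountMatrix", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    x <- assay(object, "counts")
    if (length(x)) {
        if (any(is.na(x)))
            msg <- c(msg, "counts contain NA")
        else {
            if (any(x < 0)) msg <- c(msg, "counts must be >= 0")
            if (any(x != round(x))) msg <- c(msg, "counts must be integers")
        }
    }
    need <- c("bait_id", "gtpase_name", "nucleotide_state")
    if (!all(need %in% names(colData(object))))
        msg <- c(msg, "colData must carry bait_id, gtpase_name, nucleotide_state")
    if (nrow(object) > 0L && is.null(rownames(object)))
        msg <- c(msg, "prey identifiers (rownames) are required")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts numeric matrix of non-negative integer spectral counts with
#'   prey identifiers as rownames and sample IDs as colnames.
#' @param design a [PanelDesign-class]; every count column must map to a bait.
#' @return a validated [CountMatrix-class].
#' @export
CountMatrix <- function(counts, design) {
    counts <- as.matrix(counts)
    .newPanelSE("CountMatrix", list(counts = counts), design)
}

#' Label-free intensity layer of a bait panel
#'
#' A `SummarizedExperiment` holding preys x samples label-free quantification
#' intensities (assay `"intensity"`). On the raw scale entries are
#' non-negative reals with 0 meaning "not detected"; after [logTransform()]
#' entries are log2 intensities with `NA` as the missing marker.
#'
#' @slot logScale logical flag; `TRUE` after log2 transformation.
#' @aliases IntensityMatrix
#' @export
setClass("IntensityMatrix", contains = "SummarizedExperiment",
         slots = c(logScale = "logical"),
         prototype = prototype(logScale = FALSE))

setValidity("IntensityMatrix", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        return("assay 'intensity' is required")
    x <- assay(object, "intensity")
    if (length(x)) {
        if (isTRUE(object@logScale)) {
            if (any(is.infinite(x), na.rm = TRUE))
                msg <- c(msg, "log-scale intensities must be finite or NA")
        } else {
            if (any(is.na(x)))
                msg <- c(msg, "raw-scale intensities must not be NA (0 = not detected)")
            else if (any(x < 0))
                msg <- c(msg, "raw-scale intensities must be >= 0")
        }
    }
    need <- c("bait_id", "gtpase_name", "nucleotide_state")
    if (!all(need %in% names(colData(object))))
        msg <- c(msg, "colData must carry bait_id, gtpase_name, nucleotide_state")
    if (nrow(object) > 0L && is.null(rownames(object)))
        msg <- c(msg, "prey identifiers (rownames) are required")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an IntensityMatrix
#'
#' @param intensity numeric matrix of intensities (rownames = preys,
#'   colnames = sample IDs).
#' @param design a [PanelDesign-class].
#' @param logScale logical; is the matrix already on log2 scale?
#' @return a validated [IntensityMatrix-class].
#' @export
IntensityMatrix <- function(intensity, design, logScale = FALSE) {
    intensity <- as.matrix(intensity)
    obj <- .newPanelSE("IntensityMatrix", list(intensity = intensity), design,
                       logScale = logScale)
    obj
}

## shared constructor: order columns by design, attach design as colData
.newPanelSE <- function(class, assays, design, ...) {
    m <- assays[[1L]]
    if (is.null(colnames(m)))
        stop("sample IDs (colnames) are required")
    d <- design@design
    unmapped <- setdiff(colnames(m), d$sample_id)
    if (length(unmapped))
        stop("sample(s) not in panel design: ", paste(unmapped, collapse = ", "))
    ## keep design (file) order for the samples that are present
    keep <- d$sample_id[d$sample_id %in% colnames(m)]
    m <- m[, keep, drop = FALSE]
    assays[[1L]] <- m
    cd <- d[match(keep, d$sample_id), , drop = FALSE]
    cdf <- DataFrame(cd[, setdiff(names(cd), "sample_id"), drop = FALSE],
                     row.names = cd$sample_id)
    se <- SummarizedExperiment(assays = assays, colData = cdf)
    new(class, se, ...)
}

#' One contrast of the enrichment branch
#'
#' Defines a two-group comparison: the replicates of one bait against a pooled
#' GDP-state background. GTP-locked baits are compared against the replicates
#' of *all* GDP-locked baits; GDP-locked baits against all *other* GDP-locked
#' baits (see [buildContrasts()]).
#'
#' @slot testBait bait identifier of the test group.
#' @slot testSamples sample IDs of the bait's replicates.
#' @slot backgroundSamples sample IDs of the pooled background.
#' @slot label human-readable contrast label.
#' @aliases ContrastSpec
#' @export
setClass("ContrastSpec",
         slots = c(testBait = "character", testSamples = "character",
                   backgroundSamples = "character", label = "character"))

setValidity("ContrastSpec", function(object) {
    msg <- character()
    if (!length(object@testSamples)) msg <- c(msg, "empty test group")
    if (!length(object@backgroundSamples)) msg <- c(msg, "empty background group")
    if (length(intersect(object@testSamples, object@backgroundSamples)))
        msg <- c(msg, "test and background samples overlap")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "PanelDesign", function(object) {
    d <- object@design
    cat("PanelDesign:", length(unique(d$bait_id)), "baits,",
        nrow(d), "samples\n")
    st <- table(unique(d[, c("bait_id", "nucleotide_state")])$nucleotide_state)
    cat("  states:", paste(names(st), st, sep = "=", collapse = " "), "\n")
    invisible(NULL)
})

setMethod("show", "ContrastSpec", function(object) {
    cat("ContrastSpec", object@label, ":", length(object@testSamples),
        "test vs", length(object@backgroundSamples), "background samples\n")
    invisible(NULL)
})
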