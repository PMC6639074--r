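#' @include AllGenerics.R
NULL

#' Simulate a panel and write its files
#'
#' Convenience wrapper around [generatePanel()] + [writePanelFiles()]: draws
#' a synthetic panel and writes `design.tsv`, `counts.tsv`,
#' `intensities.tsv`, `truth.tsv` and a JSON run manifest into `dir`.
#'
#' @param cfg a [simConfig()]; if `NULL`, defaults are used.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
simulatePanelFiles <- function(cfg = simConfig(), dir) {
    panel <- generatePanel(cfg)
    paths <- writePanelFiles(panel, dir)
    manifest <- list(
        tool = "proxComp", version = as.character(utils::packageVersion("proxComp")),
        stage = "simulate",
        config = cfg[setdiff(names(cfg), "biotinCarriers")],
        biotinCarriers = cfg$biotinCarriers,
        n_preys = nrow(panel$counts), n_samples = ncol(panel$counts))
    mPath <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(c(paths, manifest = mPath))
}

#' Run the full scoring pipeline
#'
#' End-to-end comparative analysis of a bait panel: reads the design and the
#' count matrix, optionally the proteinGroups-style intensity table, collapses
#' duplicate gene rows, computes the spectral-count (compass) scores and the
#' intensity enrichment branch, integrates them into bubble-volcano records
#' and ranked hit tables, and writes `<prefix>.compass.tsv`,
#' `<prefix>.enrichment.tsv`, `<prefix>.bubble.tsv`, `<prefix>.ranked.tsv`
#' plus a JSON run manifest recording parameters, seeds and per-stage row
#' counts. With no intensity file the enrichment branch is skipped with a
#' warning and ranking falls back to WD only.
#'
#' @param designFile path to the panel design TSV.
#' @param countsFile path to the spectral-count TSV.
#' @param intensitiesFile optional path to the proteinGroups-style TSV.
#' @param prefix output path prefix.
#' @param minValid,width,downshift,nPerm,s0,fdrMethod enrichment parameters,
#'   see [runEnrichment()].
#' @param aggregate count aggregation for `X_bar`, see [computeCompass()].
#' @param normalizePercentile optional percentile for [normalizeWD()]
#'   (`NULL` = off; bubble sizing always uses raw WD).
#' @param annotations optional known-interactor data.frame or path to a TSV
#'   with columns `bait_id`, `prey_id`, optional `category`.
#' @param dropContaminants remove rows flagged "Potential contaminant".
#' @param rankKey ranking key, `"WD"` or `"p_value"`.
#' @param seed global integer seed; stage seeds are derived from it.
#' @return invisibly, a list with the result tables and the manifest.
#' @export
runScorePipeline <- function(designFile, countsFile, intensitiesFile = NULL,
                             prefix, minValid = 2L, width = 0.3,
                             downshift = 1.8, nPerm = 250L, s0 = 0,
                             fdrMethod = c("permutation", "BH"),
                             aggregate = c("mean", "sum"),
                             normalizePercentile = NULL,
                             annotations = NULL, dropContaminants = FALSE,
                             rankKey = c("WD", "p_value"), seed = 1L) {
    fdrMethod <- match.arg(fdrMethod)
    aggregate <- match.arg(aggregate)
    rankKey <- match.arg(rankKey)
    if (is.character(annotations))
        annotations <- utils::read.delim(annotations, sep = "\t",
                                         stringsAsFactors = FALSE)
    counts <- list(rows_in = NA_integer_)
    design <- readPanelDesign(designFile)
    cm <- readCountMatrix(countsFile, design)
    rowsCountsIn <- nrow(cm)
    cm <- collapseDuplicateGenes(cm)
    compass <- computeCompass(cm, aggregate = aggregate)
    if (!is.null(normalizePercentile))
        compass <- normalizeWD(compass, normalizePercentile)

    rowCounts <- list(counts_rows = rowsCountsIn,
                      counts_rows_collapsed = nrow(cm),
                      compass_rows = nrow(compass))
    tables <- list(compass = compass)
    enrich <- NULL; bubble <- NULL; ranked <- NULL
    if (!is.null(intensitiesFile)) {
        im <- readProteinGroups(intensitiesFile, design,
                                dropContaminants = dropContaminants)
        rowCounts$intensity_rows <- nrow(im)
        im <- collapseDuplicateGenes(im)
        rowCounts$intensity_rows_collapsed <- nrow(im)
        enrich <- runEnrichment(im, minValid = minValid, width = width,
                                downshift = downshift, nPerm = nPerm,
                                s0 = s0, fdrMethod = fdrMethod, seed = seed)
        rowCounts$enrichment_rows <- nrow(enrich)
        contam <- rownames(im)[rowData(im)$is_contaminant]
        bubble <- assembleBubbleVolcano(enrich, compass, design,
                                        annotations = annotations,
                                        contaminants = contam)
        ranked <- rankHits(bubble, key = rankKey, counts = cm)
        tables$enrichment <- enrich
        tables$bubble <- bubble[, setdiff(names(bubble), "is_bait_protein"),
                                drop = FALSE]
        tables$ranked <- ranked
    } else {
        warning("no intensity file supplied; enrichment branch skipped")
        ranked <- rankHits(
            within(compass, {
                wd <- WD
            }), key = "WD", counts = cm)
        if (!is.null(annotations)) ranked <- annotateKnown(ranked, annotations)
        tables$ranked <- ranked
    }
    writeResultTables(tables[setdiff(names(tables), "bubble")], prefix)
    if (!is.null(bubble))
        exportPlotData(bubble, paste0(prefix, ".bubble.tsv"))
    manifest <- list(
        tool = "proxComp",
        version = as.character(utils::packageVersion("proxComp")),
        stage = "score",
        parameters = list(minValid = minValid, width = width,
                          downshift = downshift, nPerm = nPerm, s0 = s0,
                          fdrMethod = fdrMethod, aggregate = aggregate,
                          rankKey = rankKey, seed = seed,
                          dropContaminants = dropContaminants),
        inputs = list(design = designFile, counts = countsFile,
                      intensities = intensitiesFile),
        row_counts = rowCounts)
    jsonlite::write_json(manifest, paste0(prefix, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(compass = compass, enrichment = enrich, bubble = bubble,
                   ranked = ranked, manifest = manifest))
}

#' Re-export ranked and bubble tables from a score run
#'
#' Reads the `compass` and `enrichment` tables written by
#' [runScorePipeline()] under `prefix`, re-assembles the bubble-volcano
#' records (optionally with annotations) and writes `<prefix>.bubble.tsv`,
#' `<prefix>.ranked.tsv` and, optionally, one minimal SVG scatter per
#' contrast.
#'
#' @param prefix path prefix of an existing score run.
#' @param designFile path to the panel design TSV.
#' @param annotations optional annotation data.frame or TSV path.
#' @param svg logical; also write per-contrast SVG scatters.
#' @param rankKey ranking key, `"WD"` or `"p_value"`.
#' @return invisibly, the bubble record table.
#' @export
reportFromPrefix <- function(prefix, designFile, annotations = NULL,
                             svg = FALSE, rankKey = c("WD", "p_value")) {
    rankKey <- match.arg(rankKey)
    cPath <- paste0(prefix, ".compass.tsv")
    ePath <- paste0(prefix, ".enrichment.tsv")
    if (!file.exists(cPath) || !file.exists(ePath))
        stop("missing upstream outputs under prefix ", prefix)
    if (is.character(annotations))
        annotations <- utils::read.delim(annotations, sep = "\t",
                                         stringsAsFactors = FALSE)
    compass <- utils::read.delim(cPath, stringsAsFactors = FALSE)
    enrich <- utils::read.delim(ePath, stringsAsFactors = FALSE)
    design <- readPanelDesign(designFile)
    if (!nrow(enrich)) warning("empty enrichment table; header-only outputs")
    bubble <- assembleBubbleVolcano(enrich, compass, design,
                                    annotations = annotations)
    exportPlotData(bubble, paste0(prefix, ".bubble.tsv"))
    if (nrow(bubble)) {
        ranked <- rankHits(bubble, key = rankKey)
        .writeTsv(ranked[, setdiff(names(ranked), "is_bait_protein"),
                         drop = FALSE],
                  paste0(prefix, ".ranked.tsv"))
        if (svg) {
            for (lb in unique(bubble$contrast_label)) {
                sub <- bubble[bubble$contrast_label == lb &
                              !bubble$is_bait_protein, , drop = FALSE]
                df <- data.frame(x = sub$log2fc, y = sub$neg_log10_p,
                                 size = sub$bubble_size,
                                 is_known_interactor = sub$is_known_interactor)
                .writeSvgScatter(df, paste0(prefix, ".", lb, ".svg"))
            }
        }
    }
    invisible(bubble)
}
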