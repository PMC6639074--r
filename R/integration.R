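#' @include AllGenerics.R
NULL

#' Default endogenous biotin-carrier genes
#'
#' Endogenously biotinylated carboxylases dominate every streptavidin
#' pulldown regardless of bait; they are flagged (not dropped) so readers can
#' discount them.
#' @return character vector of gene symbols.
#' @export
endogenousBiotinCarriers <- function() {
    c("ACACA", "PC", "PCCA", "PCCB", "MCCC1", "MCCC2")
}

#' Combine the enrichment and spectral-count branches
#'
#' Left-joins the WD score of each contrast's test bait onto that contrast's
#' enrichment rows, producing one bubble-volcano record per post-filter prey
#' per contrast: x = log2 fold change, y = -log10 p, point size proportional
#' to the square root of the WD score (scaled panel-wide to `sizeMax`).
#' Preys absent from the compass table get `wd = 0`. The bait's own gene is
#' flagged (`is_bait_protein`) and later excluded from plot export — its
#' self-signal would dwarf every real hit — but kept in this table.
#' Endogenous biotin carriers and (when annotated) known interactors and
#' contaminants are flagged and retained.
#'
#' @param enrich an enrichment table from [runEnrichment()].
#' @param compass a compass score table from [computeCompass()].
#' @param design the [PanelDesign-class] of the panel.
#' @param annotations optional data.frame (`bait_id`, `prey_id`, optional
#'   `category`) of known interactors; see [annotateKnown()].
#' @param biotinCarriers gene symbols flagged as endogenous biotin carriers.
#' @param sizeMax bubble size assigned to the largest `sqrt(WD)` panel-wide.
#' @param contaminants optional character vector of contaminant prey IDs.
#' @return a `data.frame` of bubble records with columns `contrast_label`,
#'   `bait_id`, `prey_id`, `log2fc`, `neg_log10_p`, `p_value`, `fdr`, `wd`,
#'   `bubble_size` and logical flag columns.
#' @export
assembleBubbleVolcano <- function(enrich, compass, design,
                                  annotations = NULL,
                                  biotinCarriers = endogenousBiotinCarriers(),
                                  sizeMax = 10,
                                  contaminants = NULL) {
    stopifnot(is.data.frame(enrich), is.data.frame(compass))
    info <- .baitInfo(design)
    baitsUsed <- unique(enrich$bait_id)
    absent <- setdiff(baitsUsed, unique(compass$bait_id))
    if (length(absent))
        stop("contrast bait(s) absent from compass table: ",
             paste(absent, collapse = ", "))
    key <- paste(compass$bait_id, compass$prey_id, sep = "\r")
    i <- match(paste(enrich$bait_id, enrich$prey_id, sep = "\r"), key)
    wd <- ifelse(is.na(i), 0, compass$WD[i])
    gtpase <- info$gtpase_name[match(enrich$bait_id, info$bait_id)]
    rec <- data.frame(
        contrast_label = enrich$contrast_label,
        bait_id = enrich$bait_id,
        prey_id = enrich$prey_id,
        log2fc = enrich$log2fc,
        neg_log10_p = enrich$neg_log10_p,
        p_value = enrich$p_value,
        fdr = enrich$fdr,
        wd = wd,
        stringsAsFactors = FALSE)
    sqrtWd <- sqrt(rec$wd)
    topSize <- if (length(sqrtWd)) max(sqrtWd) else 0
    rec$bubble_size <- if (topSize > 0) sizeMax * sqrtWd / topSize else sqrtWd
    rec$is_bait_protein <- toupper(rec$prey_id) == toupper(gtpase)
    rec$is_endogenous_biotin <- rec$prey_id %in% biotinCarriers
    rec$is_contaminant <- if (is.null(contaminants)) FALSE
                          else rec$prey_id %in% contaminants
    rec$is_known_interactor <- FALSE
    rec$known_category <- NA_character_
    if (!is.null(annotations)) rec <- annotateKnown(rec, annotations)
    rec
}

#' Annotate known interactors
#'
#' Flags rows of a result table that match a user-supplied list of known
#' interactors per bait, adding/updating `is_known_interactor` and
#' `known_category` (e.g. effector / GAP / GEF / other). Names not present
#' in the table are reported via `message()`; no rows are added.
#'
#' @param table a data.frame with `bait_id` and `prey_id` columns.
#' @param known a data.frame with columns `bait_id`, `prey_id` and optional
#'   `category`, or a named list mapping bait IDs to character vectors of
#'   prey IDs.
#' @return the annotated table.
#' @export
annotateKnown <- function(table, known) {
    if (is.null(known) || (is.data.frame(known) && !nrow(known)) ||
        (!is.data.frame(known) && !length(known)))
        return(table)
    if (!is.data.frame(known)) {
        known <- data.frame(
            bait_id = rep(names(known), lengths(known)),
            prey_id = unlist(known, use.names = FALSE),
            stringsAsFactors = FALSE)
    }
    if (!"category" %in% names(known)) known$category <- "other"
    if (!"is_known_interactor" %in% names(table))
        table$is_known_interactor <- FALSE
    if (!"known_category" %in% names(table))
        table$known_category <- NA_character_
    tabKey <- paste(table$bait_id, table$prey_id, sep = "\r")
    knKey <- paste(known$bait_id, known$prey_id, sep = "\r")
    hit <- match(tabKey, knKey)
    table$is_known_interactor <- table$is_known_interactor | !is.na(hit)
    table$known_category <- ifelse(!is.na(hit), known$category[hit],
                                   table$known_category)
    unmatched <- setdiff(knKey, tabKey)
    if (length(unmatched))
        message("annotateKnown: ", length(unmatched),
                " known interactor(s) not present in table")
    table
}

#' Rank hits per contrast
#'
#' Orders each contrast's records by descending WD score (or ascending
#' p-value) with deterministic tie-breaking on the prey identifier, and
#' assigns ranks 1..n. When a [CountMatrix-class] is supplied, the test
#' bait's per-replicate spectral counts are attached (`count_rep1`, ...) for
#' replicate-dot reporting, where circle area is drawn proportional to the
#' count.
#'
#' @param records a data.frame with `contrast_label`, `bait_id`, `prey_id`
#'   and the ranking key columns (`wd`/`WD`, `p_value`).
#' @param key `"WD"` (descending) or `"p_value"` (ascending).
#' @param counts optional [CountMatrix-class] for per-replicate counts.
#' @return the table with a `rank` column, sorted; re-ranking is the
#'   identity.
#' @export
rankHits <- function(records, key = c("WD", "p_value"), counts = NULL) {
    key <- match.arg(key)
    stopifnot(nrow(records) > 0)
    wdCol <- if ("wd" %in% names(records)) "wd" else "WD"
    keyVal <- switch(key,
                     WD = -records[[wdCol]],
                     p_value = records$p_value)
    grp <- if ("contrast_label" %in% names(records)) records$contrast_label
           else records$bait_id
    ord <- order(grp, keyVal, records$prey_id)
    out <- records[ord, , drop = FALSE]
    out$rank <- stats::ave(seq_len(nrow(out)), out[[if ("contrast_label" %in%
        names(out)) "contrast_label" else "bait_id"]],
        FUN = seq_along)
    rownames(out) <- NULL
    if (!is.null(counts)) {
        m <- assay(counts, "counts")
        bait <- as.character(colData(counts)$bait_id)
        maxRep <- max(table(bait))
        for (r in seq_len(maxRep))
            out[[paste0("count_rep", r)]] <- NA_real_
        for (b in unique(out$bait_id)) {
            cols <- which(bait == b)
            rows <- which(out$bait_id == b)
            pr <- match(out$prey_id[rows], rownames(m))
            for (r in seq_along(cols)) {
                v <- rep(NA_real_, length(rows))
                ok <- !is.na(pr)
                v[ok] <- m[pr[ok], cols[r]]
                out[[paste0("count_rep", r)]][rows] <- v
            }
        }
    }
    out
}

#' Export bubble-volcano plot data
#'
#' Writes `<path>` as a tab-separated table of plot-ready bubble records
#' (columns `x` = log2 fold change, `y` = -log10 p, `size` = bubble size,
#' plus identifiers and flags). Records flagged `is_bait_protein` are
#' excluded: each plot omits the bait itself. Optionally also writes a
#' minimal SVG scatter for visual sanity checking.
#'
#' @param records bubble records from [assembleBubbleVolcano()].
#' @param path output TSV path.
#' @param svg optional path for a minimal SVG scatter (no styling
#'   guarantees).
#' @return invisibly, the TSV path.
#' @export
exportPlotData <- function(records, path, svg = NULL) {
    keep <- records[!records$is_bait_protein, , drop = FALSE]
    out <- data.frame(
        contrast_label = keep$contrast_label,
        prey_id = keep$prey_id,
        x = keep$log2fc,
        y = keep$neg_log10_p,
        size = keep$bubble_size,
        is_endogenous_biotin = keep$is_endogenous_biotin,
        is_known_interactor = keep$is_known_interactor,
        is_contaminant = keep$is_contaminant,
        stringsAsFactors = FALSE)
    ord <- order(out$contrast_label, -out$size, out$prey_id)
    out <- out[ord, , drop = FALSE]
    utils::write.table(
        local({
            o <- out
            for (j in seq_along(o))
                if (is.double(o[[j]])) o[[j]] <- .formatNum(o[[j]])
            o
        }),
        path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA",
        eol = "\n", fileEncoding = "UTF-8")
    if (!is.null(svg)) .writeSvgScatter(out, svg)
    invisible(path)
}

## tiny dependency-free SVG scatter; one circle per record
.writeSvgScatter <- function(df, path, w = 640, h = 480) {
    if (!nrow(df)) { writeLines("<svg xmlns='http://www.w3.org/2000/svg'/>", path); return(invisible(path)) }
    rx <- range(df$x, finite = TRUE); ry <- range(df$y, finite = TRUE)
    pad <- 40
    sx <- function(v) pad + (v - rx[1]) / max(diff(rx), 1e-9) * (w - 2 * pad)
    sy <- function(v) h - pad - (v - ry[1]) / max(diff(ry), 1e-9) * (h - 2 * pad)
    lines <- c(sprintf("<svg xmlns='http://www.w3.org/2000/svg' width='%d' height='%d'>", w, h),
               sprintf("<circle cx='%.2f' cy='%.2f' r='%.2f' fill='%s' fill-opacity='0.5'/>",
                       sx(df$x), sy(df$y), pmax(1, df$size),
                       ifelse(df$is_known_interactor, "red", "grey")),
               "</svg>")
    writeLines(lines, path)
    invisible(path)
}
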