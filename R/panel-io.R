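#' @include AllGenerics.R
NULL

#' Read a panel design table
#'
#' Reads a tab-separated table with columns `sample_id`, `bait_id`,
#' `gtpase_name`, `nucleotide_state` (one row per replicate sample) and
#' validates it into a [PanelDesign-class]. Replicate order is preserved as
#' in the file.
#'
#' @param path path to the tab-separated design file.
#' @return a [PanelDesign-class].
#' @export
readPanelDesign <- function(path) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("sample_id", "bait_id", "gtpase_name", "nucleotide_state")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("design file lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(d) == 0L) stop("design file is empty")
    PanelDesign(d[, need])
}

#' Read a spectral-count matrix
#'
#' Reads a tab-separated preys x samples table of total spectral counts. The
#' first column holds prey (gene) identifiers; the remaining column headers
#' are sample IDs, all of which must map to baits of `design`. Empty cells
#' are read as 0 (no spectral evidence); non-integer cells are an error.
#'
#' @param path path to the tab-separated count file.
#' @param design a [PanelDesign-class].
#' @return a [CountMatrix-class].
#' @export
readCountMatrix <- function(path, design) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(d) < 2L) stop("count file needs a prey column plus sample columns")
    preys <- as.character(d[[1L]])
    m <- d[, -1L, drop = FALSE]
    unmapped <- setdiff(names(m), sampleIds(design))
    if (length(unmapped))
        stop("count file column(s) not in panel design: ",
             paste(unmapped, collapse = ", "))
    for (j in seq_along(m)) {
        v <- m[[j]]
        if (is.character(v)) v[v == ""] <- NA
        v <- suppressWarnings(as.numeric(v))
        bad <- which(!is.na(m[[j]]) & m[[j]] != "" & is.na(v))
        if (length(bad))
            stop(sprintf("non-numeric count in row %d, column '%s': '%s'",
                         bad[1L], names(m)[j], as.character(m[[j]][bad[1L]])))
        nonint <- which(!is.na(v) & v != round(v))
        if (length(nonint))
            stop(sprintf("non-integer count in row %d, column '%s': %s",
                         nonint[1L], names(m)[j], v[nonint[1L]]))
        v[is.na(v)] <- 0
        m[[j]] <- v
    }
    mat <- as.matrix(m)
    rownames(mat) <- preys
    CountMatrix(mat, design)
}

#' Read a MaxQuant proteinGroups-style intensity table
#'
#' Parses the proteinGroups dialect: one row per protein group with columns
#' `"Majority protein IDs"`, `"Gene names"`, per-sample `"LFQ intensity
#' <sample_id>"` columns and flag columns `"Reverse"` and `"Only identified
#' by site"` (flag value `"+"`). Rows flagged as reverse-decoy hits or as
#' identified only by modified peptides are removed. Rows are keyed by gene
#' name, falling back to the first majority protein ID when the gene name is
#' empty; the protein-group accession is retained as row metadata. A
#' `"Potential contaminant"` column, when present, is carried as a boolean
#' annotation; contaminant rows are removed only if `dropContaminants = TRUE`
#' (comparative scoring normally handles the shared background).
#'
#' @param path path to the tab-separated proteinGroups-style file.
#' @param design a [PanelDesign-class]; an `"LFQ intensity <sample_id>"`
#'   column must exist for every design sample.
#' @param dropContaminants logical; remove rows flagged `"+"` in
#'   `"Potential contaminant"`.
#' @return a raw-scale [IntensityMatrix-class] (0 = not detected), with
#'   `rowData` columns `majority_protein_ids` and `is_contaminant`.
#' @export
readProteinGroups <- function(path, design, dropContaminants = FALSE) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("Majority protein IDs", "Gene names")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("proteinGroups file lacks column(s): ",
             paste(sQuote(miss), collapse = ", "))
    lfqCols <- paste("LFQ intensity", sampleIds(design))
    missLfq <- setdiff(lfqCols, names(d))
    if (length(missLfq))
        stop("missing LFQ intensity column(s) for sample(s): ",
             paste(sub("^LFQ intensity ", "", missLfq), collapse = ", "))
    keep <- rep(TRUE, nrow(d))
    for (flag in c("Reverse", "Only identified by site")) {
        if (flag %in% names(d)) {
            keep <- keep & (is.na(d[[flag]]) | d[[flag]] != "+")
        } else {
            warning("flag column '", flag, "' absent; no rows removed on it")
        }
    }
    d <- d[keep, , drop = FALSE]
    contam <- if ("Potential contaminant" %in% names(d))
        !is.na(d[["Potential contaminant"]]) & d[["Potential contaminant"]] == "+"
    else rep(FALSE, nrow(d))
    if (dropContaminants) {
        d <- d[!contam, , drop = FALSE]
        contam <- contam[!contam]
    }
    firstTok <- function(x) vapply(strsplit(x, ";", fixed = TRUE),
                                   function(t) if (length(t)) t[1L] else "",
                                   character(1))
    genes <- firstTok(as.character(d[["Gene names"]]))
    acc <- as.character(d[["Majority protein IDs"]])
    key <- ifelse(is.na(genes) | genes == "", firstTok(acc), genes)
    mat <- as.matrix(d[, lfqCols, drop = FALSE])
    mat[is.na(mat)] <- 0
    colnames(mat) <- sub("^LFQ intensity ", "", colnames(mat))
    rownames(mat) <- key
    obj <- IntensityMatrix(mat, design, logScale = FALSE)
    rowData(obj)$majority_protein_ids <- acc
    rowData(obj)$is_contaminant <- contam
    obj
}

#' Collapse duplicate gene entries
#'
#' Database redundancy can leave two protein-group rows keyed to the same
#' gene (for example two UniProt entries for one gene). For each duplicated
#' gene key only the row with the largest total signal across all samples is
#' kept; ties keep the first row in file order. Each removal is reported via
#' `message()`.
#'
#' @param x a [CountMatrix-class] or [IntensityMatrix-class].
#' @param ... unused.
#' @return the same class with unique prey identifiers.
#' @name collapseDuplicateGenes
NULL

.collapseDup <- function(x, assayName) {
    m <- assay(x, assayName)
    keys <- rownames(x)
    if (!anyDuplicated(keys)) return(x)
    totals <- rowSums(m, na.rm = TRUE)
    keep <- logical(length(keys))
    for (k in unique(keys[duplicated(keys)])) {
        idx <- which(keys == k)
        best <- idx[which.max(totals[idx])]  # which.max takes first on ties
        if (sum(totals[idx] == totals[best]) > 1L)
            message("collapseDuplicateGenes: tie for '", k,
                    "' (total ", totals[best], "); keeping first occurrence")
        best <- idx[totals[idx] == totals[best]][1L]
        keep[best] <- TRUE
        dropped <- setdiff(idx, best)
        message("collapseDuplicateGenes: removed ", length(dropped),
                " duplicate row(s) for '", k, "' (kept total ",
                totals[best], ")")
    }
    keep[!(keys %in% keys[duplicated(keys)])] <- TRUE
    ## preserve original order
    x[sort(which(keep)), ]
}

#' @rdname collapseDuplicateGenes
#' @export
setMethod("collapseDuplicateGenes", "CountMatrix",
          function(x, ...) .collapseDup(x, "counts"))
#' @rdname collapseDuplicateGenes
#' @export
setMethod("collapseDuplicateGenes", "IntensityMatrix",
          function(x, ...) .collapseDup(x, "intensity"))

## ---- result-table writers ------------------------------------------------

.formatNum <- function(x, digits = 8L) {
    vapply(x, function(v) {
        if (is.na(v)) return("NA")
        sprintf("%.*g", digits, v)
    }, character(1))
}

.orderTable <- function(df) {
    keys <- list()
    if ("contrast_label" %in% names(df)) keys <- c(keys, list(df$contrast_label))
    if ("bait_id" %in% names(df)) keys <- c(keys, list(df$bait_id))
    if ("rank" %in% names(df)) keys <- c(keys, list(df$rank))
    else if ("WD" %in% names(df)) keys <- c(keys, list(-df$WD))
    else if ("bubble_size" %in% names(df)) keys <- c(keys, list(-df$bubble_size))
    else if ("p_value" %in% names(df)) keys <- c(keys, list(df$p_value))
    if ("prey_id" %in% names(df)) keys <- c(keys, list(df$prey_id))
    if (!length(keys)) return(df)
    df[do.call(order, keys), , drop = FALSE]
}

.writeTsv <- function(df, path, digits = 8L) {
    df <- .orderTable(as.data.frame(df))
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- .formatNum(out[[j]], digits)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA",
                       eol = "\n", fileEncoding = "UTF-8")
    invisible(path)
}

#' Write result tables
#'
#' Writes the pipeline's result tables as tab-separated files
#' `<prefix>.<name>.tsv` (names typically `compass`, `enrichment`, `bubble`,
#' `ranked`). Floating-point values are rendered with 8 significant digits and
#' rows are sorted deterministically (contrast/bait, then descending score or
#' rank, then prey), so re-running on identical input is byte-identical.
#'
#' @param tables a named list of data.frames.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeResultTables <- function(tables, prefix) {
    stopifnot(is.list(tables), length(names(tables)) == length(tables))
    paths <- character(0)
    for (nm in names(tables)) {
        p <- paste0(prefix, ".", nm, ".tsv")
        .writeTsv(tables[[nm]], p)
        paths <- c(paths, p)
    }
    invisible(paths)
}
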