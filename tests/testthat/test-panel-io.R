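test_that("panel design reader validates and preserves replicate order", {
    path <- withr::local_tempfile(fileext = ".tsv")
    d <- makePairedDesign(nPairs = 17, nRep = 3)@design
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    pd <- readPanelDesign(path)
    expect_equal(nBaits(pd), 34L)
    expect_length(sampleIds(pd), 102L)
    expect_identical(sampleIds(pd), d$sample_id)

    small <- rbind(
        data.frame(sample_id = paste0("b", 1:3), bait_id = "RAB5A_GTP",
                   gtpase_name = "RAB5A", nucleotide_state = "GTP"),
        data.frame(sample_id = paste0("c", 1:3), bait_id = "CTRL",
                   gtpase_name = "control", nucleotide_state = "NONE"))
    write.table(small, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_equal(nBaits(readPanelDesign(path)), 2L)

    dup <- small
    dup$sample_id[4] <- "b1"  # same sample under two baits
    write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readPanelDesign(path), "b1")

    badState <- small
    badState$nucleotide_state[1] <- "APO"
    write.table(badState, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readPanelDesign(path), "APO")
})

test_that("design invariants reject control/state mismatches", {
    d <- makeDesign(2, 3)@design
    d$gtpase_name[1:3] <- "control"  # control must be state NONE
    expect_error(PanelDesign(d), "NONE")
})

test_that("count matrix reader enforces integer counts and design mapping", {
    design <- makeDesign(2, 3)
    path <- withr::local_tempfile(fileext = ".tsv")
    m <- matrix(0:11, 2, 6, dimnames = list(c("P1", "P2"), sampleIds(design)))
    write.table(data.frame(prey_id = rownames(m), m, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    cm <- readCountMatrix(path, design)
    expect_s4_class(cm, "CountMatrix")
    expect_equal(dim(cm), c(2L, 6L))
    expect_equal(unname(SummarizedExperiment::assay(cm)["P2", ]), seq(1, 11, 2))

    ## missing cells read as zero
    txt <- c(paste(c("prey_id", sampleIds(design)), collapse = "\t"),
             paste(c("P1", "", "2", "3", "", "5", "6"), collapse = "\t"))
    writeLines(txt, path)
    cm2 <- readCountMatrix(path, design)
    expect_equal(unname(SummarizedExperiment::assay(cm2)[1, 1:2]), c(0, 2))

    bad <- data.frame(prey_id = "P1", t(c(3.7, 1, 1, 1, 1, 1)))
    names(bad) <- c("prey_id", sampleIds(design))
    write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCountMatrix(path, design), "3.7")

    extra <- data.frame(prey_id = "P1", t(rep(1, 6)), notes = "x")
    names(extra) <- c("prey_id", sampleIds(design), "notes")
    write.table(extra, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCountMatrix(path, design), "notes")
})

test_that("proteinGroups reader removes decoy and site-only rows", {
    design <- makeDesign(2, 3)
    lfq <- matrix(2^rnorm(36, 25, 1), 6, 6,
                  dimnames = list(paste0("G", 1:6), sampleIds(design)))
    path <- withr::local_tempfile(fileext = ".txt")
    writeProteinGroupsFile(lfq, path, reverse = 2, siteOnly = 5)
    im <- readProteinGroups(path, design)
    expect_s4_class(im, "IntensityMatrix")
    expect_equal(nrow(im), 4L)
    expect_false(any(c("G2", "G5") %in% rownames(im)))
    expect_false(im@logScale)

    ## no flags set: everything retained
    writeProteinGroupsFile(lfq, path)
    expect_equal(nrow(readProteinGroups(path, design)), 6L)

    ## empty gene name falls back to the first majority protein accession
    writeProteinGroupsFile(lfq, path,
                           genes = c("", paste0("G", 2:6)),
                           accessions = c("P12345;P67890",
                                          paste0("ACC", 2:6)))
    im3 <- readProteinGroups(path, design)
    expect_true("P12345" %in% rownames(im3))

    ## contaminants flagged but retained by default, dropped on request
    writeProteinGroupsFile(lfq, path, contaminant = 1)
    im4 <- readProteinGroups(path, design)
    expect_equal(nrow(im4), 6L)
    expect_true(SummarizedExperiment::rowData(im4)$is_contaminant[1])
    expect_equal(nrow(readProteinGroups(path, design,
                                        dropContaminants = TRUE)), 5L)

    ## missing LFQ column for a design sample is an error naming the sample
    expect_error(readProteinGroups(path, makeDesign(2, 4)), "r4")

    ## absent flag columns: warning, nothing removed on that flag
    df <- data.frame("Majority protein IDs" = paste0("A", 1:6),
                     "Gene names" = paste0("G", 1:6), check.names = FALSE)
    for (s in colnames(lfq)) df[[paste("LFQ intensity", s)]] <- lfq[, s]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    w <- capture_warnings(im5 <- readProteinGroups(path, design))
    expect_length(w, 2L)
    expect_match(w, "Reverse|site", all = TRUE)
    expect_equal(nrow(im5), 6L)
})

test_that("duplicate gene entries collapse to the highest-signal row", {
    design <- makeDesign(2, 3)
    m <- rbind(rep(20, 6), rep(5, 6), rep(1, 6))
    rownames(m) <- c("RABGAP1L", "RABGAP1L", "OTHER")
    colnames(m) <- sampleIds(design)
    cm <- CountMatrix(m, design)
    out <- suppressMessages(collapseDuplicateGenes(cm))
    expect_equal(nrow(out), 2L)
    expect_equal(sum(SummarizedExperiment::assay(out)["RABGAP1L", ]), 120)

    ## unique keys: identity
    expect_equal(nrow(collapseDuplicateGenes(out)), 2L)

    ## exact tie keeps the first row in file order
    m2 <- rbind(c(rep(2, 5), 0), c(0, rep(2, 5)))
    rownames(m2) <- c("TIE", "TIE")
    colnames(m2) <- sampleIds(design)
    m2[1, ] <- c(10, 0, 0, 0, 0, 0); m2[2, ] <- c(0, 10, 0, 0, 0, 0)
    cm2 <- CountMatrix(m2, design)
    expect_message(out2 <- collapseDuplicateGenes(cm2), "tie")
    expect_equal(unname(SummarizedExperiment::assay(out2)[1, 1]), 10)

    ## surviving total equals max of group totals (property, random input)
    withr::with_seed(42, {
        keys <- sample(paste0("g", 1:5), 12, replace = TRUE)
        m3 <- matrix(rpois(12 * 6, 4), 12, 6,
                     dimnames = list(keys, sampleIds(design)))
        out3 <- suppressMessages(collapseDuplicateGenes(CountMatrix(m3, design)))
        expect_false(anyDuplicated(rownames(out3)) > 0)
        for (k in unique(keys)) {
            expect_equal(sum(SummarizedExperiment::assay(out3)[k, ]),
                         max(rowSums(m3)[keys == k]))
        }
    })
})

test_that("result tables round-trip through TSV deterministically", {
    tab <- data.frame(bait_id = c("B", "A"), prey_id = c("x", "y"),
                      WD = c(pi, exp(1)), p_value = c(0.01, 0.5))
    dir <- withr::local_tempdir()
    prefix <- file.path(dir, "run")
    writeResultTables(list(compass = tab), prefix)
    f <- paste0(prefix, ".compass.tsv")
    expect_true(file.exists(f))
    back <- read.delim(f)
    expect_equal(back$WD[back$bait_id == "B"], pi, tolerance = 1e-6)
    ## deterministic bytes on re-write
    h1 <- tools::md5sum(f)
    writeResultTables(list(compass = tab[2:1, ]), prefix)
    expect_identical(unname(tools::md5sum(f)), unname(h1))
    ## empty table gives a header-only file
    writeResultTables(list(compass = tab[0, ]), prefix)
    expect_equal(length(readLines(f)), 1L)
})
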