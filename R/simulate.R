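#' @include AllGenerics.R
NULL

#' Simulation configuration for a synthetic bait panel
#'
#' Describes a synthetic GTPase bait panel with the statistical structure the
#' scoring pipeline assumes: `nPairs` GTPases each present as a GTP-locked
#' and a GDP-locked bait with `nRep` biological replicates; a background
#' proteome shared by every bait (log-normal abundance, with high-abundance
#' mitochondrial residents, endogenously biotinylated carboxylases and the
#' bait protein itself on top); planted interactor classes (GTP-state
#' effectors, GDP-state GEF-like preys, effectors shared among bait subsets,
#' nucleotide-independent binders); negative-binomial spectral counts;
#' log-normal intensities with logistic missing-not-at-random dropout.
#'
#' @param nPairs GTPase GTP/GDP bait pairs (default 3).
#' @param nRep biological replicates per bait (default 3).
#' @param nBackground background proteome size (default 1000).
#' @param bgLoc,bgScale location/scale of the log2 background abundance.
#' @param nMito mitochondrial-resident preys (higher abundance background).
#' @param mitoBoost log2 abundance boost of mitochondrial residents.
#' @param captureRate expected spectral counts per abundance unit.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param intensityOffset log2 offset mapping abundance to LFQ intensity.
#' @param intensityNoiseSd per-measurement log2 intensity noise SD.
#' @param detectMidpoint,detectSlope logistic detection model: detection
#'   probability `plogis((log2 intensity - midpoint)/slope)`.
#' @param nEffectors planted GTP-state effectors per GTP bait.
#' @param foldEffector their enrichment fold in the target bait (>= 1).
#' @param nGefs planted GDP-state GEF-like preys per GDP bait.
#' @param foldGef their enrichment fold (>= 1).
#' @param nShared effectors shared between pairs of GTP baits.
#' @param foldShared their fold (>= 1).
#' @param sharedBaits number of GTP baits sharing each shared effector.
#' @param nNucIndep nucleotide-independent binders (one GTPase, both states).
#' @param foldNucIndep their fold (>= 1).
#' @param bystanderCapture capture efficiency of a planted specific
#'   interactor in its *non*-target samples, as a fraction of normal capture
#'   (default 0.01). Specific interactors are soluble proteins that are only
#'   efficiently biotinylated while bound to their bait; with non-cognate
#'   baits they appear at most as trace bystanders. Applied only to preys
#'   with fold > 1, so a panel with all folds 1 is pure background.
#' @param baitSelfFold fold of the bait protein in its own samples.
#' @param biotinFold fold of endogenous biotin carriers in all samples.
#' @param biotinCarriers gene symbols of the biotin-carrier class.
#' @param seed integer seed.
#' @return a validated `SimConfig` list (class `"SimConfig"`).
#' @export
simConfig <- function(nPairs = 3L, nRep = 3L, nBackground = 1000L,
                      bgLoc = 7, bgScale = 1.5,
                      nMito = 50L, mitoBoost = 2,
                      captureRate = 0.05, dispersion = 4,
                      intensityOffset = 18, intensityNoiseSd = 0.4,
                      detectMidpoint = 22, detectSlope = 1,
                      nEffectors = 10L, foldEffector = 8,
                      nGefs = 5L, foldGef = 8,
                      nShared = 5L, foldShared = 8, sharedBaits = 2L,
                      nNucIndep = 5L, foldNucIndep = 8,
                      bystanderCapture = 0.01,
                      baitSelfFold = 100, biotinFold = 50,
                      biotinCarriers = endogenousBiotinCarriers(),
                      seed = 1L) {
    cfg <- list(nPairs = as.integer(nPairs), nRep = as.integer(nRep),
                nBackground = as.integer(nBackground),
                bgLoc = bgLoc, bgScale = bgScale,
                nMito = as.integer(nMito), mitoBoost = mitoBoost,
                captureRate = captureRate, dispersion = dispersion,
                intensityOffset = intensityOffset,
                intensityNoiseSd = intensityNoiseSd,
                detectMidpoint = detectMidpoint, detectSlope = detectSlope,
                nEffectors = as.integer(nEffectors),
                foldEffector = foldEffector,
                nGefs = as.integer(nGefs), foldGef = foldGef,
                nShared = as.integer(nShared), foldShared = foldShared,
                sharedBaits = as.integer(sharedBaits),
                nNucIndep = as.integer(nNucIndep),
                foldNucIndep = foldNucIndep,
                bystanderCapture = bystanderCapture,
                baitSelfFold = baitSelfFold, biotinFold = biotinFold,
                biotinCarriers = biotinCarriers, seed = as.integer(seed))
    bad <- character()
    if (cfg$nPairs < 1L) bad <- c(bad, "nPairs")
    if (cfg$nRep < 1L) bad <- c(bad, "nRep")
    if (cfg$nBackground < 0L) bad <- c(bad, "nBackground")
    if (cfg$dispersion <= 0) bad <- c(bad, "dispersion")
    if (cfg$captureRate <= 0) bad <- c(bad, "captureRate")
    for (fld in c("foldEffector", "foldGef", "foldShared", "foldNucIndep",
                  "baitSelfFold", "biotinFold"))
        if (cfg[[fld]] < 1) bad <- c(bad, fld)
    if (cfg$intensityNoiseSd < 0) bad <- c(bad, "intensityNoiseSd")
    if (cfg$bystanderCapture < 0 || cfg$bystanderCapture > 1)
        bad <- c(bad, "bystanderCapture")
    if (cfg$detectSlope <= 0) bad <- c(bad, "detectSlope")
    if (cfg$sharedBaits < 1L || cfg$sharedBaits > cfg$nPairs)
        bad <- c(bad, "sharedBaits")
    if (length(bad))
        stop("invalid SimConfig field(s): ", paste(bad, collapse = ", "))
    structure(cfg, class = "SimConfig")
}

#' Generate a synthetic bait panel
#'
#' Draws a full synthetic panel from a [simConfig()]: the design, a
#' spectral-count matrix, a raw-scale intensity matrix with
#' missing-not-at-random dropout, and a ground-truth table of planted
#' interaction classes.
#'
#' The generative model per prey *i* and sample *s* of bait *b* is: base
#' abundance `log2 A_i ~ Normal(bgLoc, bgScale)` (shared by all baits; the
#' "similar set of background interactions" of a common-location panel);
#' enrichment fold `F_ib >= 1` applied only in the target baits of planted
#' preys; counts `~ NegBin(mean = captureRate * A_i * F_ib, size =
#' dispersion)`; intensities `log2 I_is = intensityOffset + log2(A_i F_ib) +
#' Normal(0, intensityNoiseSd)`, observed with probability
#' `plogis((log2 I_is - detectMidpoint)/detectSlope)` and reported as 0
#' otherwise — dropout is concentrated at low abundance.
#'
#' @param cfg a [simConfig()] object.
#' @return a list with elements `design` ([PanelDesign-class]), `counts`
#'   ([CountMatrix-class]), `intensity` (raw [IntensityMatrix-class]) and
#'   `truth` (data.frame `prey_id`, `class`, `target_baits`
#'   (semicolon-separated), `fold`). Bit-reproducible from `cfg$seed`.
#' @export
generatePanel <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    withr::with_seed(cfg$seed, .generatePanelImpl(cfg))
}

.generatePanelImpl <- function(cfg) {
    gtpases <- sprintf("GTPASE%02d", seq_len(cfg$nPairs))
    states <- c("GTP", "GDP")
    design <- do.call(rbind, lapply(gtpases, function(g) {
        do.call(rbind, lapply(states, function(st) {
            data.frame(
                sample_id = sprintf("%s_%s_r%d", g, st, seq_len(cfg$nRep)),
                bait_id = paste0(g, "_", st),
                gtpase_name = g, nucleotide_state = st,
                stringsAsFactors = FALSE)
        }))
    }))
    pd <- PanelDesign(design)
    baits <- unique(design$bait_id)
    gtpBaits <- baits[endsWith(baits, "_GTP")]
    gdpBaits <- baits[endsWith(baits, "_GDP")]

    ## --- prey roster and truth table ------------------------------------
    preys <- character(0); cls <- character(0)
    targets <- list(); folds <- numeric(0)
    addPrey <- function(id, class, target, fold) {
        preys <<- c(preys, id); cls <<- c(cls, class)
        targets[[length(targets) + 1L]] <<- target
        folds <<- c(folds, fold)
    }
    nBg <- cfg$nBackground
    nMito <- min(cfg$nMito, nBg)
    for (i in seq_len(nBg)) {
        mito <- i <= nMito
        addPrey(sprintf(if (mito) "MITO%04d" else "BG%04d", i),
                if (mito) "mito_resident" else "background",
                character(0), 1)
    }
    for (g in cfg$biotinCarriers)
        addPrey(g, "endog_biotin", baits, cfg$biotinFold)
    for (g in gtpases)
        addPrey(g, "bait_self", c(paste0(g, "_GTP"), paste0(g, "_GDP")),
                cfg$baitSelfFold)
    for (b in gtpBaits)
        for (k in seq_len(cfg$nEffectors))
            addPrey(sprintf("EFF_%s_%02d", sub("_GTP$", "", b), k),
                    "effector", b, cfg$foldEffector)
    for (b in gdpBaits)
        for (k in seq_len(cfg$nGefs))
            addPrey(sprintf("GEF_%s_%02d", sub("_GDP$", "", b), k),
                    "gef", b, cfg$foldGef)
    if (length(gtpBaits) >= cfg$sharedBaits && cfg$nShared > 0L) {
        for (k in seq_len(cfg$nShared)) {
            tb <- sort(sample(gtpBaits, cfg$sharedBaits))
            addPrey(sprintf("SHEFF%02d", k), "shared_effector", tb,
                    cfg$foldShared)
        }
    }
    for (k in seq_len(cfg$nNucIndep)) {
        g <- sample(gtpases, 1L)
        addPrey(sprintf("NIB%02d", k), "nucleotide_independent",
                c(paste0(g, "_GTP"), paste0(g, "_GDP")), cfg$foldNucIndep)
    }
    truth <- data.frame(
        prey_id = preys, class = cls,
        target_baits = vapply(targets, paste, character(1), collapse = ";"),
        fold = folds, stringsAsFactors = FALSE)

    nPrey <- length(preys)
    ## base abundance (log2), shared across baits
    a <- stats::rnorm(nPrey, cfg$bgLoc, cfg$bgScale)
    a[cls == "mito_resident"] <- a[cls == "mito_resident"] + cfg$mitoBoost

    ## enrichment matrix preys x baits: planted fold in target baits; for
    ## specific interactor classes, bystander-level capture elsewhere
    specific <- c("effector", "gef", "shared_effector",
                  "nucleotide_independent")
    F <- matrix(1, nPrey, length(baits), dimnames = list(preys, baits))
    for (i in seq_len(nPrey)) {
        if (!length(targets[[i]]) || folds[i] <= 1) next
        if (cls[i] %in% specific)
            F[i, ] <- cfg$bystanderCapture
        F[i, targets[[i]]] <- folds[i]
    }

    sampleBait <- design$bait_id
    nS <- nrow(design)
    muCounts <- cfg$captureRate * 2^a * F[, sampleBait, drop = FALSE]
    counts <- matrix(stats::rnbinom(nPrey * nS, size = cfg$dispersion,
                                    mu = muCounts),
                     nPrey, nS, dimnames = list(preys, design$sample_id))

    log2I <- cfg$intensityOffset + a + log2(F[, sampleBait, drop = FALSE]) +
        matrix(stats::rnorm(nPrey * nS, 0, cfg$intensityNoiseSd), nPrey, nS)
    pDet <- stats::plogis((log2I - cfg$detectMidpoint) / cfg$detectSlope)
    detected <- matrix(stats::runif(nPrey * nS) < pDet, nPrey, nS)
    intens <- ifelse(detected, 2^log2I, 0)
    dimnames(intens) <- list(preys, design$sample_id)

    list(design = pd,
         counts = CountMatrix(counts, pd),
         intensity = IntensityMatrix(intens, pd, logScale = FALSE),
         truth = truth)
}

#' Write a synthetic panel to disk
#'
#' Serializes a generated panel as plain tab-separated files: `design.tsv`,
#' `counts.tsv` (prey x sample counts), `intensities.tsv` in the
#' proteinGroups dialect ("Majority protein IDs", "Gene names", "Reverse",
#' "Only identified by site", "Potential contaminant", per-sample
#' "LFQ intensity <sample>") and `truth.tsv`.
#'
#' @param panel a list from [generatePanel()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
writePanelFiles <- function(panel, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pDesign <- file.path(dir, "design.tsv")
    utils::write.table(panel$design@design, pDesign, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cm <- assay(panel$counts, "counts")
    pCounts <- file.path(dir, "counts.tsv")
    utils::write.table(
        data.frame(prey_id = rownames(cm), cm, check.names = FALSE),
        pCounts, sep = "\t", quote = FALSE, row.names = FALSE)
    im <- assay(panel$intensity, "intensity")
    pg <- data.frame(
        "Majority protein IDs" = paste0("SYN|", rownames(im)),
        "Gene names" = rownames(im),
        Reverse = "", check.names = FALSE, stringsAsFactors = FALSE)
    pg[["Only identified by site"]] <- ""
    pg[["Potential contaminant"]] <- ""
    for (s in colnames(im))
        pg[[paste("LFQ intensity", s)]] <- .formatNum(im[, s])
    pIntens <- file.path(dir, "intensities.tsv")
    utils::write.table(pg, pIntens, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pTruth <- file.path(dir, "truth.tsv")
    utils::write.table(panel$truth, pTruth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(design = pDesign, counts = pCounts, intensities = pIntens,
                truth = pTruth))
}

#' Evaluate recovery of planted interactors
#'
#' Benchmarks a ranked hit table against the simulator's ground truth: per
#' contrast, `recall@k` (fraction of that bait's planted target preys in the
#' top `k` ranks) and a rank-separation AUC (probability that a planted prey
#' outranks a non-planted one, from the rank-sum statistic). Contrasts whose
#' bait has no planted preys report `NA`.
#'
#' @param ranked a ranked table from [rankHits()].
#' @param truth the truth table of the same panel.
#' @param k top-rank cutoff (default 15).
#' @return a `data.frame` with `contrast_label`, `bait_id`, `n_planted`,
#'   `recall_at_k`, `rank_auc`.
#' @export
evaluateRecovery <- function(ranked, truth, k = 15L) {
    if (k < 1L) stop("k must be >= 1")
    planted <- truth[truth$fold > 1 &
                     !truth$class %in% c("endog_biotin", "bait_self"), ,
                     drop = FALSE]
    tgt <- strsplit(planted$target_baits, ";", fixed = TRUE)
    grp <- unique(ranked[, c("contrast_label", "bait_id")])
    res <- lapply(seq_len(nrow(grp)), function(i) {
        b <- grp$bait_id[i]
        sub <- ranked[ranked$contrast_label == grp$contrast_label[i], ,
                      drop = FALSE]
        tp <- planted$prey_id[vapply(tgt, function(t) b %in% t, logical(1))]
        tp <- intersect(tp, sub$prey_id)
        if (!length(tp))
            return(data.frame(contrast_label = grp$contrast_label[i],
                              bait_id = b, n_planted = 0L,
                              recall_at_k = NA_real_, rank_auc = NA_real_))
        isTp <- sub$prey_id %in% tp
        topk <- sub$prey_id[sub$rank <= k]
        recall <- mean(tp %in% topk)
        r <- rank(sub$rank)  # 1 = best
        ## AUC: P(planted ranked better than non-planted)
        n1 <- sum(isTp); n0 <- sum(!isTp)
        auc <- if (n0 == 0) NA_real_ else
            (sum(rank(-sub$rank)[isTp]) - n1 * (n1 + 1) / 2) / (n1 * n0)
        data.frame(contrast_label = grp$contrast_label[i], bait_id = b,
                   n_planted = length(tp), recall_at_k = recall,
                   rank_auc = auc)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
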