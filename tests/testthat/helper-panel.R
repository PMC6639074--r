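## Builders and independent reference implementations used across the suite.

makeDesign <- function(nBaits = 3, nRep = 3, states = NULL,
                       baitNames = NULL) {
    if (is.null(baitNames))
        baitNames <- paste0("BAIT", seq_len(nBaits))
    if (is.null(states)) states <- rep("GTP", nBaits)
    d <- do.call(rbind, lapply(seq_len(nBaits), function(i) {
        data.frame(sample_id = sprintf("%s_r%d", baitNames[i], seq_len(nRep)),
                   bait_id = baitNames[i],
                   gtpase_name = if (states[i] == "NONE") "control"
                                 else baitNames[i],
                   nucleotide_state = states[i],
                   stringsAsFactors = FALSE)
    }))
    PanelDesign(d)
}

## paired GTP/GDP design, as in a nucleotide-locked GTPase panel
makePairedDesign <- function(nPairs = 3, nRep = 3) {
    d <- do.call(rbind, lapply(seq_len(nPairs), function(i) {
        g <- sprintf("G%02d", i)
        do.call(rbind, lapply(c("GTP", "GDP"), function(st)
            data.frame(sample_id = sprintf("%s_%s_r%d", g, st, seq_len(nRep)),
                       bait_id = paste0(g, "_", st),
                       gtpase_name = g, nucleotide_state = st,
                       stringsAsFactors = FALSE)))
    }))
    PanelDesign(d)
}

randomCountMatrix <- function(design, nPrey = 20, maxCount = 30,
                              zeroProp = 0.5) {
    ids <- sampleIds(design)
    m <- matrix(rbinom(nPrey * length(ids), 1, 1 - zeroProp) *
                sample.int(maxCount, nPrey * length(ids), replace = TRUE),
                nPrey, length(ids),
                dimnames = list(sprintf("P%03d", seq_len(nPrey)), ids))
    CountMatrix(m, design)
}

## naive triple-loop reference for the Z/D/WD scores
naiveCompass <- function(counts) {
    m <- SummarizedExperiment::assay(counts, "counts")
    bait <- as.character(SummarizedExperiment::colData(counts)$bait_id)
    baits <- unique(bait)
    cols <- lapply(baits, function(b) which(bait == b))
    K <- length(baits)
    oB <- oP <- character(0)
    oX <- oRep <- oF <- oOm <- oZ <- oD <- oWD <- numeric(0)
    for (prey in rownames(m)) {
        xbar <- p <- numeric(K)
        for (i in seq_len(K)) {
            v <- m[prey, cols[[i]]]
            xbar[i] <- mean(v)
            p[i] <- sum(v > 0)
        }
        if (all(p == 0)) next
        f <- sum(p > 0)
        mu <- mean(xbar)
        sigma <- sd(xbar)
        omega <- if (mu > 0) max(1, sigma / mu) else 1
        for (i in seq_len(K)) {
            z <- if (sigma == 0) 0 else (xbar[i] - mu) / sigma
            oB <- c(oB, baits[i]); oP <- c(oP, prey)
            oX <- c(oX, xbar[i]); oRep <- c(oRep, p[i])
            oF <- c(oF, f); oOm <- c(oOm, omega); oZ <- c(oZ, z)
            oD <- c(oD, sqrt(xbar[i] * (K / f)^p[i]))
            oWD <- c(oWD, sqrt(xbar[i] * ((K / f) * omega)^p[i]))
        }
    }
    if (!length(oB)) return(NULL)
    data.frame(bait_id = oB, prey_id = oP, X_bar = oX, p = oRep, f = oF,
               omega = oOm, Z = oZ, D = oD, WD = oWD,
               stringsAsFactors = FALSE)
}

## brute-force permutation FDR over ALL relabelings (identity included),
## reproducing the definition: num = mean_b #{null |t| >= |t_i|},
## den = #{obs |t| >= |t_i|}, clipped, then step-up monotone smoothing.
bruteFdr <- function(mat, n1, s0 = 0) {
    n <- ncol(mat)
    tOf <- function(idxA) {
        idxB <- setdiff(seq_len(n), idxA)
        apply(mat, 1L, function(v) {
            a <- v[idxA]; b <- v[idxB]
            lfc <- mean(a) - mean(b)
            df <- n - 2
            sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
            se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
            if (se == 0) { if (lfc == 0) 0 else Inf } else lfc / se
        })
    }
    tObs <- abs(tOf(seq_len(n1)))
    combos <- combn(n, n1)
    nullT <- abs(unlist(lapply(seq_len(ncol(combos)),
                               function(j) tOf(combos[, j]))))
    B <- ncol(combos)
    fdr <- vapply(tObs, function(ti)
        min(1, (sum(nullT >= ti) / B) / sum(tObs >= ti)), numeric(1))
    ord <- order(tObs, decreasing = TRUE)
    sm <- fdr[ord]
    sm <- rev(cummin(rev(sm)))
    fdr[ord] <- sm
    fdr
}

## write a minimal proteinGroups-dialect file; `lfq` is preys x samples
writeProteinGroupsFile <- function(lfq, path, reverse = NULL,
                                   siteOnly = NULL, contaminant = NULL,
                                   genes = rownames(lfq),
                                   accessions = paste0("ACC_", rownames(lfq))) {
    n <- nrow(lfq)
    flag <- function(x) {
        v <- rep("", n)
        if (!is.null(x)) v[x] <- "+"
        v
    }
    df <- data.frame("Majority protein IDs" = accessions,
                     "Gene names" = genes,
                     Reverse = flag(reverse),
                     check.names = FALSE, stringsAsFactors = FALSE)
    df[["Only identified by site"]] <- flag(siteOnly)
    df[["Potential contaminant"]] <- flag(contaminant)
    for (s in colnames(lfq)) df[[paste("LFQ intensity", s)]] <- lfq[, s]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}
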