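#' @include AllGenerics.R
NULL

#' Log2-transform an intensity matrix
#'
#' Replaces every positive raw intensity with its log2; zeros (not detected)
#' become the missing marker `NA`. Applying the transform twice is an error.
#'
#' @param x a raw-scale [IntensityMatrix-class].
#' @param ... unused.
#' @return a log-scale [IntensityMatrix-class].
#' @name logTransform
NULL

#' @rdname logTransform
#' @export
setMethod("logTransform", "IntensityMatrix", function(x, ...) {
    if (isTRUE(x@logScale))
        stop("intensity matrix is already on log scale")
    m <- assay(x, "intensity")
    out <- ifelse(m > 0, log2(m), NA_real_)
    SummarizedExperiment::assay(x, "intensity") <- out
    x@logScale <- TRUE
    validObject(x)
    x
})

#' Minimum-valid-value filter
#'
#' Retains preys quantified (non-missing) in at least `minValid` replicates
#' of at least one bait; all other preys are removed. This is the standard
#' pre-imputation filter of label-free volcano pipelines: a protein never
#' seen twice within any bait group carries no testable signal.
#'
#' @param x a log-scale [IntensityMatrix-class].
#' @param minValid minimum number of valid values within one bait's
#'   replicate group (default 2).
#' @param ... unused.
#' @return the filtered [IntensityMatrix-class]. Idempotent.
#' @name filterMinValid
NULL

#' @rdname filterMinValid
#' @export
setMethod("filterMinValid", "IntensityMatrix",
          function(x, minValid = 2L, ...) {
    if (!isTRUE(x@logScale))
        stop("filterMinValid expects a log-scale intensity matrix")
    m <- assay(x, "intensity")
    bait <- as.character(colData(x)$bait_id)
    baits <- unique(bait)
    nRep <- vapply(baits, function(b) sum(bait == b), integer(1))
    if (minValid > max(nRep))
        stop("minValid (", minValid, ") exceeds every bait's replicate count")
    validPerBait <- vapply(baits, function(b)
        rowSums(!is.na(m[, bait == b, drop = FALSE])), numeric(nrow(m)))
    dim(validPerBait) <- c(nrow(m), length(baits))
    keep <- rowSums(validPerBait >= minValid) > 0
    x[keep, ]
})

#' Downshifted-Gaussian imputation of missing intensities
#'
#' Missing label-free intensities are missing-not-at-random: proteins drop
#' out near the detection limit. Each missing entry in sample column *s* is
#' therefore drawn from `Normal(m_s - downshift * sd_s, (width * sd_s)^2)`,
#' where `m_s` and `sd_s` are the mean and standard deviation of the observed
#' log2 intensities of that column — i.e. noise simulated around the
#' column's detection limit. Defaults (`width = 0.3`, `downshift = 1.8`) are
#' the conventional per-column settings of label-free volcano pipelines.
#' Observed entries are untouched; draws are reproducible given `seed`.
#'
#' @param x a filtered log-scale [IntensityMatrix-class].
#' @param width imputation width as a fraction of the per-column SD (> 0).
#' @param downshift downshift in multiples of the per-column SD (>= 0).
#' @param seed integer seed for the random draws (optional).
#' @param ... unused.
#' @return a complete log-scale [IntensityMatrix-class] (no `NA` left).
#' @name imputeDownshift
NULL

#' @rdname imputeDownshift
#' @export
setMethod("imputeDownshift", "IntensityMatrix",
          function(x, width = 0.3, downshift = 1.8, seed = NULL, ...) {
    if (!isTRUE(x@logScale))
        stop("imputeDownshift expects a log-scale intensity matrix")
    stopifnot(width > 0, downshift >= 0)
    m <- assay(x, "intensity")
    doImpute <- function() {
        for (j in seq_len(ncol(m))) {
            miss <- is.na(m[, j])
            if (!any(miss)) next
            obs <- m[!miss, j]
            if (length(obs) < 2L)
                stop("column '", colnames(m)[j],
                     "' has fewer than 2 observed values; SD undefined")
            mu <- mean(obs)
            sdv <- stats::sd(obs)
            m[miss, j] <<- stats::rnorm(sum(miss),
                                        mean = mu - downshift * sdv,
                                        sd = width * sdv)
        }
    }
    if (is.null(seed)) doImpute() else withr::with_seed(seed, doImpute())
    SummarizedExperiment::assay(x, "intensity") <- m
    x
})

#' Build the panel's enrichment contrasts
#'
#' Effectors bind the GTP-loaded form, so each GTP-locked bait is compared
#' against the pooled replicates of *all* GDP-locked baits (including the
#' same GTPase's GDP form). Exchange factors act on few GTPases, so each
#' GDP-locked bait is compared against all *other* GDP-locked baits.
#' Ligase-only controls (state `NONE`) get no contrast by default.
#'
#' @param design a [PanelDesign-class] with at least 2 GDP-state baits.
#' @return a list of [ContrastSpec-class] objects.
#' @export
buildContrasts <- function(design) {
    info <- .baitInfo(design)
    gdp <- info$bait_id[info$nucleotide_state == "GDP"]
    if (length(gdp) < 2L)
        stop("need at least 2 GDP-state baits to form a pooled background")
    gdpSamples <- lapply(gdp, function(b) replicateSamples(design, b))
    names(gdpSamples) <- gdp
    allGdp <- unlist(gdpSamples, use.names = FALSE)
    out <- list()
    for (i in seq_len(nrow(info))) {
        b <- info$bait_id[i]
        st <- info$nucleotide_state[i]
        if (st == "NONE") next
        test <- replicateSamples(design, b)
        bg <- if (st == "GTP") allGdp
              else unlist(gdpSamples[setdiff(gdp, b)], use.names = FALSE)
        out[[length(out) + 1L]] <- new(
            "ContrastSpec", testBait = b, testSamples = test,
            backgroundSamples = bg,
            label = paste0(b, "_vs_", if (st == "GTP") "pooledGDP" else "otherGDP"))
    }
    out
}

#' Two-sample Student's t test with optional s0 stabilization
#'
#' Equal-variance two-sample t test on log2 intensities, as used for
#' volcano-plot enrichment: `log2fc = mean(a) - mean(b)`,
#' `t = log2fc / (SE + s0)` with the pooled standard error on
#' `|a| + |b| - 2` degrees of freedom, two-sided p from the t distribution.
#' Degenerate guard: if the pooled SE is 0 the test reports `t = 0, p = 1`
#' when the means agree and the smallest positive double as p when they do
#' not.
#'
#' @param a numeric values of the test group (length >= 2).
#' @param b numeric values of the background group (length >= 2).
#' @param s0 non-negative fudge factor added to the standard error.
#' @return a list with `t_stat`, `p_value`, `log2fc`, `df`.
#' @export
twoSampleTest <- function(a, b, s0 = 0) {
    if (length(a) < 2L || length(b) < 2L)
        stop("both groups need at least 2 values")
    stopifnot(s0 >= 0)
    n1 <- length(a); n2 <- length(b)
    lfc <- mean(a) - mean(b)
    df <- n1 + n2 - 2
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    if (se + s0 == 0) {
        if (lfc == 0) return(list(t_stat = 0, p_value = 1, log2fc = 0, df = df))
        return(list(t_stat = sign(lfc) * Inf,
                    p_value = .Machine$double.xmin, log2fc = lfc, df = df))
    }
    t <- lfc / (se + s0)
    p <- 2 * stats::pt(-abs(t), df = df)
    p <- max(p, .Machine$double.xmin)
    list(t_stat = t, p_value = p, log2fc = lfc, df = df)
}

## vectorized row-wise version used by the contrast loop and permutations
.rowTests <- function(m, idxA, idxB, s0 = 0) {
    n1 <- length(idxA); n2 <- length(idxB)
    a <- m[, idxA, drop = FALSE]; b <- m[, idxB, drop = FALSE]
    ma <- rowMeans(a); mb <- rowMeans(b)
    lfc <- ma - mb
    df <- n1 + n2 - 2
    ssa <- rowSums((a - ma)^2)
    ssb <- rowSums((b - mb)^2)
    se <- sqrt((ssa + ssb) / df * (1 / n1 + 1 / n2))
    den <- se + s0
    t <- ifelse(den == 0, ifelse(lfc == 0, 0, sign(lfc) * Inf), lfc / den)
    p <- ifelse(is.infinite(t), .Machine$double.xmin,
                pmax(2 * stats::pt(-abs(t), df = df), .Machine$double.xmin))
    p[t == 0 & den == 0] <- 1
    list(t_stat = t, p_value = p, log2fc = lfc, df = df)
}

#' Permutation false discovery rate for one contrast
#'
#' Estimates, for every prey, the FDR of calling it at its observed |t|:
#' sample-group labels of the contrast are relabeled (test-group size
#' preserved), all |t| statistics recomputed per relabeling, and
#' `FDR(prey) = mean_b #\{null |t| >= |t_obs(prey)|\} / #\{observed |t| >=
#' |t_obs(prey)|\}`, clipped to \[0, 1\] and made monotone non-increasing in
#' |t_obs| by step-up smoothing (each prey takes the minimum raw value over
#' itself and all less significant preys, as in Benjamini-Hochberg).
#'
#' When the number of distinct relabelings is at most `nPerm` and
#' `method = "auto"`, all distinct relabelings (including the identity) are
#' enumerated once, making the result an exact brute-force computation.
#' Otherwise `nPerm` random relabelings are drawn, excluding the identity;
#' `method = "sample"` forces this path and warns when fewer distinct
#' relabelings than `nPerm` exist (sampling is then with replacement).
#'
#' @param m complete log-scale intensity matrix (preys x samples) or a
#'   complete [IntensityMatrix-class].
#' @param contrast a [ContrastSpec-class].
#' @param nPerm number of relabelings (default 250).
#' @param s0 fudge factor passed to the t statistic.
#' @param seed integer seed (optional).
#' @param method `"auto"`, `"exhaustive"` or `"sample"`.
#' @return named numeric vector of FDR values, one per prey.
#' @export
permutationFDR <- function(m, contrast, nPerm = 250L, s0 = 0, seed = NULL,
                           method = c("auto", "exhaustive", "sample")) {
    method <- match.arg(method)
    stopifnot(nPerm >= 1L)
    if (is(m, "IntensityMatrix")) m <- assay(m, "intensity")
    if (anyNA(m)) stop("matrix must be complete (impute first)")
    cols <- c(contrast@testSamples, contrast@backgroundSamples)
    if (!all(cols %in% colnames(m)))
        stop("contrast samples missing from matrix")
    sub <- m[, cols, drop = FALSE]
    n <- ncol(sub)
    n1 <- length(contrast@testSamples)
    obs <- .rowTests(sub, seq_len(n1), (n1 + 1L):n, s0)
    tObs <- abs(obs$t_stat)

    nDistinct <- choose(n, n1)
    exhaustive <- method == "exhaustive" ||
        (method == "auto" && nDistinct <= nPerm)
    perms <- if (exhaustive) {
        asplit(utils::combn(n, n1), 2L)
    } else {
        if (method == "sample" && nDistinct < nPerm)
            warning("fewer distinct relabelings (", nDistinct,
                    ") than nPerm; sampling with replacement")
        identity <- seq_len(n1)
        gen <- function() {
            lapply(seq_len(nPerm), function(i) {
                repeat {
                    s <- sort(sample.int(n, n1))
                    if (!identical(s, identity)) return(s)
                }
            })
        }
        if (is.null(seed)) gen() else withr::with_seed(seed, gen())
    }
    B <- length(perms)
    nullT <- numeric(0)
    for (pm in perms) {
        idxA <- as.integer(pm)
        idxB <- setdiff(seq_len(n), idxA)
        nullT <- c(nullT, abs(.rowTests(sub, idxA, idxB, s0)$t_stat))
    }
    nullSorted <- sort(nullT)
    ## count of null |t| >= threshold, averaged over permutations
    num <- (length(nullSorted) -
            findInterval(tObs, nullSorted, left.open = TRUE)) / B
    obsSorted <- sort(tObs)
    den <- length(obsSorted) - findInterval(tObs, obsSorted, left.open = TRUE)
    fdr <- pmin(1, pmax(0, num / den))
    ## step-up smoothing: monotone non-increasing in |t_obs|
    ord <- order(tObs, decreasing = TRUE)
    sm <- fdr[ord]
    sm <- rev(cummin(rev(sm)))
    fdr[ord] <- sm
    names(fdr) <- rownames(sub)
    fdr
}

#' Run the intensity enrichment branch
#'
#' End-to-end composition of the intensity analysis: log2 transform,
#' minimum-valid filter, downshifted-Gaussian imputation, contrast
#' construction and per-prey two-sample t tests with FDR (permutation by
#' default, Benjamini-Hochberg on the analytic p as an alternative).
#'
#' @param x a raw-scale [IntensityMatrix-class].
#' @param minValid minimum valid values within one bait (default 2).
#' @param width,downshift imputation parameters, see [imputeDownshift()].
#' @param nPerm permutations per contrast (default 250).
#' @param s0 t-statistic fudge factor (default 0).
#' @param fdrMethod `"permutation"` or `"BH"`.
#' @param seed integer seed; per-stage seeds (imputation, each contrast's
#'   permutations) are derived deterministically from it.
#' @param contrasts optional list of [ContrastSpec-class]; defaults to
#'   [buildContrasts()] on the embedded design.
#' @return a `data.frame` with columns `contrast_label`, `bait_id`,
#'   `prey_id`, `log2fc`, `t_stat`, `p_value`, `neg_log10_p`, `fdr`,
#'   `n_test`, `n_background`.
#' @export
runEnrichment <- function(x, minValid = 2L, width = 0.3, downshift = 1.8,
                          nPerm = 250L, s0 = 0,
                          fdrMethod = c("permutation", "BH"),
                          seed = NULL, contrasts = NULL) {
    fdrMethod <- match.arg(fdrMethod)
    design <- panelDesign(x)
    if (is.null(contrasts)) contrasts <- buildContrasts(design)
    lg <- logTransform(x)
    flt <- filterMinValid(lg, minValid = minValid)
    empty <- data.frame(contrast_label = character(), bait_id = character(),
                        prey_id = character(), log2fc = numeric(),
                        t_stat = numeric(), p_value = numeric(),
                        neg_log10_p = numeric(), fdr = numeric(),
                        n_test = integer(), n_background = integer(),
                        stringsAsFactors = FALSE)
    if (nrow(flt) == 0L) return(empty)
    seeds <- .deriveSeeds(seed, length(contrasts) + 1L)
    imp <- imputeDownshift(flt, width = width, downshift = downshift,
                           seed = seeds[[1L]])
    m <- assay(imp, "intensity")
    out <- vector("list", length(contrasts))
    for (i in seq_along(contrasts)) {
        ct <- contrasts[[i]]
        idxA <- match(ct@testSamples, colnames(m))
        idxB <- match(ct@backgroundSamples, colnames(m))
        tt <- .rowTests(m, idxA, idxB, s0)
        fdr <- if (fdrMethod == "BH") {
            stats::p.adjust(tt$p_value, method = "BH")
        } else {
            permutationFDR(m, ct, nPerm = nPerm, s0 = s0,
                           seed = seeds[[i + 1L]])
        }
        out[[i]] <- data.frame(
            contrast_label = ct@label,
            bait_id = ct@testBait,
            prey_id = rownames(m),
            log2fc = tt$log2fc,
            t_stat = tt$t_stat,
            p_value = tt$p_value,
            neg_log10_p = -log10(tt$p_value),
            fdr = as.numeric(fdr),
            n_test = length(idxA),
            n_background = length(idxB),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

## derive k reproducible 32-bit sub-seeds from one seed (NULL stays NULL)
.deriveSeeds <- function(seed, k) {
    if (is.null(seed)) return(vector("list", k))
    as.list((as.numeric(seed) * 48271 + 7919 * seq_len(k)) %% 2147483647)
}
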