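#' @include AllGenerics.R
NULL

#' CompPASS-family component scores
#'
#' Vectorized closed forms of the panel-comparative spectral-count scores.
#' With `X_bar` the mean spectral count of a prey over one bait's replicates,
#' `p` the number of that bait's replicates in which the prey was detected,
#' `K` the number of baits in the panel, `f` the number of baits that
#' detected the prey, `mu`/`sigma` the mean and (n-1) standard deviation of
#' the prey's bait-level means over all `K` baits, and
#' `omega = max(1, sigma/mu)` the cross-bait variability weight:
#'
#' * `zScore`: `(X_bar - mu) / sigma`, 0 where `sigma = 0` (a prey found at
#'   identical levels everywhere is uninformative, not infinitely significant);
#' * `dScore`: `sqrt(X_bar * (K/f)^p)` — rewards preys found with few baits,
#'   reproducibly;
#' * `wdScore`: `sqrt(X_bar * ((K/f) * omega)^p)` — additionally up-weights
#'   preys whose counts in a bait subset stand above the general background
#'   level, so effectors shared by a few related GTPases are not penalized.
#'
#' @param xbar mean spectral count(s) over the bait's replicates.
#' @param mu,sigma cross-panel mean and standard deviation of bait-level means.
#' @param p number of replicates with detection.
#' @param f number of baits with detection.
#' @param K number of baits in the panel.
#' @param omega cross-bait variability weight, `>= 1`.
#' @return numeric vector of scores.
#' @examples
#' dScore(10, p = 3, f = 1, K = 34)  # ~626.93
#' @name compass-scores
NULL

#' @rdname compass-scores
#' @export
zScore <- function(xbar, mu, sigma) {
    z <- (xbar - mu) / sigma
    z[sigma == 0] <- 0
    z
}

#' @rdname compass-scores
#' @export
dScore <- function(xbar, p, f, K) {
    sqrt(xbar * (K / f)^p)
}

#' @rdname compass-scores
#' @export
wdScore <- function(xbar, p, f, K, omega) {
    sqrt(xbar * ((K / f) * omega)^p)
}

#' Bait-level and panel-level prey statistics
#'
#' First stage of the panel-comparative scoring: per (bait, prey) the mean
#' spectral count `X_bar` over the bait's replicates and the replicate
#' reproducibility `p` (replicates with count > 0); per prey, over all `K`
#' baits (zero-count baits included), the bait frequency `f`, the mean `mu`
#' and standard deviation `sigma` (n-1 denominator) of the bait-level means,
#' and the variability weight `omega = max(1, sigma/mu)`. Preys detected with
#' no bait are dropped.
#'
#' @param counts a [CountMatrix-class].
#' @param aggregate `"mean"` (default; replicate-number invariant) or `"sum"`
#'   to aggregate replicate counts into `X_bar`.
#' @return a list with data.frames `baitPrey` (`bait_id`, `prey_id`, `X_bar`,
#'   `p`) and `preyPanel` (`prey_id`, `f`, `mu`, `sigma`, `omega`), plus `K`
#'   and the per-bait replicate counts `nRep`.
#' @export
baitLevelStats <- function(counts, aggregate = c("mean", "sum")) {
    aggregate <- match.arg(aggregate)
    m <- assay(counts, "counts")
    bait <- as.character(colData(counts)$bait_id)
    baits <- unique(bait)
    K <- length(baits)
    if (K < 2L)
        stop("panel statistics need at least 2 baits (K = ", K, ")")
    if (anyDuplicated(rownames(m)))
        stop("duplicate prey identifiers; run collapseDuplicateGenes() first")
    nRep <- vapply(baits, function(b) sum(bait == b), integer(1))
    if (nrow(m) == 0L) {
        return(list(
            baitPrey = data.frame(bait_id = character(), prey_id = character(),
                                  X_bar = numeric(), p = integer()),
            preyPanel = data.frame(prey_id = character(), f = integer(),
                                   mu = numeric(), sigma = numeric(),
                                   omega = numeric()),
            K = K, nRep = nRep))
    }
    ## preys x baits matrices of replicate means and detection counts
    sums <- vapply(baits, function(b)
        rowSums(m[, bait == b, drop = FALSE]), numeric(nrow(m)))
    det <- vapply(baits, function(b)
        rowSums(m[, bait == b, drop = FALSE] > 0), numeric(nrow(m)))
    dim(sums) <- dim(det) <- c(nrow(m), K)
    means <- sweep(sums, 2L, nRep, "/")
    xb <- if (aggregate == "mean") means else sums
    keep <- rowSums(det) > 0
    means <- means[keep, , drop = FALSE]
    xb <- xb[keep, , drop = FALSE]
    det <- det[keep, , drop = FALSE]
    preys <- rownames(m)[keep]

    f <- as.integer(rowSums(det > 0))
    mu <- rowMeans(means)
    sigma <- sqrt(rowSums((means - mu)^2) / (K - 1))
    omega <- ifelse(mu > 0, pmax(1, sigma / mu), 1)

    baitPrey <- data.frame(
        bait_id = rep(baits, each = length(preys)),
        prey_id = rep(preys, times = K),
        X_bar = as.vector(xb),
        p = as.integer(det),
        stringsAsFactors = FALSE)
    preyPanel <- data.frame(prey_id = preys, f = f, mu = mu, sigma = sigma,
                            omega = omega, row.names = NULL,
                            stringsAsFactors = FALSE)
    list(baitPrey = baitPrey, preyPanel = preyPanel, K = K, nRep = nRep)
}

#' Panel-comparative spectral-count scoring
#'
#' Computes the full score table: one row per (bait, prey) for every prey
#' detected with at least one bait, carrying `X_bar`, `p`, `f`, `omega` and
#' the Z, D and WD scores (see [dScore()] for the formulas). High D/WD marks
#' preys found reproducibly with few baits — the signature of a specific
#' interactor against the shared mitochondrial/cytosolic background of the
#' panel.
#'
#' @inheritParams baitLevelStats
#' @return a `data.frame` with columns `bait_id`, `prey_id`, `X_bar`, `p`,
#'   `f`, `omega`, `Z`, `D`, `WD`; attributes `K` and `nRep`.
#' @examples
#' # a prey exclusive to one bait dominates the WD ranking
#' @export
computeCompass <- function(counts, aggregate = c("mean", "sum")) {
    st <- baitLevelStats(counts, aggregate = aggregate)
    bp <- st$baitPrey
    pp <- st$preyPanel
    i <- match(bp$prey_id, pp$prey_id)
    tab <- data.frame(
        bait_id = bp$bait_id,
        prey_id = bp$prey_id,
        X_bar = bp$X_bar,
        p = bp$p,
        f = pp$f[i],
        omega = pp$omega[i],
        Z = zScore(bp$X_bar, pp$mu[i], pp$sigma[i]),
        D = dScore(bp$X_bar, bp$p, pp$f[i], st$K),
        WD = wdScore(bp$X_bar, bp$p, pp$f[i], st$K, pp$omega[i]),
        stringsAsFactors = FALSE)
    tab <- tab[order(tab$bait_id, -tab$WD, tab$prey_id), , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "K") <- st$K
    attr(tab, "nRep") <- st$nRep
    tab
}

#' Percentile normalization of WD scores
#'
#' Optionally rescales WD scores by the panel-wide WD value at a given
#' percentile (linear interpolation between order statistics, the default
#' quantile definition), adding a `WD_norm` column; `WD` itself is unchanged.
#' Off by default in the pipeline: bubble sizing uses the raw square root of
#' the WD score.
#'
#' @param table a compass score table from [computeCompass()].
#' @param percentile percentile in (0, 100] defining the divisor.
#' @return the table with an added `WD_norm` column.
#' @export
normalizeWD <- function(table, percentile = 100) {
    if (!is.numeric(percentile) || length(percentile) != 1L ||
        percentile <= 0 || percentile > 100)
        stop("percentile must be a single value in (0, 100]")
    if (!nrow(table)) stop("empty score table")
    divisor <- as.numeric(stats::quantile(table$WD, percentile / 100,
                                          type = 7, names = FALSE))
    if (divisor <= 0) {
        warning("WD percentile divisor is 0; WD_norm set to 0")
        table$WD_norm <- 0
    } else {
        table$WD_norm <- table$WD / divisor
    }
    table
}
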