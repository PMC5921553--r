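#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroniThreshold(0.05, 1211 * 6291)   # 6.56e-9
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
    if (m < 1) stop("m must be >= 1")
    alpha / m
}

#' Fisher-Z asymptotic p-value for a Pearson correlation
#'
#' Two-sided p-value from the Fisher transform: \eqn{z = \mathrm{atanh}(r)},
#' with \eqn{z\sqrt{n-3}} asymptotically standard normal under the null of no
#' correlation. `|r| = 1` is handled as the zero limit.
#'
#' @param r Pearson correlation(s) in \[-1, 1\].
#' @param n Number of paired observations (>= 4).
#' @return p-value(s) in \[0, 1\].
#' @export
fisherZPvalue <- function(r, n) {
    if (n < 4) stop("need n >= 4 observations")
    z <- atanh(pmax(pmin(r, 1), -1))
    2 * stats::pnorm(-abs(z) * sqrt(n - 3))
}

#' Cross-omic phenotypic correlation screen
#'
#' Computes all |A| x |B| Pearson correlations between two feature sets on
#' the same subjects, with Fisher-Z asymptotic p-values and a Bonferroni
#' threshold of `alpha / (|A| * |B|)`. The full grid is processed in blocks
#' of `blockSize` rows of set A so large screens stream without holding every
#' result: exact pass counts are kept for the whole grid, while only pairs
#' with p-value at most `reportThreshold` are materialized.
#'
#' Zero-variance features yield undefined correlations; their pairs are
#' reported with `r = NA` and remain in the multiple-testing denominator
#' (the grid size is the denominator, not the testable subset).
#'
#' @param setA,setB Features x subjects matrices (or `SummarizedExperiment`s)
#'   sharing the same subject columns.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param blockSize Rows of set A per block (default 512).
#' @param reportThreshold p-value cutoff for materialized pairs; defaults to
#'   the Bonferroni threshold when the grid exceeds `10^6` pairs, else 1
#'   (report everything).
#' @return List with `results` (`data.frame`: `featureA`, `featureB`, `r`,
#'   `z`, `p`, `passes_bonferroni`), `m` (grid size), `threshold`, `nPass`
#'   (exact count of passing pairs over the whole grid), `nNA` (pairs with
#'   undefined r), and `n` (subjects).
#' @examples
#' ped <- simulatePedigree(seed = 1)
#' a <- simulateFeatures(ped, 10, vg = 0.5, vc = 0, ve = 0.5, seed = 2)
#' b <- simulateFeatures(ped, 8, vg = 0.5, vc = 0, ve = 0.5, seed = 3)
#' scr <- phenotypicScreen(a, b)
#' scr$m; scr$threshold
#' @export
phenotypicScreen <- function(setA, setB, alpha = 0.05, blockSize = 512L,
                             reportThreshold = NULL) {
    XA <- .featureValues(setA)
    XB <- .featureValues(setB)
    if (!is.null(colnames(XA)) && !is.null(colnames(XB))) {
        if (!setequal(colnames(XA), colnames(XB)))
            stop("the two sets cover different subjects")
        XB <- XB[, colnames(XA), drop = FALSE]
    } else if (ncol(XA) != ncol(XB))
        stop("subject count mismatch")
    n <- ncol(XA)
    if (n < 4) stop("need at least 4 subjects")
    mA <- nrow(XA); mB <- nrow(XB)
    m <- mA * mB
    threshold <- bonferroniThreshold(alpha, m)
    if (is.null(reportThreshold))
        reportThreshold <- if (m > 1e6) threshold else 1
    idA <- rownames(XA) %||% sprintf("A%05d", seq_len(mA))
    idB <- rownames(XB) %||% sprintf("B%05d", seq_len(mB))
    tB <- t(XB)
    nPass <- 0L; nNA <- 0L
    chunks <- list()
    for (start in seq(1L, mA, by = blockSize)) {
        rows <- start:min(start + blockSize - 1L, mA)
        r <- suppressWarnings(stats::cor(t(XA[rows, , drop = FALSE]), tB))
        p <- fisherZPvalue(r, n)
        nNA <- nNA + sum(is.na(r))
        pass <- !is.na(p) & p <= threshold
        nPass <- nPass + sum(pass)
        keep <- which(is.na(p) | p <= reportThreshold, arr.ind = TRUE)
        if (nrow(keep)) {
            rk <- r[keep]
            chunks[[length(chunks) + 1L]] <- data.frame(
                featureA = idA[rows[keep[, 1]]], featureB = idB[keep[, 2]],
                r = rk, z = atanh(pmax(pmin(rk, 1), -1)), p = p[keep],
                passes_bonferroni = !is.na(p[keep]) & p[keep] <= threshold,
                stringsAsFactors = FALSE)
        }
    }
    results <- if (length(chunks)) do.call(rbind, chunks) else
        data.frame(featureA = character(0), featureB = character(0),
                   r = numeric(0), z = numeric(0), p = numeric(0),
                   passes_bonferroni = logical(0))
    rownames(results) <- NULL
    list(results = results[order(results$p), , drop = FALSE], m = m,
         threshold = threshold, nPass = nPass, nNA = nNA, n = n)
}
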