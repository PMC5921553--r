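#' Reference-based cell-type proportion estimation
#'
#' Estimates per-subject cell-type proportions from bulk profiles by least
#' squares against a reference signature, enforcing nonnegativity by
#' iterative pruning: fit unconstrained OLS on the active set, drop the most
#' negative coefficient, and refit until all remaining coefficients are
#' nonnegative. With `constrainSum = TRUE` the coefficients are renormalized
#' to sum to one.
#'
#' @param bulk Features x subjects matrix or `SummarizedExperiment`; features
#'   are intersected with the signature's by name (if neither is named, the
#'   rows are matched positionally and must agree in number).
#' @param signature Features x cell-types reference matrix (full column
#'   rank), e.g. from [makeCellSignature()].
#' @param constrainSum Renormalize each subject's coefficients to sum to one
#'   (default `TRUE`).
#' @return Subjects x cell-types matrix of proportions (unconstrained
#'   coefficients when `constrainSum = FALSE`).
#' @examples
#' sig <- makeCellSignature(nFeatures = 60, nTypes = 3, seed = 1)
#' mix <- simulateMixture(sig, nSubjects = 5, seed = 2)
#' p <- estimateProportions(mix$values, sig)
#' max(abs(p - mix$proportions)) < 1e-6
#' @export
estimateProportions <- function(bulk, signature, constrainSum = TRUE) {
    B <- .featureValues(bulk)
    S <- as.matrix(signature)
    if (!is.null(rownames(B)) && !is.null(rownames(S))) {
        common <- intersect(rownames(B), rownames(S))
        B <- B[common, , drop = FALSE]
        S <- S[common, , drop = FALSE]
    } else if (nrow(B) != nrow(S))
        stop("unnamed bulk and signature features do not match in number")
    p <- ncol(S)
    if (nrow(S) < p)
        stop(sprintf("feature intersection (%d) smaller than cell-type count (%d)",
                     nrow(S), p))
    if (qr(S)$rank < p) stop("signature matrix is rank deficient")
    out <- matrix(0, ncol(B), p,
                  dimnames = list(colnames(B), colnames(S)))
    for (s in seq_len(ncol(B))) {
        y <- B[, s]
        if (all(y == 0)) {
            warning(sprintf("subject %s has an all-zero profile",
                            colnames(B)[s] %||% s))
            next
        }
        active <- seq_len(p)
        beta <- numeric(p)
        while (length(active)) {
            co <- qr.coef(qr(S[, active, drop = FALSE]), y)
            if (all(co >= 0)) { beta[active] <- co; break }
            active <- active[-which.min(co)]
        }
        if (constrainSum) {
            tot <- sum(beta)
            beta <- if (tot > 0) beta / tot else beta
        }
        out[s, ] <- beta
    }
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group cell-type proportions into reporting classes
#'
#' Sums member-type proportions within each class (e.g. collapsing many
#' leukocyte subtypes into lymphocytes / neutrophils / monocytes); row sums
#' are preserved.
#'
#' @param props Subjects x cell-types matrix, e.g. from
#'   [estimateProportions()].
#' @param grouping Named character vector mapping every cell type to a class.
#' @return Subjects x classes matrix.
#' @examples
#' p <- matrix(c(0.2, 0.3, 0.5), 1, dimnames = list("s1", c("a", "b", "c")))
#' groupProportions(p, c(a = "lymph", b = "lymph", c = "mono"))
#' @export
groupProportions <- function(props, grouping) {
    P <- as.matrix(props)
    unmapped <- setdiff(colnames(P), names(grouping))
    if (length(unmapped))
        stop("unmapped cell type(s): ", paste(unmapped, collapse = ", "))
    cls <- grouping[colnames(P)]
    out <- t(rowsum(t(P), group = cls))
    rownames(out) <- rownames(P)
    out
}
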