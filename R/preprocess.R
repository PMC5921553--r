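#' Build a feature SummarizedExperiment
#'
#' Convenience constructor wrapping a features x subjects value matrix,
#' optional detection p-value matrix of the same shape, optional feature
#' annotations and per-subject covariates into a `SummarizedExperiment`.
#'
#' @param values Features x subjects numeric matrix with dimnames.
#' @param detection Optional detection p-value matrix, same shape.
#' @param annotations Optional `data.frame` (one row per feature) with
#'   columns such as `chromosome`, `start`, `end`, `symbol`.
#' @param covariates Optional `data.frame` (one row per subject).
#' @return A `SummarizedExperiment`.
#' @export
makeFeatureSet <- function(values, detection = NULL, annotations = NULL,
                           covariates = NULL) {
    values <- as.matrix(values)
    if (anyDuplicated(rownames(values)))
        stop("duplicate feature ids")
    if (anyDuplicated(colnames(values)))
        stop("duplicate subject ids")
    assays <- list(values = values)
    if (!is.null(detection)) {
        detection <- as.matrix(detection)
        if (!identical(dim(detection), dim(values)))
            stop("detection matrix must shape-match values")
        assays$detection <- detection
    }
    colD <- if (is.null(covariates))
        S4Vectors::DataFrame(row.names = colnames(values))
    else S4Vectors::DataFrame(covariates, row.names = colnames(values))
    if (is.null(colnames(values)) && nrow(colD) == 0)
        colD <- S4Vectors::make_zero_col_DFrame(ncol(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = colD)
    if (!is.null(annotations))
        SummarizedExperiment::rowData(se) <- annotations
    se
}

#' Read / write feature matrices as TSV
#'
#' On disk, matrices are TSV with subjects as rows and features as columns,
#' first column the subject id (a detection matrix uses the same layout).
#' Internally, matrices are features x subjects.
#'
#' @param path TSV path.
#' @param detectionPath Optional path of a matching detection p-value TSV.
#' @return `readFeatureMatrix()`: a `SummarizedExperiment`;
#'   `writeFeatureMatrix()`: the path, invisibly.
#' @export
readFeatureMatrix <- function(path, detectionPath = NULL) {
    rd <- function(p) {
        d <- utils::read.table(p, header = TRUE, sep = "\t",
                               row.names = 1, check.names = FALSE)
        t(as.matrix(d))
    }
    values <- rd(path)
    det <- if (is.null(detectionPath)) NULL else rd(detectionPath)
    makeFeatureSet(values, detection = det)
}

#' @rdname readFeatureMatrix
#' @param se `SummarizedExperiment` or features x subjects matrix.
#' @param assay Assay to write (default `"values"`).
#' @export
writeFeatureMatrix <- function(se, path, assay = "values") {
    X <- .featureValues(se, assay)
    d <- data.frame(subject = colnames(X), t(X), check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Detection-based feature filter
#'
#' Keeps features whose detection p-value calls them detected in at least
#' `subjectFraction` of subjects (boundary inclusive). Expression arrays
#' conventionally call a probe detected when its detection p-value is at most
#' the threshold (`direction = "below"`); the direction is a parameter so the
#' opposite convention can be applied where a platform reports it that way.
#'
#' @param se `SummarizedExperiment` with assays `"values"` and `"detection"`.
#' @param threshold Detection p-value threshold (default 0.05).
#' @param subjectFraction Minimum fraction of subjects (default 0.25).
#' @param direction `"below"`: detected means p <= threshold (default);
#'   `"above"`: detected means p > threshold.
#' @param verbose Print a kept/total summary line (default `TRUE`).
#' @return The filtered `SummarizedExperiment`; `metadata()$detection_filter`
#'   records `kept`, `total` and `percent`.
#' @examples
#' ped <- simulatePedigree(seed = 1)
#' se <- simulateFeatures(ped, 200, vg = 0.3, vc = 0.1, ve = 0.6, seed = 2)
#' se <- simulateDetection(se, detectedFraction = 0.4, seed = 3)
#' kept <- detectionFilter(se)
#' S4Vectors::metadata(kept)$detection_filter
#' @export
detectionFilter <- function(se, threshold = 0.05, subjectFraction = 0.25,
                            direction = c("below", "above"), verbose = TRUE) {
    direction <- match.arg(direction)
    if (!"detection" %in% SummarizedExperiment::assayNames(se))
        stop("no detection p-value assay present")
    P <- SummarizedExperiment::assay(se, "detection")
    det <- if (direction == "below") P <= threshold else P > threshold
    keep <- rowMeans(det) >= subjectFraction
    out <- se[keep, ]
    info <- list(kept = sum(keep), total = length(keep),
                 percent = round(100 * sum(keep) / length(keep), 1))
    S4Vectors::metadata(out)$detection_filter <- info
    if (verbose)
        message(sprintf("detection filter: kept %d of %d features (%.1f%%)",
                        info$kept, info$total, info$percent))
    out
}

#' Log-transform and quantile-normalize a feature matrix
#'
#' Applies `log2(x + offset)` followed by quantile normalization across
#' subjects (each subject's sorted values are replaced by the rank-wise mean
#' distribution; ties receive the mean of the quantiles they span). This is
#' the package's normalization stand-in for array-specific background
#' correction and variance-stabilizing transforms, which require raw array
#' data; it preserves within-subject rank order and makes the per-subject
#' distributions identical, which is the contract downstream stages rely on.
#'
#' @param se `SummarizedExperiment` or features x subjects matrix.
#' @param log2Offset Offset added before `log2` (default 1); set to `NA` to
#'   skip the log step.
#' @param assay Assay to normalize.
#' @return Same container type with the normalized assay.
#' @export
normalizeFeatures <- function(se, log2Offset = 1, assay = "values") {
    X <- .featureValues(se, assay)
    if (!is.numeric(X)) stop("non-numeric feature values")
    if (!is.na(log2Offset)) {
        if (any(X + log2Offset <= 0))
            stop("values + offset must be strictly positive for log2")
        X <- log2(X + log2Offset)
    }
    ## quantile normalization across subjects (columns)
    X <- limma::normalizeQuantiles(X, ties = TRUE)
    if (is(se, "SummarizedExperiment")) {
        SummarizedExperiment::assay(se, assay) <- X
        se
    } else X
}

#' Build the covariate design matrix
#'
#' Intercept, microarray batch and array-position indicators, sex, centered
#' age, centered age squared, sex-by-age interactions, and cell-proportion
#' columns (dropping the last class, since proportions sum to one). Age is
#' centered before squaring to reduce collinearity; the coefficients are
#' nuisance parameters and are not interpreted.
#'
#' @param covariates `data.frame`/`DataFrame` with columns `sex`, `age` and
#'   optionally `batch`, `position`.
#' @param cellProps Optional subjects x classes proportion matrix.
#' @return Numeric design matrix (subjects x columns).
#' @export
buildDesign <- function(covariates, cellProps = NULL) {
    cv <- as.data.frame(covariates)
    sexM <- as.numeric(cv$sex == "male")
    ageC <- cv$age - mean(cv$age)
    X <- cbind(intercept = 1, sex = sexM, age = ageC, age2 = ageC^2,
               sex_age = sexM * ageC, sex_age2 = sexM * ageC^2)
    for (fac in c("batch", "position")) {
        if (!is.null(cv[[fac]])) {
            f <- factor(cv[[fac]])
            if (nlevels(f) > 1) {
                M <- stats::model.matrix(~f)[, -1, drop = FALSE]
                colnames(M) <- paste0(fac, levels(f)[-1])
                X <- cbind(X, M)
            }
        }
    }
    if (!is.null(cellProps)) {
        P <- as.matrix(cellProps)
        P <- P[, -ncol(P), drop = FALSE]   # sum-to-one: drop one class
        colnames(P) <- paste0("cell_", colnames(P))
        X <- cbind(X, P)
    }
    X
}

#' Residualize features on covariates
#'
#' Per feature, ordinary least-squares residuals on the covariate design.
#' Collinear design columns are detected by QR pivoting and dropped with a
#' warning; residuals are orthogonal to every retained column.
#'
#' @param se `SummarizedExperiment` (features x subjects) or matrix.
#' @param design Numeric design matrix (subjects x columns), e.g. from
#'   [buildDesign()]. Defaults to building one from `colData(se)`.
#' @param cellProps Optional subjects x classes proportions passed to
#'   [buildDesign()] when `design` is `NULL`.
#' @param returnCoef Attach the coefficient matrix as
#'   `metadata()$covariate_coef` / `attr(,"coef")` (default `FALSE`).
#' @return Same container type with the residualized `"values"` assay.
#' @examples
#' ped <- simulatePedigree(seed = 1)
#' se <- simulateFeatures(ped, 20, vg = 0.4, vc = 0.1, ve = 0.5,
#'                        betaSex = 1, seed = 2)
#' res <- residualizeFeatures(se)
#' @export
residualizeFeatures <- function(se, design = NULL, cellProps = NULL,
                                returnCoef = FALSE) {
    X <- .featureValues(se)
    if (is.null(design)) {
        if (!is(se, "SummarizedExperiment"))
            stop("supply a design matrix for plain-matrix input")
        design <- buildDesign(SummarizedExperiment::colData(se), cellProps)
    }
    design <- as.matrix(design)
    n <- ncol(X)
    if (nrow(design) != n)
        stop("design rows must equal number of subjects")
    qrX <- qr(design)
    if (qrX$rank < ncol(design)) {
        dropped <- colnames(design)[qrX$pivot[-seq_len(qrX$rank)]]
        warning("dropping collinear design column(s): ",
                paste(dropped, collapse = ", "))
        design <- design[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
        qrX <- qr(design)
    }
    if (n <= qrX$rank)
        stop("fewer subjects than design columns after pruning")
    Yt <- t(X)                             # subjects x features
    resid <- qr.resid(qrX, Yt)
    out <- t(resid)
    dimnames(out) <- dimnames(X)
    coef <- if (returnCoef) qr.coef(qrX, Yt) else NULL
    if (is(se, "SummarizedExperiment")) {
        SummarizedExperiment::assay(se, "values") <- out
        if (returnCoef) S4Vectors::metadata(se)$covariate_coef <- coef
        se
    } else {
        if (returnCoef) attr(out, "coef") <- coef
        out
    }
}
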