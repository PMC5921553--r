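#' Read a pedigree file
#'
#' Reads a LINKAGE/PED-dialect pedigree table: whitespace- or tab-delimited
#' columns `FamilyID IndividualID FatherID MotherID Sex Age`, header optional,
#' `"0"` (or empty) coding a missing parent, sex coded `1`/`M` = male,
#' `2`/`F` = female.
#'
#' @param path Path to the pedigree file.
#' @return A validated [Pedigree]; subject order equals file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("f1 mom 0 0 2 41", "f1 dad 0 0 1 44",
#'              "f1 kid dad mom 2 12"), f)
#' readPedigree(f)
#' @export
readPedigree <- function(path) {
    if (!file.exists(path)) stop("pedigree file not found: ", path)
    first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t,]+")[[1]]
    header <- any(grepl("fam|^id$|individual|sex|age", first,
                        ignore.case = TRUE))
    d <- utils::read.table(path, header = header, stringsAsFactors = FALSE,
                           colClasses = c(rep("character", 5), "numeric"))
    if (ncol(d) < 6)
        stop("expected 6 columns: FamilyID IndividualID FatherID MotherID Sex Age")
    names(d)[1:6] <- c("family_id", "id", "father_id", "mother_id",
                       "sex", "age")
    Pedigree(d[, c("id", "family_id", "father_id", "mother_id", "sex", "age")])
}

#' Additive (numerator) relationship matrix
#'
#' Computes twice the kinship coefficient for every subject pair by the
#' standard recursion over a parents-first ordering: founders are unrelated
#' and non-inbred, \eqn{\Phi(i,i) = \tfrac12(1 + \Phi(m_i, f_i))} and
#' \eqn{\Phi(i,j) = \tfrac12(\Phi(m_i, j) + \Phi(f_i, j))} for a non-founder
#' `i` with `j` already processed; a missing parent contributes 0.
#'
#' @param ped A [Pedigree].
#' @return A [RelationshipMatrix] of kind `"additive"` in subject order
#'   (parent-offspring entries 0.5, full sibs 0.5, founder diagonal 1).
#' @export
additiveMatrix <- function(ped) {
    stopifnot(is(ped, "Pedigree"))
    d <- ped@data
    n <- nrow(d)
    mo <- match(d$mother_id, d$id)
    fa <- match(d$father_id, d$id)
    ord <- .topoOrder(d)
    K <- matrix(0, n, n)
    phi <- function(a, b) if (is.na(a)) 0 else K[a, b]
    for (pos in seq_along(ord)) {
        i <- ord[pos]
        K[i, i] <- 0.5 * (1 + if (!is.na(mo[i]) && !is.na(fa[i]))
            K[mo[i], fa[i]] else 0)
        for (j in ord[seq_len(pos - 1L)]) {
            kij <- 0.5 * (phi(mo[i], j) + phi(fa[i], j))
            K[i, j] <- K[j, i] <- kij
        }
    }
    A <- 2 * K
    dimnames(A) <- list(d$id, d$id)
    new("RelationshipMatrix", values = A, kind = "additive")
}

#' Household (shared-family) relationship matrix
#'
#' Indicator matrix of shared family membership used to model
#' common-environment covariance: entry (i, j) is 1 when subjects i and j
#' belong to the same family, else 0.
#'
#' @param ped A [Pedigree].
#' @return A [RelationshipMatrix] of kind `"household"`.
#' @export
householdMatrix <- function(ped) {
    stopifnot(is(ped, "Pedigree"))
    fam <- ped@data$family_id
    H <- 1 * outer(fam, fam, "==")
    dimnames(H) <- list(ped@data$id, ped@data$id)
    new("RelationshipMatrix", values = H, kind = "household")
}

#' Write a relationship matrix as TSV
#'
#' @param rel A [RelationshipMatrix].
#' @param path Output path; subject ids become row and column labels.
#' @return `path`, invisibly.
#' @export
writeRelationshipMatrix <- function(rel, path) {
    stopifnot(is(rel, "RelationshipMatrix"))
    utils::write.table(relValues(rel), path, sep = "\t", quote = FALSE,
                       col.names = NA)
    invisible(path)
}

#' Classify all unordered subject pairs by relationship
#'
#' Each of the n(n-1)/2 pairs receives exactly one most-specific label:
#' `sibling` (at least one shared listed parent), `mother-offspring`,
#' `father-offspring`, `spouse` (co-parents of at least one child, no
#' genetic link), or `unrelated` (everything else, including cross-family
#' pairs). `parent-offspring` is the union of the mother- and
#' father-offspring classes and is reported by [pairCorrelations()].
#'
#' @param ped A [Pedigree].
#' @return A `data.frame` with columns `id1`, `id2`, `class`, carrying a
#'   `"counts"` attribute (a named table of class counts).
#' @examples
#' ped <- simulatePedigree(seed = 1)
#' table(classifyPairs(ped)$class)
#' @export
classifyPairs <- function(ped) {
    stopifnot(is(ped, "Pedigree"))
    d <- ped@data
    n <- nrow(d)
    mo <- d$mother_id
    fa <- d$father_id
    ## co-parent (spouse) lookup: unordered "mother|father" keys
    couples <- unique(stats::na.omit(
        ifelse(!is.na(mo) & !is.na(fa), paste(mo, fa, sep = "\r"), NA)))
    idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    cls <- rep("unrelated", length(i))
    sameParent <- (!is.na(mo[i]) & !is.na(mo[j]) & mo[i] == mo[j]) |
                  (!is.na(fa[i]) & !is.na(fa[j]) & fa[i] == fa[j])
    cls[sameParent] <- "sibling"
    isMO <- (!is.na(mo[j]) & mo[j] == d$id[i]) |
            (!is.na(mo[i]) & mo[i] == d$id[j])
    isFO <- (!is.na(fa[j]) & fa[j] == d$id[i]) |
            (!is.na(fa[i]) & fa[i] == d$id[j])
    cls[isMO] <- "mother-offspring"
    cls[isFO] <- "father-offspring"
    key1 <- paste(d$id[i], d$id[j], sep = "\r")
    key2 <- paste(d$id[j], d$id[i], sep = "\r")
    cls[cls == "unrelated" & (key1 %in% couples | key2 %in% couples)] <- "spouse"
    out <- data.frame(id1 = d$id[i], id2 = d$id[j], class = cls,
                      stringsAsFactors = FALSE)
    attr(out, "counts") <- table(factor(out$class,
        levels = c("sibling", "mother-offspring", "father-offspring",
                   "spouse", "unrelated")))
    out
}

#' Per-class mean absolute correlation between relative pairs
#'
#' For each relationship class, computes Pearson correlations between the
#' feature values of pair members and summarizes the absolute correlations.
#' Under the default `method = "per-feature"`, the correlation for a feature
#' is taken across all pairs of a class (member-1 value vs member-2 value);
#' the mean and SD of |r| are then taken over features. Symmetric classes
#' (sibling, spouse, unrelated) are double-entered — each pair contributes in
#' both orders — to remove ordering arbitrariness. `method = "per-pair"`
#' instead correlates the two members' whole profiles across features and
#' summarizes over pairs.
#'
#' The summarized classes are sibling, mother-offspring, father-offspring,
#' parent-offspring (their union), spouse, and unrelated; when
#' `includeSpouses = TRUE` (default) spouse pairs are additionally pooled
#' into the unrelated class, which is how family studies with co-parent
#' founders usually report it.
#'
#' @param values Numeric matrix, features x subjects, with subject ids as
#'   column names covering the pedigree, or a `SummarizedExperiment`.
#' @param pairs Result of [classifyPairs()].
#' @param method `"per-feature"` (default) or `"per-pair"`.
#' @param doubleEntry Double-enter symmetric classes (default `TRUE`).
#' @param includeSpouses Pool spouse pairs into `unrelated` (default `TRUE`).
#' @param minPairs Classes with fewer pairs are skipped with a warning.
#' @return `data.frame` with columns `class`, `n_pairs`, `mean_abs_r`,
#'   `sd_abs_r`, `n_used`, `n_skipped` (zero-variance features or pairs
#'   skipped).
#' @export
pairCorrelations <- function(values, pairs, method = c("per-feature", "per-pair"),
                             doubleEntry = TRUE, includeSpouses = TRUE,
                             minPairs = 3L) {
    method <- match.arg(method)
    X <- .featureValues(values)
    if (is.null(colnames(X)))
        stop("values must have subject ids as column names")
    symClasses <- c("sibling", "spouse", "unrelated")
    classes <- list(
        "sibling" = "sibling",
        "mother-offspring" = "mother-offspring",
        "father-offspring" = "father-offspring",
        "parent-offspring" = c("mother-offspring", "father-offspring"),
        "spouse" = "spouse",
        "unrelated" = if (includeSpouses) c("unrelated", "spouse")
                      else "unrelated")
    rows <- lapply(names(classes), function(cl) {
        sel <- pairs$class %in% classes[[cl]]
        nPairs <- sum(sel)
        if (nPairs < minPairs) {
            warning(sprintf("class '%s' has %d pair(s) (< %d); skipped",
                            cl, nPairs, minPairs))
            return(data.frame(class = cl, n_pairs = nPairs,
                              mean_abs_r = NA_real_, sd_abs_r = NA_real_,
                              n_used = 0L, n_skipped = 0L))
        }
        i1 <- match(pairs$id1[sel], colnames(X))
        i2 <- match(pairs$id2[sel], colnames(X))
        sym <- doubleEntry && all(classes[[cl]] %in% symClasses)
        if (sym) {
            tmp <- c(i1, i2); i2 <- c(i2, i1); i1 <- tmp
        }
        if (method == "per-feature") {
            r <- .rowPairCor(X[, i1, drop = FALSE], X[, i2, drop = FALSE])
            used <- is.finite(r)
            data.frame(class = cl, n_pairs = nPairs,
                       mean_abs_r = mean(abs(r[used])),
                       sd_abs_r = stats::sd(abs(r[used])),
                       n_used = sum(used), n_skipped = sum(!used))
        } else {
            r <- vapply(seq_along(i1), function(k)
                suppressWarnings(stats::cor(X[, i1[k]], X[, i2[k]])),
                numeric(1))
            used <- is.finite(r)
            data.frame(class = cl, n_pairs = nPairs,
                       mean_abs_r = mean(abs(r[used])),
                       sd_abs_r = stats::sd(abs(r[used])),
                       n_used = sum(used), n_skipped = sum(!used))
        }
    })
    do.call(rbind, rows)
}

## Row-wise Pearson correlation between two conformable matrices; rows with
## zero variance on either side yield NA.
.rowPairCor <- function(X1, X2) {
    m1 <- rowMeans(X1); m2 <- rowMeans(X2)
    C1 <- X1 - m1; C2 <- X2 - m2
    num <- rowSums(C1 * C2)
    den <- sqrt(rowSums(C1 * C1) * rowSums(C2 * C2))
    r <- num / den
    r[den <= .Machine$double.eps * ncol(X1)] <- NA_real_
    r
}

.featureValues <- function(x, assay = "values") {
    if (is(x, "SummarizedExperiment"))
        return(SummarizedExperiment::assay(x, assay))
    as.matrix(x)
}
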