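#' Simulate a nuclear-family pedigree
#'
#' Generates a pedigree of nuclear families: every family has an enrolled
#' mother, each child links to her, and a subset of families also enrolls the
#' father. The default (`preset = "study"`) emulates a 48-subject cohort of
#' 16 families with 16 mothers, 6 fathers and 26 children: child counts
#' 3,3,3,2,2,2,2,1,...,1 (giving 13 sibling pairs) and fathers present in
#' families 1, 2, 4, 8, 9, 10 (giving 11 father-offspring pairs, hence 37
#' parent-offspring pairs in total). Parent ages are drawn uniformly in
#' 30-55 y, child ages in 8-18 y, child sex Bernoulli(0.5); structure is
#' fully deterministic, ages and sexes depend only on `seed`.
#'
#' @param nFamilies Number of families (ignored for the study preset).
#' @param childCounts Integer vector, children per family.
#' @param fatherFamilies Indices of families whose father is enrolled.
#' @param preset `"study"` (default) or `"custom"`.
#' @param seed Integer seed controlling ages and child sexes.
#' @return A [Pedigree].
#' @examples
#' ped <- simulatePedigree(seed = 7)
#' length(ped)                       # 48
#' attr(classifyPairs(ped), "counts")
#' @export
simulatePedigree <- function(nFamilies = 16L,
                             childCounts = NULL,
                             fatherFamilies = NULL,
                             preset = c("study", "custom"),
                             seed = 1L) {
    preset <- match.arg(preset)
    if (preset == "study") {
        nFamilies <- 16L
        childCounts <- c(3L, 3L, 3L, 2L, 2L, 2L, 2L, rep(1L, 9L))
        fatherFamilies <- c(1L, 2L, 4L, 8L, 9L, 10L)
    } else {
        if (is.null(childCounts))
            childCounts <- rep(1L, nFamilies)
        if (length(childCounts) != nFamilies)
            stop("childCounts must have one entry per family")
        if (is.null(fatherFamilies)) fatherFamilies <- integer(0)
        if (any(childCounts < 0))
            stop("negative child count")
    }
    withSeed(seed, {
        rows <- list()
        for (f in seq_len(nFamilies)) {
            fam <- sprintf("F%02d", f)
            mom <- sprintf("%s_M", fam)
            dad <- if (f %in% fatherFamilies) sprintf("%s_F", fam) else NA
            rows[[length(rows) + 1L]] <- data.frame(
                id = mom, family_id = fam, father_id = NA, mother_id = NA,
                sex = "female", age = stats::runif(1, 30, 55))
            if (!is.na(dad))
                rows[[length(rows) + 1L]] <- data.frame(
                    id = dad, family_id = fam, father_id = NA, mother_id = NA,
                    sex = "male", age = stats::runif(1, 30, 55))
            for (k in seq_len(childCounts[f]))
                rows[[length(rows) + 1L]] <- data.frame(
                    id = sprintf("%s_C%d", fam, k), family_id = fam,
                    father_id = dad, mother_id = mom,
                    sex = ifelse(stats::runif(1) < 0.5, "female", "male"),
                    age = stats::runif(1, 8, 18))
        }
        Pedigree(do.call(rbind, rows))
    })
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so the
#' simulator's per-stage substreams do not perturb user code.
#'
#' @param seed Integer seed (or `NULL` for no seeding).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

## Symmetric (eigen) factor L with L %*% t(L) = S, valid for PSD matrices
## (singular limits like ve = 0 included); errors when S is indefinite.
.psdFactor <- function(S, label = "covariance") {
    e <- eigen(S, symmetric = TRUE)
    tol <- 1e-8 * max(abs(e$values), 1)
    if (min(e$values) < -tol)
        stop(label, " is not positive semidefinite")
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

.vcFactor <- function(ped, vg, vc, ve) {
    A <- relValues(additiveMatrix(ped))
    H <- relValues(householdMatrix(ped))
    S <- vg * A + vc * H + ve * diag(nrow(A))
    .psdFactor(S, sprintf("covariance vg*A + vc*H + ve*I (vg=%g, vc=%g, ve=%g)",
                          vg, vc, ve))
}

#' Simulate family-structured features with known variance components
#'
#' Draws each feature from a zero-mean multivariate normal over subjects with
#' covariance \eqn{V_g A + V_c H + V_e I} (A = additive relationship, H =
#' household indicator), via a symmetric eigenfactorization (so singular
#' limits such as ve = 0 are allowed), then adds optional
#' fixed covariate effects (sex, age, age squared, batch). The true
#' components and covariate design are stored in the metadata so downstream
#' estimators can be scored against ground truth.
#'
#' @param ped A [Pedigree].
#' @param nFeatures Number of features to draw.
#' @param vg,vc,ve Non-negative true variance components.
#' @param betaSex,betaAge,betaAge2,betaBatch Covariate effect sizes
#'   (default 0). Batch effects are per-batch normal(0, betaBatch) shifts.
#' @param nBatches Number of microarray batches (subjects assigned
#'   round-robin); each batch has `positionsPerBatch` positions.
#' @param positionsPerBatch Array positions per batch.
#' @param seed Integer seed.
#' @return A `SummarizedExperiment` (features x subjects, assay `"values"`)
#'   with colData columns `sex`, `age`, `batch`, `position`, `family`, and
#'   `metadata()$truth = list(vg, vc, ve)`.
#' @examples
#' ped <- simulatePedigree(seed = 1)
#' se <- simulateFeatures(ped, 50, vg = 0.5, vc = 0.2, ve = 0.3, seed = 2)
#' dim(se)
#' @export
simulateFeatures <- function(ped, nFeatures, vg, vc, ve,
                             betaSex = 0, betaAge = 0, betaAge2 = 0,
                             betaBatch = 0, nBatches = 4L,
                             positionsPerBatch = 12L, seed = 1L) {
    stopifnot(is(ped, "Pedigree"), vg >= 0, vc >= 0, ve >= 0, vg + vc + ve > 0)
    d <- ped@data
    n <- nrow(d)
    L <- .vcFactor(ped, vg, vc, ve)
    withSeed(seed, {
        Y <- L %*% matrix(stats::rnorm(n * nFeatures), n, nFeatures)
        batch <- factor(rep_len(seq_len(nBatches), n))
        position <- factor(stats::ave(seq_len(n), batch, FUN = function(i)
            rep_len(seq_len(positionsPerBatch), length(i))))
        sexM <- as.numeric(d$sex == "male")
        ageC <- d$age - mean(d$age)
        shift <- betaSex * sexM + betaAge * ageC + betaAge2 * ageC^2
        if (betaBatch != 0)
            shift <- shift + stats::rnorm(nBatches, 0, betaBatch)[batch]
        Y <- Y + shift
        mat <- t(Y)   # features x subjects
        dimnames(mat) <- list(sprintf("feat_%05d", seq_len(nFeatures)), d$id)
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(values = mat),
            colData = S4Vectors::DataFrame(
                sex = d$sex, age = d$age, batch = batch,
                position = position, family = d$family_id,
                row.names = d$id))
        S4Vectors::metadata(se)$truth <- list(vg = vg, vc = vc, ve = ve)
        se
    })
}

#' Simulate paired traits with known component correlations
#'
#' Draws `nPairs` trait pairs from the two-trait variance-components model:
#' within-trait covariance \eqn{V_g A + V_c H + V_e I} and cross-trait
#' covariance \eqn{\rho_g\sqrt{V_{g1}V_{g2}}A + \rho_c\sqrt{V_{c1}V_{c2}}H +
#' \rho_e\sqrt{V_{e1}V_{e2}}I}. Used to validate [geneticCorrelation()].
#'
#' @param ped A [Pedigree].
#' @param nPairs Number of feature pairs.
#' @param vg1,vc1,ve1,vg2,vc2,ve2 True per-trait components.
#' @param rhoG,rhoC,rhoE Component correlations in \[-1, 1\].
#' @param seed Integer seed.
#' @return List with elements `trait1`, `trait2` (features x subjects
#'   matrices, row k of each being pair k) and `truth`.
#' @export
simulateBivariate <- function(ped, nPairs, vg1, vc1, ve1,
                              vg2 = vg1, vc2 = vc1, ve2 = ve1,
                              rhoG = 0, rhoC = 0, rhoE = 0, seed = 1L) {
    stopifnot(abs(rhoG) <= 1, abs(rhoC) <= 1, abs(rhoE) <= 1)
    A <- relValues(additiveMatrix(ped))
    H <- relValues(householdMatrix(ped))
    n <- nrow(A)
    Cg <- .comp2x2(vg1, vg2, rhoG)
    Cc <- .comp2x2(vc1, vc2, rhoC)
    Ce <- .comp2x2(ve1, ve2, rhoE)
    S <- kronecker(Cg, A) + kronecker(Cc, H) + kronecker(Ce, diag(n))
    L <- .psdFactor(S, sprintf(
        "bivariate covariance (rhoG=%g, rhoC=%g, rhoE=%g)", rhoG, rhoC, rhoE))
    withSeed(seed, {
        Z <- L %*% matrix(stats::rnorm(2 * n * nPairs), 2 * n, nPairs)
        t1 <- t(Z[seq_len(n), , drop = FALSE])
        t2 <- t(Z[n + seq_len(n), , drop = FALSE])
        dimnames(t1) <- dimnames(t2) <-
            list(sprintf("pair_%04d", seq_len(nPairs)), rownames(A))
        list(trait1 = t1, trait2 = t2,
             truth = list(vg1 = vg1, vc1 = vc1, ve1 = ve1, vg2 = vg2,
                          vc2 = vc2, ve2 = ve2, rhoG = rhoG, rhoC = rhoC,
                          rhoE = rhoE))
    })
}

.comp2x2 <- function(v1, v2, rho)
    matrix(c(v1, rho * sqrt(v1 * v2), rho * sqrt(v1 * v2), v2), 2, 2)

#' Synthetic cell-type reference signature
#'
#' Builds a features x cell-types signature with per-type marker blocks on a
#' shared lognormal baseline, guaranteeing full column rank. This is a
#' synthetic stand-in for published blood reference signatures, which are not
#' redistributed here; user-supplied signatures in the same layout are
#' accepted everywhere a signature is needed.
#'
#' @param nFeatures Number of signature features (>= `nTypes`).
#' @param nTypes Number of cell types.
#' @param markerStrength Multiplicative marker elevation (default 8).
#' @param seed Integer seed.
#' @return Numeric matrix features x types with dimnames.
#' @export
makeCellSignature <- function(nFeatures = 200L, nTypes = 6L,
                              markerStrength = 8, seed = 1L) {
    stopifnot(nFeatures >= nTypes)
    withSeed(seed, {
        base <- matrix(stats::rlnorm(nFeatures * nTypes, meanlog = 2,
                                     sdlog = 0.4), nFeatures, nTypes)
        markers <- rep_len(seq_len(nTypes), nFeatures)
        for (t in seq_len(nTypes))
            base[markers == t, t] <- base[markers == t, t] * markerStrength
        dimnames(base) <- list(sprintf("sig_%04d", seq_len(nFeatures)),
                               sprintf("type%d", seq_len(nTypes)))
        base
    })
}

#' Simulate bulk profiles as cell-type mixtures
#'
#' Each subject's profile is `signature %*% proportions` plus Gaussian noise,
#' with proportions drawn from a symmetric Dirichlet (gamma-normalized).
#'
#' @param signature Features x cell-types matrix (full column rank).
#' @param ped A [Pedigree] (or `nSubjects` may be given instead).
#' @param nSubjects Number of subjects when no pedigree is supplied.
#' @param alpha Dirichlet concentration (scalar or per-type vector).
#' @param noiseSd Gaussian noise SD added to each profile entry.
#' @param seed Integer seed.
#' @return List with `values` (features x subjects matrix) and `proportions`
#'   (subjects x types, rows summing to 1).
#' @export
simulateMixture <- function(signature, ped = NULL, nSubjects = NULL,
                            alpha = 1, noiseSd = 0, seed = 1L) {
    sig <- as.matrix(signature)
    if (qr(sig)$rank < ncol(sig))
        stop("signature matrix is rank deficient")
    if (!is.null(ped)) {
        ids <- subjectIds(ped); n <- length(ids)
    } else {
        if (is.null(nSubjects)) stop("supply ped or nSubjects")
        n <- nSubjects; ids <- sprintf("S%03d", seq_len(n))
    }
    p <- ncol(sig)
    alpha <- rep_len(alpha, p)
    withSeed(seed, {
        G <- matrix(stats::rgamma(n * p, shape = rep(alpha, each = n)), n, p)
        P <- G / rowSums(G)
        V <- sig %*% t(P)
        if (noiseSd > 0)
            V <- V + matrix(stats::rnorm(length(V), 0, noiseSd), nrow(V))
        dimnames(V) <- list(rownames(sig), ids)
        dimnames(P) <- list(ids, colnames(sig))
        list(values = V, proportions = P)
    })
}

#' Attach a synthetic detection p-value matrix
#'
#' Designates a fraction of features as "detected": those receive detection
#' p-values below `threshold` in at least `subjectFraction` of subjects;
#' undetected features receive sub-threshold p-values in strictly fewer
#' subjects, so the standard detection filter recovers the designated set
#' exactly. The ground-truth detected indicator is stored in the metadata.
#'
#' @param se `SummarizedExperiment` with a `"values"` assay (or a features x
#'   subjects matrix, which is wrapped).
#' @param detectedFraction Fraction of features designated detected.
#' @param threshold Detection p-value threshold (default 0.05).
#' @param subjectFraction Subject fraction defining detection (default 0.25).
#' @param seed Integer seed.
#' @return The input with an added `"detection"` assay and
#'   `metadata()$detected` logical vector.
#' @export
simulateDetection <- function(se, detectedFraction = 0.384, threshold = 0.05,
                              subjectFraction = 0.25, seed = 1L) {
    if (!is(se, "SummarizedExperiment"))
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(values = as.matrix(se)))
    m <- nrow(se); n <- ncol(se)
    need <- ceiling(subjectFraction * n)   # subjects required to pass
    withSeed(seed, {
        detected <- seq_len(m) %in%
            sample.int(m, round(detectedFraction * m))
        P <- matrix(stats::runif(m * n, min = threshold + 1e-9, max = 1), m, n)
        for (f in seq_len(m)) {
            kBelow <- if (detected[f])
                sample(seq.int(need, n), 1L)
            else if (need > 1L) sample.int(need, 1L) - 1L else 0L
            if (kBelow > 0) {
                cols <- sample.int(n, kBelow)
                P[f, cols] <- stats::runif(kBelow, 0, threshold)
            }
        }
        dimnames(P) <- dimnames(SummarizedExperiment::assay(se, "values"))
        SummarizedExperiment::assays(se)$detection <- P
        S4Vectors::metadata(se)$detected <- detected
        S4Vectors::metadata(se)$detection_rule <-
            list(threshold = threshold, subjectFraction = subjectFraction)
        se
    })
}
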