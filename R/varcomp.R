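## ---- internal machinery ----------------------------------------------------
##
## The covariance vg*A + vc*H + ve*I is block diagonal by family (founders of
## different families are unrelated and households do not overlap), so the
## likelihood factorizes over families. Families sharing an identical
## within-family (A, H) template are grouped so one Cholesky factor serves all
## of them; this is what makes genome scans over many families cheap.

.relMat <- function(x) {
    if (is(x, "RelationshipMatrix")) relValues(x) else as.matrix(x)
}

## connected components of the nonzero off-diagonal pattern of A + H
.blockMembership <- function(M) {
    n <- nrow(M)
    adj <- (abs(M) > 1e-12)
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (comp[s]) next
        cur <- cur + 1L
        frontier <- s
        comp[s] <- cur
        while (length(frontier)) {
            nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
            comp[nb] <- cur
            frontier <- nb
        }
    }
    comp
}

.vcStructure <- function(A, H, fams = NULL) {
    n <- nrow(A)
    if (is.null(fams)) fams <- .blockMembership(A + H)
    byFam <- split(seq_len(n), fams)
    keys <- vapply(byFam, function(ix)
        paste(length(ix),
              paste(signif(A[ix, ix], 12), collapse = ","),
              paste(H[ix, ix], collapse = ","), sep = "|"),
        character(1))
    groups <- lapply(split(byFam, keys), function(famList) {
        ix1 <- famList[[1]]
        list(A = A[ix1, ix1, drop = FALSE],
             H = H[ix1, ix1, drop = FALSE],
             k = length(ix1), m = length(famList),
             idx = matrix(unlist(famList), nrow = length(ix1)))
    })
    list(groups = unname(groups), n = n)
}

## One pass over all blocks: log|Sigma|, y'Si y, 1'Si y, 1'Si 1.
.vcEval <- function(y, vcs, vg, vc, ve) {
    ld <- 0; qyy <- 0; u <- 0; d <- 0
    for (g in vcs$groups) {
        S <- vg * g$A + vc * g$H
        diag(S) <- diag(S) + ve
        R <- tryCatch(chol(S), error = function(e) NULL)
        if (is.null(R)) return(NULL)
        Yb <- matrix(y[g$idx], nrow = g$k)
        Z <- backsolve(R, Yb, transpose = TRUE)
        O <- backsolve(R, rep(1, g$k), transpose = TRUE)
        ld <- ld + 2 * g$m * sum(log(diag(R)))
        qyy <- qyy + sum(Z * Z)
        u <- u + sum(O * rowSums(Z))
        d <- d + g$m * sum(O * O)
    }
    list(ld = ld, qyy = qyy, u = u, d = d)
}

.vcLogLik <- function(ev, n, mu = NULL) {
    if (is.null(ev)) return(list(loglik = -Inf, mu = NA_real_))
    if (is.null(mu)) mu <- ev$u / ev$d
    quad <- ev$qyy - 2 * mu * ev$u + mu^2 * ev$d
    list(loglik = -0.5 * (n * log(2 * pi) + ev$ld + quad), mu = mu)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplusInv <- function(v) {
    v <- pmax(v, 1e-10)
    ifelse(v > 30, v, log(expm1(v)))
}

## ---- exported likelihood ---------------------------------------------------

#' Variance-components log-likelihood
#'
#' Multivariate-normal log density of `y` with mean `mu * 1` and covariance
#' \eqn{V_g A + V_c H + V_e I}, computed by Cholesky factorization. Returns
#' `-Inf` (with attribute `singular = TRUE`) rather than raising when the
#' covariance is not positive definite, so optimizers can step past bad
#' parameter values.
#'
#' @param y Numeric subject vector.
#' @param A,H Additive and household [RelationshipMatrix] objects (or plain
#'   matrices) in the same subject order as `y`.
#' @param vg,vc,ve Variance components.
#' @param mu Mean (default 0).
#' @return The log-likelihood (scalar).
#' @export
varCompLogLik <- function(y, A, H, vg, vc, ve, mu = 0) {
    A <- .relMat(A); H <- .relMat(H)
    n <- length(y)
    S <- vg * A + vc * H + ve * diag(n)
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) return(structure(-Inf, singular = TRUE))
    z <- backsolve(R, y - mu, transpose = TRUE)
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z * z))
}

## ---- fitting ---------------------------------------------------------------

.fitNullInternal <- function(y, veFloor = 1e-8) {
    n <- length(y)
    mu <- mean(y)
    s2 <- mean((y - mu)^2)
    degenerate <- s2 < veFloor
    ve <- max(s2, veFloor)
    ll <- -0.5 * n * (log(2 * pi * ve) + s2 / ve)
    new("VarCompFit", vg = 0, vc = 0, ve = ve, mu = mu, loglik = ll,
        converged = TRUE, degenerate = degenerate, model = "null",
        n = as.integer(n))
}

## Maximize the profiled (over mu) likelihood for one variance model.
## freeG/freeC: whether vg / vc are free; ve is always free.
.optimVC <- function(y, vcs, freeG, freeC, starts, veFloor, reltol) {
    n <- vcs$n
    nay <- function(th) {
        k <- 1L
        vg <- 0; vc <- 0
        if (freeG) { vg <- softplus(th[k]); k <- k + 1L }
        if (freeC) { vc <- softplus(th[k]); k <- k + 1L }
        ve <- softplus(th[k]) + veFloor
        ev <- .vcEval(y, vcs, vg, vc, ve)
        ll <- .vcLogLik(ev, n)$loglik
        if (!is.finite(ll)) 1e10 else -ll
    }
    best <- NULL
    for (st in starts) {
        o <- stats::optim(softplusInv(st), nay, method = "Nelder-Mead",
                          control = list(reltol = reltol, maxit = 1000))
        if (is.null(best) || o$value < best$value - 1e-12) best <- o
    }
    k <- 1L
    vg <- 0; vc <- 0
    if (freeG) { vg <- softplus(best$par[k]); k <- k + 1L }
    if (freeC) { vc <- softplus(best$par[k]); k <- k + 1L }
    ve <- softplus(best$par[k]) + veFloor
    prof <- .vcLogLik(.vcEval(y, vcs, vg, vc, ve), n)
    list(vg = vg, vc = vc, ve = ve, mu = prof$mu, loglik = prof$loglik,
         converged = best$convergence == 0L, npar = freeG + freeC)
}

.fitVC <- function(y, vcs, model, veFloor = 1e-8, reltol = 1e-9) {
    n <- vcs$n
    mu0 <- mean(y)
    s2 <- mean((y - mu0)^2)
    if (s2 < 1e-12)
        return(new("VarCompFit", vg = 0, vc = 0, ve = veFloor, mu = mu0,
                   loglik = .fitNullInternal(y, veFloor)@loglik,
                   converged = FALSE, degenerate = TRUE, model = model,
                   n = as.integer(n)))
    eps <- s2 * 1e-3
    cand <- list(E = .fitNullInternal(y, veFloor))
    if (model %in% c("full", "ae"))
        cand$AE <- .optimVC(y, vcs, TRUE, FALSE,
                            list(c(s2 / 2, s2 / 2), c(0.9 * s2, 0.1 * s2)),
                            veFloor, reltol)
    if (model %in% c("full", "ce"))
        cand$CE <- .optimVC(y, vcs, FALSE, TRUE,
                            list(c(s2 / 2, s2 / 2), c(0.9 * s2, 0.1 * s2)),
                            veFloor, reltol)
    if (model == "full")
        cand$FULL <- .optimVC(y, vcs, TRUE, TRUE,
                              list(c(s2, s2, s2) / 3,
                                   c(0.8 * s2, 0.1 * s2, 0.1 * s2),
                                   c(eps, eps, s2)),
                              veFloor, reltol)
    ll <- vapply(cand, function(f)
        if (is(f, "VarCompFit")) f@loglik else f$loglik, numeric(1))
    npar <- vapply(cand, function(f)
        if (is(f, "VarCompFit")) 0 else f$npar, numeric(1))
    ## prefer the simplest candidate whose likelihood ties the best within
    ## tolerance: this is what puts boundary estimates exactly at zero
    ok <- ll >= max(ll) - 1e-6
    pick <- names(cand)[ok][order(npar[ok], -ll[ok])][1]
    f <- cand[[pick]]
    if (is(f, "VarCompFit"))
        return(new("VarCompFit", vg = 0, vc = 0, ve = f@ve, mu = f@mu,
                   loglik = f@loglik, converged = TRUE, degenerate = FALSE,
                   model = model, n = as.integer(n)))
    new("VarCompFit", vg = f$vg, vc = f$vc, ve = f$ve, mu = f$mu,
        loglik = f$loglik, converged = isTRUE(f$converged),
        degenerate = FALSE, model = model, n = as.integer(n))
}

#' Fit a variance-components model to one feature
#'
#' Maximum-likelihood estimation of \eqn{(\mu, V_g, V_c, V_e)} for
#' \eqn{y \sim N(\mu 1, V_g A + V_c H + V_e I)} under nonnegativity. The
#' variances are optimized on a softplus scale from a fixed set of
#' deterministic starting points (equal split, genetic-heavy,
#' environment-only), the mean is profiled out analytically, and boundary
#' solutions are resolved exactly: nested submodels with one or both familial
#' components pinned at zero are fitted alongside, and the simplest model
#' whose likelihood ties the best within 1e-6 is returned, so null features
#' land exactly on \eqn{V_g = V_c = 0}. `ve` is floored at `veFloor` for
#' numerical stability.
#'
#' @param y Numeric subject vector (typically residualized feature values).
#' @param ped A [Pedigree] (preferred: supplies relationship matrices and
#'   family blocks). Alternatively pass `A` and `H` directly.
#' @param A,H Optional additive / household matrices overriding `ped`.
#' @param model `"full"` (Vg, Vc, Ve), `"ae"` (Vc = 0), `"ce"` (Vg = 0) or
#'   `"null"` (Vg = Vc = 0, closed form).
#' @param veFloor Lower bound for `ve` (default 1e-8).
#' @param reltol Optimizer relative tolerance.
#' @return A [VarCompFit].
#' @examples
#' ped <- simulatePedigree(seed = 1)
#' se <- simulateFeatures(ped, 1, vg = 0.6, vc = 0.2, ve = 0.2, seed = 5)
#' fitVarComp(SummarizedExperiment::assay(se)[1, ], ped)
#' @export
fitVarComp <- function(y, ped = NULL, A = NULL, H = NULL,
                       model = c("full", "ae", "ce", "null"),
                       veFloor = 1e-8, reltol = 1e-9) {
    model <- match.arg(model)
    y <- as.numeric(y)
    if (any(!is.finite(y))) stop("y contains non-finite values")
    if (model == "null") {
        if (length(y) < 2) stop("need at least 2 subjects")
        return(.fitNullInternal(y, veFloor))
    }
    fams <- NULL
    if (!is.null(ped)) {
        stopifnot(is(ped, "Pedigree"))
        if (is.null(A)) A <- relValues(additiveMatrix(ped))
        if (is.null(H)) H <- relValues(householdMatrix(ped))
        fams <- familyIds(ped)
    }
    if (is.null(A)) stop("supply ped or A")
    A <- .relMat(A)
    if (is.null(H)) H <- matrix(0, nrow(A), ncol(A))
    H <- .relMat(H)
    if (length(y) != nrow(A)) stop("length(y) must match relationship matrices")
    if (!is.null(fams) && length(unique(fams)) < 2 && model == "full")
        stop("need at least 2 families")
    vcs <- .vcStructure(A, H, fams)
    .fitVC(y, vcs, model, veFloor, reltol)
}

#' Familial-effect likelihood-ratio test
#'
#' Tests the joint null \eqn{V_g = V_c = 0} (no familial resemblance) by the
#' likelihood ratio between a full fit and the null fit on the same data. The
#' statistic is clamped at zero when numerically negative. The default
#' reference distribution is chi-square with 2 degrees of freedom, which is
#' conservative because both components sit on the boundary under the null;
#' `mixture = TRUE` uses the boundary-corrected mixture
#' \eqn{\tfrac14\chi^2_0 + \tfrac12\chi^2_1 + \tfrac14\chi^2_2}.
#'
#' @param full A [VarCompFit] with `model = "full"` (or `"ae"`, in which case
#'   df defaults to 1).
#' @param null The matching `"null"` [VarCompFit].
#' @param mixture Use the boundary mixture distribution (default `FALSE`).
#' @return Named list with `lrt`, `df`, `p`.
#' @export
familialTest <- function(full, null, mixture = FALSE) {
    stopifnot(is(full, "VarCompFit"), is(null, "VarCompFit"))
    if (full@n != null@n)
        stop("fits are not on the same subjects")
    lrt <- 2 * (full@loglik - null@loglik)
    if (lrt < -1e-6)
        warning(sprintf("likelihood ratio %.3g < 0: optimizer failure?", lrt))
    lrt <- max(lrt, 0)
    df <- if (full@model == "ae") 1L else 2L
    p <- if (mixture) {
        if (lrt <= 0) 1
        else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE) +
             0.25 * stats::pchisq(lrt, 2, lower.tail = FALSE)
    } else stats::pchisq(lrt, df, lower.tail = FALSE)
    list(lrt = lrt, df = df, p = p)
}

#' Heritability proportions from a variance-components fit
#'
#' Maximal heritability \eqn{h^2_{max} = (V_g + V_c)/(V_g + V_c + V_e)},
#' genetic heritability \eqn{h^2_g = V_g/(V_g + V_c + V_e)} and common
#' environmental effect \eqn{c^2 = V_c/(V_g + V_c + V_e)}; the identity
#' \eqn{h^2_{max} = h^2_g + c^2} holds to machine precision by construction.
#'
#' @param fit A [VarCompFit].
#' @param percent Return percentages instead of proportions.
#' @return Named numeric vector `h2_max`, `h2_g`, `c2`.
#' @export
setGeneric("heritability", function(fit, percent = FALSE)
    standardGeneric("heritability"))

#' @rdname heritability
#' @export
setMethod("heritability", "VarCompFit", function(fit, percent = FALSE) {
    tot <- fit@vg + fit@vc + fit@ve
    if (tot <= 0) stop("all variance components are zero")
    h2g <- fit@vg / tot
    c2 <- fit@vc / tot
    out <- c(h2_max = h2g + c2, h2_g = h2g, c2 = c2)
    if (percent) out * 100 else out
})

#' Genome-wide variance-components scan
#'
#' Fits the full and null models to every feature, tests the familial effect,
#' computes the three heritability proportions and Benjamini-Hochberg
#' FDR-adjusted p-values across features.
#'
#' @param se `SummarizedExperiment` (features x subjects, residualized
#'   `"values"` assay) or plain matrix with subject ids as column names in
#'   pedigree order.
#' @param ped A [Pedigree] covering the subjects.
#' @param mixture Passed to [familialTest()].
#' @param veFloor,reltol Passed to the fitter.
#' @param verbose Emit a progress message every 200 features.
#' @return A `S4Vectors::DataFrame` with one row per feature: `feature_id`,
#'   `vg`, `vc`, `ve`, `h2_max`, `h2_g`, `c2`, `lrt`, `df`, `p`, `p_fdr`,
#'   `converged`, `boundary_zero` (h2_max exactly 0), `boundary_one`
#'   (h2_max at 1 up to the `ve` floor). Features with non-finite values are
#'   skipped with a message. Use [scanSummary()] for the per-stratum
#'   mean/SD summary.
#' @examples
#' ped <- simulatePedigree(seed = 1)
#' se <- simulateFeatures(ped, 25, vg = 0.5, vc = 0.2, ve = 0.3, seed = 2)
#' scan <- genomeScan(se, ped)
#' scanSummary(scan)
#' @export
genomeScan <- function(se, ped, mixture = FALSE, veFloor = 1e-8,
                       reltol = 1e-9, verbose = FALSE) {
    X <- .featureValues(se)
    stopifnot(is(ped, "Pedigree"))
    ids <- subjectIds(ped)
    if (!is.null(colnames(X))) {
        if (!all(ids %in% colnames(X)))
            stop("feature matrix does not cover all pedigree subjects")
        X <- X[, ids, drop = FALSE]
    } else if (ncol(X) != length(ids))
        stop("subject count mismatch")
    A <- relValues(additiveMatrix(ped))
    H <- relValues(householdMatrix(ped))
    vcs <- .vcStructure(A, H, familyIds(ped))
    m <- nrow(X)
    fid <- rownames(X) %||% sprintf("feat_%05d", seq_len(m))
    rows <- vector("list", m)
    for (f in seq_len(m)) {
        y <- X[f, ]
        if (any(!is.finite(y))) {
            message("skipping feature with non-finite values: ", fid[f])
            next
        }
        full <- .fitVC(y, vcs, "full", veFloor, reltol)
        null <- .fitNullInternal(y, veFloor)
        ft <- familialTest(full, null, mixture = mixture)
        h <- heritability(full)
        rows[[f]] <- data.frame(
            feature_id = fid[f], vg = full@vg, vc = full@vc, ve = full@ve,
            h2_max = h[["h2_max"]], h2_g = h[["h2_g"]], c2 = h[["c2"]],
            lrt = ft$lrt, df = ft$df, p = ft$p,
            converged = full@converged,
            boundary_zero = h[["h2_max"]] == 0,
            boundary_one = h[["h2_max"]] >= 1 - 1e-6,
            stringsAsFactors = FALSE)
        if (verbose && f %% 200 == 0)
            message("scanned ", f, "/", m, " features")
    }
    out <- do.call(rbind, rows)
    out$p_fdr <- stats::p.adjust(out$p, method = "BH")
    out <- out[, c("feature_id", "vg", "vc", "ve", "h2_max", "h2_g", "c2",
                   "lrt", "df", "p", "p_fdr", "converged",
                   "boundary_zero", "boundary_one")]
    S4Vectors::DataFrame(out)
}

#' Summarize a genome scan by significance stratum
#'
#' Mean and SD (in percent) of the three heritability estimates over all
#' features, features with familial-test p <= `alpha`, and features with
#' FDR-adjusted p <= `alpha`, plus counts of features at the boundary
#' estimates 0% and 100%.
#'
#' @param scan Result of [genomeScan()].
#' @param alpha Significance level (default 0.05).
#' @return A `data.frame` with one row per stratum.
#' @export
scanSummary <- function(scan, alpha = 0.05) {
    scan <- as.data.frame(scan)
    strata <- list(all = rep(TRUE, nrow(scan)),
                   significant = scan$p <= alpha,
                   fdr_significant = scan$p_fdr <= alpha)
    do.call(rbind, lapply(names(strata), function(s) {
        d <- scan[strata[[s]], , drop = FALSE]
        data.frame(stratum = s, n = nrow(d),
                   h2_max_mean = 100 * mean(d$h2_max),
                   h2_max_sd = 100 * stats::sd(d$h2_max),
                   h2_g_mean = 100 * mean(d$h2_g),
                   h2_g_sd = 100 * stats::sd(d$h2_g),
                   c2_mean = 100 * mean(d$c2),
                   c2_sd = 100 * stats::sd(d$c2),
                   n_boundary_zero = sum(d$boundary_zero),
                   n_boundary_one = sum(d$boundary_one))
    }))
}
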