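## Bivariate variance-components model: for each family block the 2k x 2k
## covariance is kron(Cg, A_f) + kron(Cc, H_f) + kron(Ce, I_k) with
## Cx = [[vx1, rx*sqrt(vx1*vx2)], [., vx2]]. Means are profiled by GLS on the
## two-column trait-indicator design. Correlations are optimized on an atanh
## scale and pinned to |rho| <= 1 - 1e-6 so the covariance stays PSD.

.RHO_MAX <- 1 - 1e-6

## Precomputes all parameter-independent per-group pieces (stacked data,
## design, identity) and returns an evaluator of the profiled log-likelihood.
.bivClosure <- function(y1, y2, vcs) {
    pre <- lapply(vcs$groups, function(g) {
        k <- g$k
        list(A = g$A, H = g$H, Ik = diag(k), k = k, m = g$m,
             i1 = seq_len(k), i2 = k + seq_len(k),
             Yb = rbind(matrix(y1[g$idx], nrow = k),
                        matrix(y2[g$idx], nrow = k)),
             Xb = cbind(rep(c(1, 0), each = k), rep(c(0, 1), each = k)),
             S = matrix(0, 2 * k, 2 * k))
    })
    n2 <- 2 * vcs$n
    function(v, rho) {
        cg <- rho[1] * sqrt(v[1] * v[4])
        cc <- rho[2] * sqrt(v[2] * v[5])
        ce <- rho[3] * sqrt(v[3] * v[6])
        ld <- 0; qyy <- 0
        XtSiX <- matrix(0, 2, 2); XtSiy <- numeric(2)
        out <- tryCatch({
            for (g in pre) {
                S <- g$S
                S[g$i1, g$i1] <- v[1] * g$A + v[2] * g$H + v[3] * g$Ik
                S[g$i2, g$i2] <- v[4] * g$A + v[5] * g$H + v[6] * g$Ik
                cross <- cg * g$A + cc * g$H + ce * g$Ik
                S[g$i1, g$i2] <- cross
                S[g$i2, g$i1] <- cross
                R <- chol(S)
                Z <- backsolve(R, g$Yb, transpose = TRUE)
                W <- backsolve(R, g$Xb, transpose = TRUE)
                ld <- ld + 2 * g$m * sum(log(diag(R)))
                qyy <- qyy + sum(Z * Z)
                XtSiX <- XtSiX + g$m * crossprod(W)
                XtSiy <- XtSiy + crossprod(W, rowSums(Z))
            }
            mu <- solve(XtSiX, XtSiy)
            quad <- qyy - 2 * sum(mu * XtSiy) +
                drop(t(mu) %*% XtSiX %*% mu)
            list(loglik = -0.5 * (n2 * log(2 * pi) + ld + quad),
                 mu = drop(mu))
        }, error = function(e) NULL)
        out
    }
}

.bivOptim <- function(evalFn, freeRhoG, starts, veFloor, reltol) {
    nay <- function(th) {
        v <- softplus(th[1:6]) + c(0, 0, veFloor, 0, 0, veFloor)
        rho <- if (freeRhoG) tanh(th[7:9]) else c(0, tanh(th[7:8]))
        rho <- pmax(pmin(rho, .RHO_MAX), -.RHO_MAX)
        ev <- evalFn(v, rho)
        if (is.null(ev) || !is.finite(ev$loglik)) 1e10 else -ev$loglik
    }
    best <- NULL
    for (st in starts) {
        o <- stats::optim(st, nay, method = "Nelder-Mead",
                          control = list(reltol = reltol, maxit = 5000))
        if (is.null(best) || o$value < best$value - 1e-12) best <- o
    }
    th <- best$par
    v <- softplus(th[1:6]) + c(0, 0, veFloor, 0, 0, veFloor)
    rho <- if (freeRhoG) tanh(th[7:9]) else c(0, tanh(th[7:8]))
    rho <- pmax(pmin(rho, .RHO_MAX), -.RHO_MAX)
    ev <- evalFn(v, rho)
    list(v = v, rho = rho, loglik = ev$loglik,
         converged = best$convergence == 0L)
}

#' Bivariate genetic correlation between two features
#'
#' Fits the two-trait variance-components model by maximum likelihood and
#' estimates the genetic (\eqn{\rho_g}), common-environment (\eqn{\rho_c})
#' and unique-environment (\eqn{\rho_e}) correlations. \eqn{\rho_g = 0} is
#' tested by likelihood ratio with one degree of freedom. Starting values are
#' deterministic: univariate fits of each trait seed the variance components,
#' and the phenotypic correlation (plus a zero start) seeds the correlations.
#'
#' When either trait shows essentially no familial variance
#' (\eqn{(V_g + V_c)/(V_g+V_c+V_e)} below `minFamilial` in its univariate
#' fit), the genetic correlation is not identifiable: the fit is returned
#' with `rhoG = NA` and a machine-readable `reason`, not an error.
#'
#' @param y1,y2 Residualized subject vectors on the same subjects.
#' @param ped A [Pedigree] (or supply `A` and `H`).
#' @param A,H Optional relationship matrices overriding `ped`.
#' @param veFloor Floor on the unique-environment variances.
#' @param reltol Optimizer tolerance.
#' @param minFamilial Minimal univariate familial-variance share for
#'   \eqn{\rho_g} to be considered identifiable (default 1e-4).
#' @return A [BivariateFit].
#' @examples
#' ped <- simulatePedigree(seed = 1)
#' sim <- simulateBivariate(ped, 1, vg1 = 0.6, vc1 = 0.2, ve1 = 0.2,
#'                          rhoG = 0.9, seed = 3)
#' \donttest{geneticCorrelation(sim$trait1[1, ], sim$trait2[1, ], ped)}
#' @export
geneticCorrelation <- function(y1, y2, ped = NULL, A = NULL, H = NULL,
                               veFloor = 1e-8, reltol = 1e-8,
                               minFamilial = 1e-4) {
    y1 <- as.numeric(y1); y2 <- as.numeric(y2)
    if (length(y1) != length(y2)) stop("traits measured on different subjects")
    fams <- NULL
    if (!is.null(ped)) {
        stopifnot(is(ped, "Pedigree"))
        if (is.null(A)) A <- relValues(additiveMatrix(ped))
        if (is.null(H)) H <- relValues(householdMatrix(ped))
        fams <- familyIds(ped)
    }
    A <- .relMat(A); H <- .relMat(H)
    vcs <- .vcStructure(A, H, fams)
    f1 <- .fitVC(y1, vcs, "full", veFloor, reltol)
    f2 <- .fitVC(y2, vcs, "full", veFloor, reltol)
    fam1 <- (f1@vg + f1@vc) / (f1@vg + f1@vc + f1@ve)
    fam2 <- (f2@vg + f2@vc) / (f2@vg + f2@vc + f2@ve)
    mkFit <- function(v, rho, loglik, lrt, p, conv, reason)
        new("BivariateFit", vg1 = v[1], vc1 = v[2], ve1 = v[3],
            vg2 = v[4], vc2 = v[5], ve2 = v[6],
            rhoG = rho[1], rhoC = rho[2], rhoE = rho[3],
            loglik = loglik, lrt = lrt, p = p, converged = conv,
            reason = reason)
    if (fam1 < minFamilial || fam2 < minFamilial)
        return(mkFit(c(f1@vg, f1@vc, f1@ve, f2@vg, f2@vc, f2@ve),
                     c(NA_real_, NA_real_, NA_real_),
                     NA_real_, NA_real_, NA_real_, FALSE,
                     "no familial variance in at least one trait"))
    r0 <- suppressWarnings(stats::cor(y1, y2))
    if (!is.finite(r0)) r0 <- 0
    r0 <- max(min(r0, 0.95), -0.95)
    vst <- pmax(c(f1@vg, f1@vc, f1@ve, f2@vg, f2@vc, f2@ve), 1e-4)
    thv <- softplusInv(vst)
    evalFn <- .bivClosure(y1, y2, vcs)
    starts <- list(c(thv, atanh(rep(r0, 3))),
                   c(thv, rep(0, 3)))
    free <- .bivOptim(evalFn, TRUE, starts, veFloor, reltol)
    ## constrained fit starts from the free optimum with rhoG removed
    starts0 <- list(c(softplusInv(pmax(free$v - c(0, 0, veFloor, 0, 0, veFloor),
                                       1e-6)),
                      atanh(free$rho[2:3])),
                    c(thv, rep(0, 2)))
    null <- .bivOptim(evalFn, FALSE, starts0, veFloor, reltol)
    lrt <- max(2 * (free$loglik - null$loglik), 0)
    p <- stats::pchisq(lrt, 1, lower.tail = FALSE)
    conv <- free$converged && null$converged && is.finite(free$loglik)
    mkFit(free$v, free$rho, free$loglik, lrt, p, conv,
          if (conv) "" else "optimizer did not converge")
}
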