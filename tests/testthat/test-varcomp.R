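test_that("the blockwise likelihood matches a dense MVN oracle", {
    set.seed(7)
    maxDiff <- 0
    for (rep in 1:20) {
        n <- sample(5:12, 1)
        ped <- randomPedigree(n, seed = 200 + rep)
        A <- relValues(additiveMatrix(ped))
        H <- relValues(householdMatrix(ped))
        y <- rnorm(n)
        for (k in 1:5) {
            vg <- runif(1, 0, 2); vc <- runif(1, 0, 2)
            ve <- runif(1, 0.05, 2); mu <- rnorm(1)
            S <- vg * A + vc * H + ve * diag(n)
            ll <- varCompLogLik(y, A, H, vg, vc, ve, mu = mu)
            oracle <- denseMvnLogLik(y, S, mu)
            maxDiff <- max(maxDiff, abs(ll - oracle))
        }
    }
    expect_lt(maxDiff, 1e-8)
})

test_that("the likelihood obeys closed forms and scaling laws", {
    ped <- simulatePedigree(seed = 1)
    A <- additiveMatrix(ped); H <- householdMatrix(ped)
    set.seed(3)
    y <- rnorm(48)
    ## vg=vc=0, ve=1, mu=0: sum of standard-normal log densities
    expect_equal(varCompLogLik(y, A, H, 0, 0, 1, mu = 0),
                 sum(dnorm(y, log = TRUE)), tolerance = 1e-10)
    ## scaling y and variance components: loglik shifts by -n*log(c)
    cc <- 2.7
    ll1 <- varCompLogLik(y, A, H, 0.5, 0.3, 0.2, mu = 0)
    ll2 <- varCompLogLik(cc * y, A, H, cc^2 * 0.5, cc^2 * 0.3, cc^2 * 0.2,
                         mu = 0)
    expect_equal(ll2, ll1 - 48 * log(cc), tolerance = 1e-8)
    ## singular covariance: -Inf with a flag, no exception
    llSing <- varCompLogLik(y, A, H, 0, 0, 0)
    expect_true(is.infinite(llSing) && llSing < 0)
    expect_true(isTRUE(attr(llSing, "singular")))
})

test_that("the null fit is the closed-form ML Gaussian fit", {
    y <- c(0, 0, 2, 2)
    f <- fitVarComp(y, model = "null")
    expect_equal(f@mu, 1)
    expect_equal(f@ve, 1)             # ML variance, divisor n
    expect_equal(f@loglik, sum(dnorm(y, 1, 1, log = TRUE)))
    ## consistency at large n
    set.seed(5)
    big <- fitVarComp(rnorm(1e4), model = "null")
    expect_lt(abs(big@ve - 1), 0.05)
    ## zero variance is floored and flagged
    flat <- fitVarComp(rep(3, 10), model = "null")
    expect_true(flat@degenerate)
    expect_equal(flat@ve, 1e-8)
})

test_that("full fits nest the null and land exactly on boundaries for noise", {
    ped <- simulatePedigree(seed = 1)
    se <- simulateFeatures(ped, 120, vg = 0, vc = 0, ve = 1, seed = 21)
    X <- SummarizedExperiment::assay(se)
    scan <- genomeScan(se, ped)
    expect_true(all(scan$lrt >= 0))
    ## under a true null, a large fraction of h2_max estimates sit exactly at 0
    expect_gt(mean(scan$h2_max == 0), 0.10)
    ## heritability identity at machine precision
    expect_lt(max(abs(scan$h2_max - (scan$h2_g + scan$c2))), 1e-10)
    ## LRT invariant to affine transformation of y
    y <- X[1, ]
    f1 <- fitVarComp(y, ped); n1 <- fitVarComp(y, model = "null")
    f2 <- fitVarComp(5 * y + 11, ped)
    n2 <- fitVarComp(5 * y + 11, model = "null")
    lrt1 <- familialTest(f1, n1)$lrt
    lrt2 <- familialTest(f2, n2)$lrt
    expect_equal(lrt1, lrt2, tolerance = 1e-4)
})

test_that("heritability proportions follow their defining ratios", {
    f <- new("VarCompFit", vg = 0.6, vc = 0.18, ve = 0.22, mu = 0,
             loglik = -1, converged = TRUE, degenerate = FALSE,
             model = "full", n = 48L)
    h <- heritability(f)
    expect_equal(unname(h), c(0.78, 0.60, 0.18))
    ## vg=vc=0 -> h2_max 0
    f0 <- new("VarCompFit", vg = 0, vc = 0, ve = 1, mu = 0, loglik = -1,
              converged = TRUE, degenerate = FALSE, model = "null", n = 4L)
    expect_equal(unname(heritability(f0))[1], 0)
    ## percent scale and the additive identity on printed-style shares
    fT <- new("VarCompFit", vg = 26.04, vc = 57.60, ve = 16.36, mu = 0,
              loglik = -1, converged = TRUE, degenerate = FALSE,
              model = "full", n = 48L)
    hp <- heritability(fT, percent = TRUE)
    expect_equal(unname(hp[["h2_max"]]), 83.64, tolerance = 1e-12)
})

test_that("familialTest clamps, defaults to df=2 and supports the mixture", {
    ped <- simulatePedigree(seed = 1)
    se <- simulateFeatures(ped, 1, vg = 0, vc = 0, ve = 1, seed = 31)
    y <- SummarizedExperiment::assay(se)[1, ]
    full <- fitVarComp(y, ped)
    null <- fitVarComp(y, model = "null")
    ft <- familialTest(full, null)
    expect_gte(ft$lrt, 0)
    expect_equal(ft$df, 2L)
    if (ft$lrt == 0) expect_equal(ft$p, 1)
    ftm <- familialTest(full, null, mixture = TRUE)
    expect_lte(ftm$p, ft$p + 1e-12)   # mixture is less conservative
    expect_error(familialTest(full, fitVarComp(rnorm(10), model = "null")),
                 "same subjects")
})

test_that("variance components are recovered and power grows with vg", {
    ped <- studyLikePedigree(60, seed = 2)
    se <- simulateFeatures(ped, 60, vg = 0.4, vc = 0.2, ve = 0.4, seed = 41)
    scan <- genomeScan(se, ped)
    expect_lt(abs(mean(scan$vg) - 0.4), 0.08)
    expect_lt(abs(mean(scan$vc) - 0.2), 0.08)
    expect_lt(abs(mean(scan$ve) - 0.4), 0.08)
    ## power at vg = 0.6 exceeds power at vg = 0.2 (study-like 16 families)
    ped16 <- simulatePedigree(seed = 1)
    hi <- genomeScan(simulateFeatures(ped16, 80, vg = 0.6, vc = 0, ve = 0.4,
                                      seed = 42), ped16)
    lo <- genomeScan(simulateFeatures(ped16, 80, vg = 0.2, vc = 0, ve = 0.8,
                                      seed = 43), ped16)
    expect_gt(mean(hi$p <= 0.05), mean(lo$p <= 0.05))
})

test_that("AE fits agree with the full model when vc=0 and absorb vc otherwise", {
    ## vc = 0 truth: the AE fit recovers vg, and the full model's familial
    ## variance (vg + vc) agrees with it -- the vg/vc split itself is only
    ## weakly identified because A and H are collinear within small families
    pedBig <- studyLikePedigree(50, seed = 4)
    se0 <- simulateFeatures(pedBig, 50, vg = 0.5, vc = 0, ve = 0.5, seed = 51)
    X0 <- SummarizedExperiment::assay(se0)
    famFull <- vgAE <- numeric(50)
    for (i in 1:50) {
        ff <- fitVarComp(X0[i, ], pedBig)
        famFull[i] <- ff@vg + ff@vc
        vgAE[i] <- fitVarComp(X0[i, ], pedBig, model = "ae")@vg
    }
    expect_lt(abs(mean(vgAE) - 0.5), 0.08)
    expect_lt(abs(mean(famFull) - mean(vgAE)), 0.08)
    ## vc > 0 truth: AE inflates vg relative to the full model
    ped <- simulatePedigree(seed = 1)
    se1 <- simulateFeatures(ped, 80, vg = 0.3, vc = 0.4, ve = 0.3, seed = 52)
    X1 <- SummarizedExperiment::assay(se1)
    d <- vapply(seq_len(80), function(i)
        fitVarComp(X1[i, ], ped, model = "ae")@vg -
        fitVarComp(X1[i, ], ped)@vg, numeric(1))
    expect_gt(mean(d), 0)
    ## degenerate zero-variance input
    flat <- fitVarComp(rep(2, 48), ped)
    expect_true(flat@degenerate)
})

test_that("BH adjustment in the scan matches the step-up definition", {
    ## brute-force BH on the worked sequence
    p <- c(0.01, 0.02, 0.03, 0.04, 0.2)
    m <- length(p)
    ord <- order(p)
    manual <- rev(cummin(rev(p[ord] * m / seq_len(m))))[order(ord)]
    expect_equal(p.adjust(p, "BH"), pmin(manual, 1))
    expect_equal(p.adjust(p, "BH"), c(0.05, 0.05, 0.05, 0.05, 0.2))
    ## scans expose BH-adjusted p and significant features are enriched
    ped <- simulatePedigree(seed = 1)
    mixse <- rbind(
        SummarizedExperiment::assay(
            simulateFeatures(ped, 25, vg = 0.7, vc = 0.2, ve = 0.1,
                             seed = 61)),
        SummarizedExperiment::assay(
            simulateFeatures(ped, 75, vg = 0, vc = 0, ve = 1, seed = 62)))
    rownames(mixse) <- sprintf("f%03d", seq_len(nrow(mixse)))
    scan <- genomeScan(mixse, ped)
    expect_equal(scan$p_fdr, p.adjust(scan$p, "BH"))
    sm <- scanSummary(scan)
    expect_gt(sm$h2_max_mean[sm$stratum == "significant"],
              sm$h2_max_mean[sm$stratum == "all"])
})
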