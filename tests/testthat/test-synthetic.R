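test_that("simulatePedigree presets are deterministic and study-shaped", {
    p1 <- simulatePedigree(seed = 5)
    p2 <- simulatePedigree(seed = 5)
    expect_identical(pedData(p1), pedData(p2))
    d <- pedData(p1)
    expect_equal(nrow(d), 48L)
    founders <- is.na(d$mother_id) & is.na(d$father_id)
    expect_equal(sum(founders & d$sex == "female"), 16L)   # mothers
    expect_equal(sum(founders & d$sex == "male"), 6L)      # fathers
    expect_equal(sum(!founders), 26L)                      # children
    ## single family, 2 parents + 2 children -> one sibling pair
    p3 <- simulatePedigree(nFamilies = 1, childCounts = 2L,
                           fatherFamilies = 1L, preset = "custom", seed = 1)
    expect_equal(length(p3), 4L)
    cnt <- attr(classifyPairs(p3), "counts")
    expect_equal(unname(cnt[["sibling"]]), 1L)
    expect_error(simulatePedigree(nFamilies = 2, childCounts = 1L,
                                  preset = "custom"),
                 "childCounts")
})

test_that("simulated features reproduce the implied pair correlations", {
    ped <- simulatePedigree(seed = 1)
    pc <- classifyPairs(ped)
    sib <- pc[pc$class == "sibling", ]
    fam <- familyIds(ped)

    ## pure noise: sibling correlation ~ 0
    se0 <- simulateFeatures(ped, 2000, vg = 0, vc = 0, ve = 1, seed = 2)
    X0 <- SummarizedExperiment::assay(se0)
    r0 <- mean(vapply(seq_len(nrow(sib)), function(k)
        cor(X0[, sib$id1[k]], X0[, sib$id2[k]]), numeric(1)))
    expect_lt(abs(r0), 0.05)

    ## vg=1 on a fully-fathered pedigree (all siblings full sibs, A = 0.5):
    ## sibling correlation = vg*A_ij/(vg+vc+ve) = 0.5 over 2000 features
    pedF <- simulatePedigree(nFamilies = 8, childCounts = rep(2L, 8),
                             fatherFamilies = 1:8, preset = "custom",
                             seed = 9)
    sibF <- subset(classifyPairs(pedF), class == "sibling")
    se1 <- simulateFeatures(pedF, 2000, vg = 1, vc = 0, ve = 0, seed = 3)
    X1 <- SummarizedExperiment::assay(se1)
    r1 <- mean(vapply(seq_len(nrow(sibF)), function(k)
        cor(X1[, sibF$id1[k]], X1[, sibF$id2[k]]), numeric(1)))
    expect_lt(abs(r1 - 0.5), 0.05)
    ## in the study preset, mother-only families yield half-sib kinship 0.25
    A <- relValues(additiveMatrix(ped))
    expect_equal(A["F01_C1", "F01_C2"], 0.5)   # father enrolled
    expect_equal(A["F03_C1", "F03_C2"], 0.25)  # father absent

    ## vc=1, vg=ve=0: all members of a family share one draw
    se2 <- simulateFeatures(ped, 50, vg = 0, vc = 1, ve = 0, seed = 4)
    X2 <- SummarizedExperiment::assay(se2)
    sameFam <- which(fam == fam[1])
    expect_lt(max(abs(X2[, sameFam] - X2[, sameFam[1]])), 1e-6)
})

test_that("empirical feature covariance converges to vg*A + vc*H + ve*I", {
    ped <- simulatePedigree(seed = 1)
    A <- relValues(additiveMatrix(ped))
    H <- relValues(householdMatrix(ped))
    target <- 0.5 * A + 0.2 * H + 0.3 * diag(48)
    frob <- vapply(c(200, 1600, 12800), function(m) {
        se <- simulateFeatures(ped, m, vg = 0.5, vc = 0.2, ve = 0.3,
                               seed = 99)
        X <- t(SummarizedExperiment::assay(se))   # subjects x features
        emp <- tcrossprod(X - rowMeans(X)) / (m - 1)
        sqrt(sum((emp - target)^2))
    }, numeric(1))
    expect_true(all(diff(frob) < 0))
})

test_that("bivariate simulation honours the cross-trait closed form", {
    ped <- simulatePedigree(seed = 1)
    ## perfect correlation of identical components: trait2 == trait1
    s1 <- simulateBivariate(ped, 5, vg1 = 0.5, vc1 = 0.3, ve1 = 0.2,
                            rhoG = 1, rhoC = 1, rhoE = 1, seed = 2)
    expect_lt(max(abs(s1$trait1 - s1$trait2)), 1e-6)
    ## independent components: cross-correlation ~ 0
    s0 <- simulateBivariate(ped, 3000, vg1 = 0.5, vc1 = 0, ve1 = 0.5,
                            rhoG = 0, rhoE = 0, seed = 3)
    r0 <- mean(vapply(seq_len(48), function(i)
        cor(s0$trait1[, i], s0$trait2[, i]), numeric(1)))
    expect_lt(abs(r0), 0.05)
    ## rhoG=0.9, rhoC=rhoE=0, components (0.6,0.2,0.2):
    ## within-subject cross-trait correlation = 0.9*0.6 = 0.54
    s2 <- simulateBivariate(ped, 3000, vg1 = 0.6, vc1 = 0.2, ve1 = 0.2,
                            rhoG = 0.9, seed = 4)
    r2 <- mean(vapply(seq_len(48), function(i)
        cor(s2$trait1[, i], s2$trait2[, i]), numeric(1)))
    expect_lt(abs(r2 - 0.54), 0.05)
    expect_error(simulateBivariate(ped, 2, vg1 = 1, vc1 = 0, ve1 = 0,
                                   rhoG = 2),
                 "rhoG")
})

test_that("cell mixtures are exact linear combinations with simplex proportions", {
    sig <- makeCellSignature(nFeatures = 40, nTypes = 2, seed = 1)
    ## fixed proportions, zero noise
    mix <- simulateMixture(sig, nSubjects = 6, noiseSd = 0, seed = 2)
    expect_equal(rowSums(mix$proportions), rep(1, 6), tolerance = 1e-12,
                 ignore_attr = TRUE)
    recon <- sig %*% t(mix$proportions)
    expect_lt(max(abs(recon - mix$values)), 1e-10)
    ## all mass on one type: profile equals that signature column
    oneType <- matrix(c(1, 0), 1, 2)
    v <- sig %*% t(oneType)
    expect_equal(unname(drop(v)), unname(sig[, 1]))
    ## rank-deficient signature rejected
    bad <- cbind(sig[, 1], sig[, 1])
    expect_error(simulateMixture(bad, nSubjects = 2), "rank deficient")
})

test_that("synthetic detection p-values encode the designated detected set", {
    ped <- simulatePedigree(seed = 1)
    se <- simulateFeatures(ped, 1000, vg = 0, vc = 0, ve = 1, seed = 5)
    ## fraction 1: everything passes the filter
    seAll <- simulateDetection(se, detectedFraction = 1, seed = 6)
    keptAll <- detectionFilter(seAll, verbose = FALSE)
    expect_equal(nrow(keptAll), 1000L)
    ## 38% designated detected: filter recovers exactly the designated set
    se38 <- simulateDetection(se, detectedFraction = 0.38, seed = 7)
    truth <- S4Vectors::metadata(se38)$detected
    kept <- detectionFilter(se38, verbose = FALSE)
    expect_identical(sort(rownames(kept)), sort(rownames(se38)[truth]))
    ## a feature undetected in every subject fails the 25% rule
    P <- SummarizedExperiment::assay(se38, "detection")
    allHigh <- which(rowSums(P <= 0.05) == 0)
    expect_true(length(allHigh) > 0)
    expect_false(any(rownames(se38)[allHigh] %in% rownames(kept)))
})

test_that("simulation is reproducible under a fixed seed", {
    ped <- simulatePedigree(seed = 3)
    a <- simulateFeatures(ped, 20, vg = 0.4, vc = 0.1, ve = 0.5, seed = 11)
    b <- simulateFeatures(ped, 20, vg = 0.4, vc = 0.1, ve = 0.5, seed = 11)
    expect_identical(SummarizedExperiment::assay(a),
                     SummarizedExperiment::assay(b))
    m1 <- simulateMixture(makeCellSignature(seed = 2), nSubjects = 4,
                          seed = 12)
    m2 <- simulateMixture(makeCellSignature(seed = 2), nSubjects = 4,
                          seed = 12)
    expect_identical(m1, m2)
})
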