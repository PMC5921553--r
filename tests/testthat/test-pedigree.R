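test_that("readPedigree parses PED-dialect files and validates structure", {
    f <- tempfile()
    writeLines(c("f1 mom 0 0 2 40", "f1 dad 0 0 1 44",
                 "f1 kid dad mom 2 11"), f)
    ped <- readPedigree(f)
    expect_s4_class(ped, "Pedigree")
    expect_equal(length(ped), 3L)
    d <- pedData(ped)
    expect_equal(d$mother_id[3], "mom")
    expect_equal(d$father_id[3], "dad")
    expect_true(is.na(d$mother_id[1]))

    writeLines(c("f1 mom 0 0 2 40", "f1 kid ghost mom 1 9"), f)
    expect_error(readPedigree(f), "dangling.*ghost")

    writeLines(c("f1 mom 0 0 2 40", "f1 mom 0 0 2 41"), f)
    expect_error(readPedigree(f), "duplicate.*mom")

    writeLines(c("f1 a b 0 2 40", "f1 b 0 a 1 40"), f)
    expect_error(readPedigree(f), "cycle")
})

test_that("a study-shaped pedigree file round-trips with 48 subjects, 16 families", {
    ped <- simulatePedigree(seed = 3)
    f <- tempfile()
    d <- pedData(ped)
    write.table(
        data.frame(d$family_id, d$id,
                   ifelse(is.na(d$father_id), "0", d$father_id),
                   ifelse(is.na(d$mother_id), "0", d$mother_id),
                   ifelse(d$sex == "male", 1, 2), d$age),
        f, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    ped2 <- readPedigree(f)
    expect_equal(length(ped2), 48L)
    expect_equal(length(unique(familyIds(ped2))), 16L)
    expect_equal(pedData(ped2)$id, d$id)
})

test_that("additive matrix gives textbook values on defined relationships", {
    ped <- Pedigree(data.frame(
        id = c("gm", "gf", "mom", "aunt", "dad", "unc", "kid1", "kid2",
               "cous"),
        family_id = "f1",
        father_id = c(NA, NA, "gf", "gf", NA, NA, "dad", "dad", "unc"),
        mother_id = c(NA, NA, "gm", "gm", NA, NA, "mom", "mom", "aunt"),
        sex = c("female", "male", "female", "female", "male", "male",
                "male", "female", "male"),
        age = c(70, 72, 40, 38, 41, 43, 10, 12, 9)))
    A <- relValues(additiveMatrix(ped))
    expect_equal(A["mom", "kid1"], 0.5)       # parent-offspring
    expect_equal(A["kid1", "kid2"], 0.5)      # full siblings
    expect_equal(A["gm", "gm"], 1.0)          # non-inbred founder
    expect_equal(A["gm", "kid1"], 0.25)       # grandparent-grandchild
    expect_equal(A["kid1", "cous"], 0.125)    # first cousins
    expect_equal(A["mom", "aunt"], 0.5)       # full sibs in parent generation
    expect_equal(A["mom", "cous"], 0.25)      # aunt-nephew (avuncular)
    expect_equal(A["gm", "dad"], 0)           # unrelated founders
})

test_that("recursive kinship matches the gene-dropping oracle", {
    ## 3-generation toy pedigree: grandparent-grandchild and half-sibs at 0.25
    ped <- Pedigree(data.frame(
        id = c("gm", "gf", "m1", "m3", "d1", "c1", "c2"),
        family_id = "f1",
        father_id = c(NA, NA, "gf", NA, NA, "d1", "d1"),
        mother_id = c(NA, NA, "gm", NA, NA, "m1", "m3"),
        sex = c("female", "male", "female", "female", "male", "male", "male"),
        age = c(70, 71, 40, 41, 42, 9, 8)))
    A <- relValues(additiveMatrix(ped))
    expect_equal(A["gm", "c1"], 0.25)
    expect_equal(A["c1", "c2"], 0.25)         # half sibs (shared father only)
    K <- geneDropKinship(ped, nDrops = 1e5, seed = 11)
    expect_lt(max(abs(2 * K - A)), 0.02)
})

test_that("kinship equals the gene-dropping oracle on random pedigrees (<=10)", {
    for (seed in 1:5) {
        n <- sample(4:10, 1)
        ped <- randomPedigree(n, seed = 100 + seed)
        A <- relValues(additiveMatrix(ped))
        K <- geneDropKinship(ped, nDrops = 4e4, seed = seed)
        expect_lt(max(abs(2 * K - A)), 0.035)
        ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
        expect_gte(min(ev), -1e-8)
    }
})

test_that("household matrix is the block indicator of shared family", {
    ped <- simulatePedigree(seed = 2)
    H <- relValues(householdMatrix(ped))
    fam <- familyIds(ped)
    expect_true(all(H %in% c(0, 1)))
    expect_equal(unname(diag(H)), rep(1, 48))
    expect_equal(H["F01_M", "F01_C1"], 1)
    expect_equal(H["F01_M", "F02_M"], 0)
    ## block-diagonal with 16 blocks
    expect_equal(sum(H), sum(table(fam)^2))
})

test_that("relationship matrices round-trip through labelled TSV", {
    ped <- simulatePedigree(seed = 4)
    A <- additiveMatrix(ped)
    f <- tempfile(fileext = ".tsv")
    writeRelationshipMatrix(A, f)
    back <- as.matrix(read.table(f, header = TRUE, sep = "\t",
                                 row.names = 1, check.names = FALSE))
    expect_equal(back, relValues(A), tolerance = 1e-12)
    expect_identical(rownames(back), subjectIds(ped))
})

test_that("classifyPairs partitions all pairs with study-shaped counts", {
    ped <- simulatePedigree(seed = 1)
    pc <- classifyPairs(ped)
    expect_equal(nrow(pc), 48 * 47 / 2)       # 1128 unordered pairs
    cnt <- attr(pc, "counts")
    expect_equal(unname(cnt[["mother-offspring"]]), 26L)
    expect_equal(unname(cnt[["sibling"]]), 13L)
    expect_equal(unname(cnt[["mother-offspring"]] + cnt[["father-offspring"]]),
                 37L)
    expect_equal(unname(cnt[["spouse"]]), 6L)
    ## spouses pool into unrelated for Table-1-style summaries: 1128-13-37
    expect_equal(unname(cnt[["unrelated"]] + cnt[["spouse"]]), 1078L)
    expect_equal(sum(cnt), nrow(pc))

    toy <- Pedigree(data.frame(
        id = c("mom", "kid"), family_id = "f", father_id = NA,
        mother_id = c(NA, "mom"), sex = c("female", "male"), age = c(40, 9)))
    expect_equal(classifyPairs(toy)$class, "mother-offspring")
})

test_that("null pair correlations follow the folded-normal closed form", {
    ped <- simulatePedigree(seed = 1)
    pc <- classifyPairs(ped)
    se <- simulateFeatures(ped, 1500, vg = 0, vc = 0, ve = 1, seed = 42)
    pr <- pairCorrelations(SummarizedExperiment::assay(se), pc)
    unrel <- pr[pr$class == "unrelated", ]
    expect_equal(unrel$n_pairs, 1078L)
    expected <- sqrt(2 / (pi * (unrel$n_pairs - 1)))
    expect_lt(abs(unrel$mean_abs_r - expected) / expected, 0.2)
    ## permutation-style check at a second class size: mother-offspring (26)
    mo <- pr[pr$class == "mother-offspring", ]
    expect_lt(abs(mo$mean_abs_r - sqrt(2 / (pi * 25))) / sqrt(2 / (pi * 25)),
              0.2)
})

test_that("heritable features raise related-pair correlations above unrelated", {
    ped <- simulatePedigree(seed = 1)
    pc <- classifyPairs(ped)
    se <- simulateFeatures(ped, 500, vg = 0.5, vc = 0, ve = 0.5, seed = 7)
    pr <- pairCorrelations(SummarizedExperiment::assay(se), pc)
    sib <- pr$mean_abs_r[pr$class == "sibling"]
    unrel <- pr$mean_abs_r[pr$class == "unrelated"]
    expect_gt(sib, unrel)
})

test_that("pair correlations are invariant to subject order and flag zero variance", {
    ped <- simulatePedigree(seed = 1)
    pc <- classifyPairs(ped)
    se <- simulateFeatures(ped, 50, vg = 0.3, vc = 0.1, ve = 0.6, seed = 8)
    X <- SummarizedExperiment::assay(se)
    pr1 <- pairCorrelations(X, pc)
    perm <- sample(ncol(X))
    pr2 <- pairCorrelations(X[, perm], pc)
    expect_equal(pr1$mean_abs_r, pr2$mean_abs_r)
    ## constant feature is skipped and counted
    X2 <- rbind(X, flat = rep(3, ncol(X)))
    pr3 <- pairCorrelations(X2, pc)
    expect_equal(pr3$n_skipped[pr3$class == "sibling"], 1L)
    ## classes below the minimum pair count are skipped with a warning
    tiny <- Pedigree(data.frame(
        id = c("mom", "kid"), family_id = "f", father_id = NA,
        mother_id = c(NA, "mom"), sex = c("female", "male"), age = c(40, 9)))
    tc <- classifyPairs(tiny)
    Xt <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("mom", "kid")))
    w <- capture_warnings(pairCorrelations(Xt, tc))
    expect_true(any(grepl("skipped", w)))
})
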