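## Independent oracles used across test files. These deliberately avoid the
## package's own computational paths: kinship by Monte-Carlo gene dropping,
## multivariate-normal densities by dense determinant + solve.

## Gene-dropping kinship estimate: founders carry unique alleles, children
## inherit one random allele from each parent; the kinship of (i, j) is the
## probability that one allele sampled from each is identical by descent,
## averaged over drops (vectorized over drops).
geneDropKinship <- function(ped, nDrops = 1e5, seed = 1) {
    d <- pedData(ped)
    n <- nrow(d)
    mo <- match(d$mother_id, d$id)
    fa <- match(d$father_id, d$id)
    ## parents-first order by repeated sweeps (independent of the package's
    ## topological sort implementation detail)
    done <- logical(n); ord <- integer(0)
    while (length(ord) < n) {
        ready <- which(!done &
            (is.na(mo) | done[replace(mo, is.na(mo), 1L)]) &
            (is.na(fa) | done[replace(fa, is.na(fa), 1L)]))
        stopifnot(length(ready) > 0)
        done[ready] <- TRUE; ord <- c(ord, ready)
    }
    set.seed(seed)
    a1 <- matrix(0L, n, nDrops)
    a2 <- matrix(0L, n, nDrops)
    for (i in ord) {
        if (is.na(mo[i]) && is.na(fa[i])) {
            a1[i, ] <- 2L * i - 1L
            a2[i, ] <- 2L * i
        } else {
            pickM <- stats::runif(nDrops) < 0.5
            a1[i, ] <- ifelse(pickM, a1[mo[i], ], a2[mo[i], ])
            pickF <- stats::runif(nDrops) < 0.5
            a2[i, ] <- ifelse(pickF, a1[fa[i], ], a2[fa[i], ])
        }
    }
    K <- matrix(0, n, n, dimnames = list(d$id, d$id))
    for (i in seq_len(n)) for (j in i:n) {
        share <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
                 (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
        K[i, j] <- K[j, i] <- mean(share) / 4
    }
    K
}

## Dense multivariate-normal log density via determinant() and solve(),
## independent of the package's Cholesky/blockwise path.
denseMvnLogLik <- function(y, S, mu = 0) {
    n <- length(y)
    r <- y - mu
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% solve(S, r)))
}

## Random valid single-family pedigree of exactly n members: starts with a
## founder couple; each later member is a founder or a child of a random
## earlier opposite-sex pair, giving multi-generation structures.
randomPedigree <- function(n, seed) {
    set.seed(seed)
    id <- sprintf("i%02d", seq_len(n))
    sex <- c("female", "male",
             sample(c("female", "male"), n - 2, replace = TRUE))
    mother <- father <- rep(NA_character_, n)
    for (i in 3:n) {
        if (stats::runif(1) < 0.35) next   # founder
        fem <- which(sex[1:(i - 1)] == "female")
        mal <- which(sex[1:(i - 1)] == "male")
        if (!length(fem) || !length(mal)) next
        mother[i] <- id[fem[sample.int(length(fem), 1)]]
        father[i] <- id[mal[sample.int(length(mal), 1)]]
    }
    Pedigree(data.frame(id = id, family_id = "fam1", father_id = father,
                        mother_id = mother, sex = sex,
                        age = stats::runif(n, 5, 60)))
}

## Study-like pedigree replicated to nFamilies (16-family composition tiled).
studyLikePedigree <- function(nFamilies, seed = 1) {
    cc <- rep(c(3L, 3L, 3L, 2L, 2L, 2L, 2L, rep(1L, 9L)),
              length.out = nFamilies)
    pat <- rep(FALSE, 16); pat[c(1, 2, 4, 8, 9, 10)] <- TRUE
    simulatePedigree(nFamilies = nFamilies, childCounts = cc,
                     fatherFamilies = which(rep(pat, length.out = nFamilies)),
                     preset = "custom", seed = seed)
}
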