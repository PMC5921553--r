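#' @import methods
NULL

#' Pedigree of nuclear families
#'
#' An ordered collection of individuals with family membership, parent links,
#' sex and age. Subject order is fixed at construction and shared by every
#' matrix derived from the pedigree (relationship matrices, simulated feature
#' matrices), so row/column `i` always refers to the `i`-th pedigree member.
#'
#' @slot data A `data.frame` with one row per individual and columns
#'   `id` (unique character), `family_id` (character), `father_id`,
#'   `mother_id` (character or `NA` for founders), `sex` (`"female"` or
#'   `"male"`) and `age` (non-negative numeric, years).
#'
#' @details Validity requires unique ids, existing parents of the appropriate
#' sex, parents in the same family as the child, and an acyclic parent graph.
#' Founders are assumed non-inbred and mutually unrelated.
#'
#' @seealso [readPedigree()], [additiveMatrix()], [householdMatrix()],
#'   [classifyPairs()]
#' @export
setClass("Pedigree", representation(data = "data.frame"))

.validPedigree <- function(object) {
    d <- object@data
    need <- c("id", "family_id", "father_id", "mother_id", "sex", "age")
    miss <- setdiff(need, names(d))
    if (length(miss))
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    if (anyDuplicated(d$id))
        return(sprintf("duplicate individual id: %s",
                       paste(unique(d$id[duplicated(d$id)]), collapse = ", ")))
    if (!all(d$sex %in% c("female", "male")))
        return("sex must be 'female' or 'male'")
    if (any(!is.na(d$age) & d$age < 0))
        return("negative age")
    for (side in c("mother_id", "father_id")) {
        ref <- d[[side]]
        has <- !is.na(ref)
        dangling <- ref[has][!(ref[has] %in% d$id)]
        if (length(dangling))
            return(sprintf("dangling parent reference: %s",
                           paste(unique(dangling), collapse = ", ")))
        wantSex <- if (side == "mother_id") "female" else "male"
        idx <- match(ref[has], d$id)
        bad <- d$id[idx][d$sex[idx] != wantSex]
        if (length(bad))
            return(sprintf("parent %s listed as %s but has sex %s",
                           bad[1], sub("_id", "", side),
                           d$sex[match(bad[1], d$id)]))
        child <- d$id[has]
        if (any(d$family_id[match(ref[has], d$id)] !=
                d$family_id[match(child, d$id)]))
            return("parent and child in different families")
    }
    ord <- .topoOrder(d)
    if (is.character(ord)) return(ord)
    TRUE
}

## Kahn topological sort over parent -> child edges; returns indices with
## parents before children, or an error string naming an individual on a cycle.
.topoOrder <- function(d) {
    n <- nrow(d)
    mo <- match(d$mother_id, d$id)
    fa <- match(d$father_id, d$id)
    done <- logical(n)
    ord <- integer(0)
    parentDone <- function(p) is.na(p) | done[replace(p, is.na(p), 1L)]
    repeat {
        ready <- which(!done & parentDone(mo) & parentDone(fa))
        if (!length(ready)) break
        done[ready] <- TRUE
        ord <- c(ord, ready)
    }
    if (length(ord) < n)
        return(sprintf("pedigree cycle involving id %s",
                       d$id[which(!done)[1]]))
    ord
}

setValidity("Pedigree", .validPedigree)

#' Relationship matrix over pedigree subjects
#'
#' A symmetric subjects-by-subjects matrix in pedigree subject order, of one
#' of two kinds: `"additive"` holds twice the kinship coefficient (expected
#' proportion of alleles shared identical by descent), `"household"` is the
#' 0/1 indicator of shared family used to model common-environment
#' covariance.
#'
#' @slot values Symmetric numeric matrix with subject ids as dimnames.
#' @slot kind `"additive"` or `"household"`.
#' @export
setClass("RelationshipMatrix",
         representation(values = "matrix", kind = "character"))

setValidity("RelationshipMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v) || nrow(v) != ncol(v))
        return("values must be a square numeric matrix")
    if (max(abs(v - t(v))) > 1e-10)
        return("matrix not symmetric")
    if (!object@kind %in% c("additive", "household"))
        return("kind must be 'additive' or 'household'")
    if (object@kind == "additive") {
        if (any(v < -1e-12) || any(v > 2 + 1e-12))
            return("additive entries must lie in [0, 2]")
    } else {
        if (!all(v %in% c(0, 1)))
            return("household entries must be 0 or 1")
        if (any(diag(v) != 1))
            return("household diagonal must be 1")
    }
    TRUE
})

#' Fitted variance-components decomposition for one feature
#'
#' Maximum-likelihood fit of the polygenic model
#' \eqn{y \sim N(\mu 1,\; V_g A + V_c H + V_e I)} where `A` is the additive
#' relationship matrix and `H` the household indicator. `model` records which
#' components were free: `"full"` (Vg, Vc, Ve), `"ae"` (Vc fixed at 0),
#' `"ce"` (Vg fixed at 0), `"null"` (Vg = Vc = 0).
#'
#' @slot vg,vc,ve Non-negative variance components.
#' @slot mu Estimated mean.
#' @slot loglik Maximized log-likelihood.
#' @slot converged Logical convergence flag.
#' @slot degenerate Logical; `TRUE` when the response had (near) zero
#'   variance and the fit is a flagged floor fit.
#' @slot model Character model label.
#' @slot n Number of subjects.
#' @seealso [fitVarComp()], [heritability()], [familialTest()]
#' @export
setClass("VarCompFit",
         representation(vg = "numeric", vc = "numeric", ve = "numeric",
                        mu = "numeric", loglik = "numeric",
                        converged = "logical", degenerate = "logical",
                        model = "character", n = "integer"))

setValidity("VarCompFit", function(object) {
    if (object@vg < 0 || object@vc < 0 || object@ve < 0)
        return("variance components must be non-negative")
    if (!object@model %in% c("full", "ae", "ce", "null"))
        return("unknown model label")
    TRUE
})

#' Bivariate variance-components fit for a feature pair
#'
#' Two-trait polygenic model whose cross-trait covariance is
#' \eqn{\rho_g\sqrt{V_{g1}V_{g2}}A + \rho_c\sqrt{V_{c1}V_{c2}}H +
#' \rho_e\sqrt{V_{e1}V_{e2}}I}. The genetic correlation `rhoG` is tested
#' against zero by a likelihood ratio with one degree of freedom.
#'
#' @slot vg1,vc1,ve1,vg2,vc2,ve2 Per-trait variance components.
#' @slot rhoG,rhoC,rhoE Component correlations in \[-1, 1\] (`NA` when
#'   undefined, e.g. no familial variance in a trait).
#' @slot loglik Maximized log-likelihood of the free model.
#' @slot lrt,p Likelihood-ratio statistic and p-value for `rhoG = 0` (df 1).
#' @slot converged Logical convergence flag.
#' @slot reason Character; non-convergence / undefined-estimate reason, or
#'   `""`.
#' @seealso [geneticCorrelation()]
#' @export
setClass("BivariateFit",
         representation(vg1 = "numeric", vc1 = "numeric", ve1 = "numeric",
                        vg2 = "numeric", vc2 = "numeric", ve2 = "numeric",
                        rhoG = "numeric", rhoC = "numeric", rhoE = "numeric",
                        loglik = "numeric", lrt = "numeric", p = "numeric",
                        converged = "logical", reason = "character"))

#' @describeIn Pedigree Number of individuals.
#' @param x A `Pedigree`.
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@data))

setMethod("show", "Pedigree", function(object) {
    d <- object@data
    cat(sprintf("Pedigree: %d individuals in %d families\n",
                nrow(d), length(unique(d$family_id))))
    founders <- is.na(d$mother_id) & is.na(d$father_id)
    cat(sprintf("  founders: %d (%d female, %d male); non-founders: %d\n",
                sum(founders), sum(founders & d$sex == "female"),
                sum(founders & d$sex == "male"), sum(!founders)))
})

setMethod("show", "RelationshipMatrix", function(object) {
    cat(sprintf("RelationshipMatrix (%s): %d x %d subjects\n",
                object@kind, nrow(object@values), ncol(object@values)))
})

setMethod("show", "VarCompFit", function(object) {
    cat(sprintf("VarCompFit [%s] n=%d%s\n", object@model, object@n,
                if (object@degenerate) " (degenerate)" else ""))
    cat(sprintf("  vg=%.4g vc=%.4g ve=%.4g mu=%.4g logLik=%.4f converged=%s\n",
                object@vg, object@vc, object@ve, object@mu, object@loglik,
                object@converged))
    h <- heritability(object)
    cat(sprintf("  h2_max=%.3f h2_g=%.3f c2=%.3f\n",
                h[["h2_max"]], h[["h2_g"]], h[["c2"]]))
})

setMethod("show", "BivariateFit", function(object) {
    cat(sprintf(
        "BivariateFit: rhoG=%.3f rhoC=%.3f rhoE=%.3f (LRT=%.3f, p=%.3g)\n",
        object@rhoG, object@rhoC, object@rhoE, object@lrt, object@p))
    cat(sprintf("  trait1: vg=%.3g vc=%.3g ve=%.3g; trait2: vg=%.3g vc=%.3g ve=%.3g\n",
                object@vg1, object@vc1, object@ve1,
                object@vg2, object@vc2, object@ve2))
    if (!object@converged)
        cat(sprintf("  NOT converged: %s\n", object@reason))
})

#' Accessors for pedigree and relationship objects
#'
#' `pedData()` returns the pedigree as a `data.frame` in subject order;
#' `subjectIds()` the ordered ids; `familyIds()` the per-subject family ids;
#' `relValues()` the numeric matrix inside a [RelationshipMatrix];
#' `relKind()` its kind.
#'
#' @param x A [Pedigree] or [RelationshipMatrix].
#' @return See individual descriptions.
#' @name pedigree-accessors
#' @export
pedData <- function(x) {
    stopifnot(is(x, "Pedigree"))
    x@data
}

#' @rdname pedigree-accessors
#' @export
subjectIds <- function(x) {
    stopifnot(is(x, "Pedigree"))
    x@data$id
}

#' @rdname pedigree-accessors
#' @export
familyIds <- function(x) {
    stopifnot(is(x, "Pedigree"))
    x@data$family_id
}

#' @rdname pedigree-accessors
#' @export
relValues <- function(x) {
    stopifnot(is(x, "RelationshipMatrix"))
    x@values
}

#' @rdname pedigree-accessors
#' @export
relKind <- function(x) {
    stopifnot(is(x, "RelationshipMatrix"))
    x@kind
}

#' Construct a Pedigree from a data.frame
#'
#' @param data A `data.frame` with columns `id`, `family_id`, `father_id`,
#'   `mother_id`, `sex`, `age`. Missing parents are `NA` (or `"0"`/`""`,
#'   which are converted). Sex may be coded `1`/`"M"`/`"male"` or
#'   `2`/`"F"`/`"female"`.
#' @return A validated [Pedigree]; subject order is row order.
#' @examples
#' ped <- Pedigree(data.frame(
#'     id = c("mom", "dad", "kid"), family_id = "f1",
#'     father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mom"),
#'     sex = c("female", "male", "female"), age = c(40, 42, 12)))
#' length(ped)
#' @export
Pedigree <- function(data) {
    d <- as.data.frame(data, stringsAsFactors = FALSE)
    for (col in c("id", "family_id", "father_id", "mother_id"))
        d[[col]] <- as.character(d[[col]])
    for (col in c("father_id", "mother_id"))
        d[[col]][d[[col]] %in% c("0", "", "NA") | is.na(d[[col]])] <- NA_character_
    d$sex <- .normalizeSex(d$sex)
    d$age <- as.numeric(d$age)
    rownames(d) <- NULL
    new("Pedigree", data = d)
}

.normalizeSex <- function(sex) {
    s <- tolower(as.character(sex))
    out <- rep(NA_character_, length(s))
    out[s %in% c("1", "m", "male")] <- "male"
    out[s %in% c("2", "f", "female")] <- "female"
    if (anyNA(out))
        stop("unrecognized sex code: ",
             paste(unique(s[is.na(out)]), collapse = ", "))
    out
}
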