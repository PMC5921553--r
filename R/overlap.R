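#' Count CpG-like sites near transcript regions
#'
#' Extends each transcript interval by `windowBp` on both sides (floored at
#' position 0) and counts, per chromosome, the sites overlapping at least one
#' extended region; a site counts once per chromosome no matter how many
#' regions it hits. Coordinates are 0-based half-open internally (BED
#' convention): a point site at position `p` overlaps an extended region
#' `[s - w, e + w)` iff `s - w <= p < e + w`. 1-based closed inputs are
#' accepted with `oneBased = TRUE`.
#'
#' @param transcripts,sites `data.frame`s with columns `chromosome`, `start`,
#'   `end` (point sites may omit `end`, taken as `start + 1`), optional `id`;
#'   or `GRanges` (used as-is, 1-based closed as usual).
#' @param windowBp Extension in base pairs on each side.
#' @param oneBased Treat `data.frame` coordinates as 1-based closed.
#' @param genomeTranscripts,genomeSites Optional genome-build labels; an
#'   error is raised when both are set and differ.
#' @param perBoundary Count a site only when within `windowBp` of a region
#'   boundary (rather than anywhere in the extended region).
#' @return Named list: `perChromosome` (named integer vector) and `total`.
#' @examples
#' tx <- data.frame(chromosome = "chr1", start = c(100, 500),
#'                  end = c(200, 600))
#' cpg <- data.frame(chromosome = "chr1", start = c(95, 250, 510))
#' windowOverlap(tx, cpg, windowBp = 10)$total   # 2
#' @export
windowOverlap <- function(transcripts, sites, windowBp,
                          oneBased = FALSE,
                          genomeTranscripts = NA, genomeSites = NA,
                          perBoundary = FALSE) {
    if (!is.na(genomeTranscripts) && !is.na(genomeSites) &&
        genomeTranscripts != genomeSites)
        stop(sprintf("genome builds differ: %s vs %s",
                     genomeTranscripts, genomeSites))
    tx <- .asGRanges(transcripts, oneBased)
    cp <- .asGRanges(sites, oneBased)
    ext <- if (perBoundary) {
        c(GenomicRanges::flank(tx, windowBp, start = TRUE, both = TRUE),
          GenomicRanges::flank(tx, windowBp, start = FALSE, both = TRUE))
    } else {
        GenomicRanges::resize(tx, GenomicRanges::width(tx) + 2 * windowBp,
                              fix = "center")
    }
    ext <- GenomicRanges::trim(IRanges::restrict(ext, start = 1L))
    ## seqlevels may legitimately differ between the two inputs
    hit <- suppressWarnings(IRanges::overlapsAny(cp, ext))
    chroms <- as.character(GenomeInfoDb::seqnames(cp))
    per <- vapply(split(hit, chroms), sum, integer(1))
    list(perChromosome = per, total = sum(hit))
}

## data.frame (0-based half-open, or 1-based closed) -> GRanges
.asGRanges <- function(x, oneBased = FALSE) {
    if (is(x, "GRanges")) return(x)
    d <- as.data.frame(x)
    if (is.null(d$end)) d$end <- d$start + if (oneBased) 0 else 1
    start1 <- if (oneBased) d$start else d$start + 1
    end1 <- d$end
    GenomicRanges::GRanges(d$chromosome,
                           IRanges::IRanges(start = start1, end = end1))
}

#' Hypergeometric over-representation test
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the hit genes and the set, given the
#' universe, with Benjamini-Hochberg adjustment across sets. Symbols are
#' upper-cased on input.
#'
#' @param hits Character vector of hit gene symbols (must all be in
#'   `universe`).
#' @param universe Character vector of all testable gene symbols.
#' @param geneSets Named list of character vectors (e.g. from [readGmt()]).
#' @return `data.frame`: `set`, `set_size` (within universe), `overlap`,
#'   `p`, `p_adj`, ordered by `p`.
#' @examples
#' sets <- list(s1 = c("A", "B", "C"), s2 = c("D", "E"))
#' oraTest(c("A", "B"), LETTERS[1:10], sets)
#' @export
oraTest <- function(hits, universe, geneSets) {
    hits <- unique(toupper(hits))
    universe <- unique(toupper(universe))
    bad <- setdiff(hits, universe)
    if (length(bad))
        stop("hit gene(s) absent from universe: ",
             paste(bad, collapse = ", "))
    if (!length(geneSets) || any(!vapply(geneSets, length, 1L)))
        stop("gene sets must be non-empty")
    N <- length(universe)
    nh <- length(hits)
    rows <- lapply(names(geneSets), function(s) {
        set <- intersect(toupper(geneSets[[s]]), universe)
        K <- length(set)
        k <- length(intersect(set, hits))
        p <- if (K == 0) 1 else
            stats::phyper(k - 1, K, N - K, nh, lower.tail = FALSE)
        data.frame(set = s, set_size = K, overlap = k, p = min(p, 1))
    })
    out <- do.call(rbind, rows)
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out[order(out$p), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (set name, description, member genes per
#'   tab-separated line).
#' @return Named list of upper-cased gene symbol vectors.
#' @export
readGmt <- function(path) {
    sets <- fgsea::gmtPathways(path)
    lapply(sets, toupper)
}
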