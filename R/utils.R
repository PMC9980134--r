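#' Convert a Phred+33 quality string to integer scores
#'
#' @param qual Character vector of quality strings (Sanger encoding; HiFi
#'   reads use scores up to Q93, i.e. characters up to `~`).
#' @return For a single string, an integer vector of per-base scores; for a
#'   vector of strings, a list of integer vectors.
#' @export
phredToInt <- function(qual) {
    out <- lapply(qual, function(q) {
        if (is.na(q) || !nzchar(q)) return(integer(0))
        as.integer(charToRaw(q)) - 33L
    })
    if (length(out) == 1L) out[[1]] else out
}

#' Convert integer quality scores to a Phred+33 string
#'
#' @param q Integer vector of Phred scores in [0, 93].
#' @return A single quality string.
#' @export
intToPhred <- function(q) {
    stopifnot(all(q >= 0L & q <= 93L))
    rawToChar(as.raw(as.integer(q) + 33L))
}

## Minimal union-find over 1..n; returns component id per element.
## Used for seed-cluster graph components and chimera-set closure --
## group sizes here are tens of nodes, so no graph library is warranted.
unionFindComponents <- function(n, edges) {
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    if (length(edges) && nrow(edges) > 0L) {
        for (k in seq_len(nrow(edges))) {
            ri <- find(edges[k, 1L]); rj <- find(edges[k, 2L])
            if (ri != rj) parent[ri] <- rj
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))
}

## Run code under a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items, used
#' to score recovery of the true read-to-clone assignment on simulated data.
#'
#' @param x,y Vectors of equal length giving the two labellings.
#' @return A number in [-1, 1]; 1 means identical partitions.
#' @export
adjustedRandIndex <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (length(x) == 0L) return(NA_real_)
    tab <- table(x, y)
    nij <- sum(choose(tab, 2))
    a <- sum(choose(rowSums(tab), 2))
    b <- sum(choose(colSums(tab), 2))
    n2 <- choose(length(x), 2)
    expected <- a * b / n2
    maxi <- (a + b) / 2
    if (maxi == expected) return(1)
    (nij - expected) / (maxi - expected)
}
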