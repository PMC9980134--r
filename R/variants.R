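## Candidate variants are plain data.frames with columns
##   pos   1-based reference position (for a pure insertion: the reference
##         base the insertion is anchored *after*; 0 = before the sequence)
##   ref   reference allele ("" for a pure insertion)
##   alt   alternate allele ("" for a deletion)
##   vtype one of "SNV", "MNV", "insertion", "deletion"
##   qual  Phred-scaled quality of the call
## Set identity is the (pos, ref, alt) triple.

#' Empty candidate-variant table
#' @return A zero-row variant data.frame with the canonical columns.
#' @export
emptyVariants <- function() {
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               vtype = character(0), qual = integer(0),
               stringsAsFactors = FALSE)
}

#' Build a candidate-variant table
#'
#' @param pos Integer vector of 1-based reference positions.
#' @param ref,alt Allele strings; exactly one of the two may be empty per row
#'   ("" ref = insertion anchored after `pos`, "" alt = deletion).
#' @param qual Integer Phred qualities.
#' @param vtype Optional types; inferred from allele lengths when omitted.
#' @return A variant data.frame ordered by position.
#' @export
variantTable <- function(pos, ref, alt, qual, vtype = NULL) {
    if (length(pos) == 0L) return(emptyVariants())
    if (is.null(vtype)) {
        vtype <- ifelse(nchar(ref) == 0L, "insertion",
                 ifelse(nchar(alt) == 0L, "deletion",
                 ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "MNV")))
    }
    bad <- nchar(ref) == 0L & nchar(alt) == 0L
    if (any(bad)) stop("variant with both ref and alt empty")
    df <- data.frame(pos = as.integer(pos), ref = as.character(ref),
                     alt = as.character(alt), vtype = as.character(vtype),
                     qual = as.integer(qual), stringsAsFactors = FALSE)
    df[order(df$pos, df$ref, df$alt), , drop = FALSE]
}

#' Identity keys of candidate variants
#'
#' @param v A variant data.frame.
#' @return Character vector `pos:ref>alt`, the identity used for all set
#'   operations (support counting, Jaccard, genotype comparison).
#' @export
variantKey <- function(v) {
    if (nrow(v) == 0L) return(character(0))
    paste0(v$pos, ":", v$ref, ">", v$alt)
}

#' Serialize variants to the `pos:ref>alt:qual` string form
#' @param v A variant data.frame.
#' @return Single string, entries comma-joined; "" for an empty set (WT).
#' @export
formatVariants <- function(v) {
    if (nrow(v) == 0L) return("")
    paste0(v$pos, ":", v$ref, ">", v$alt, ":", v$qual, collapse = ",")
}

#' Parse the serialized variant string form
#' @param s A string as produced by [formatVariants()].
#' @return A variant data.frame.
#' @export
parseVariants <- function(s) {
    if (is.na(s) || !nzchar(s)) return(emptyVariants())
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "[:>]")
    variantTable(pos = vapply(parts, function(p) as.integer(p[1]), integer(1)),
                 ref = vapply(parts, `[`, "", 2),
                 alt = vapply(parts, `[`, "", 3),
                 qual = vapply(parts, function(p) as.integer(p[4]), integer(1)))
}

## Left-align one indel against the reference string. Substitutions are
## returned unchanged. Standard shift: an indel may move one position left
## when the reference base preceding it equals the last base of the
## inserted/deleted sequence.
leftAlignVariant <- function(pos, ref, alt, refseq) {
    if (nchar(ref) > 0L && nchar(alt) > 0L) return(list(pos = pos, ref = ref, alt = alt))
    if (nchar(alt) == 0L) {           # deletion of ref[pos .. pos+k-1]
        k <- nchar(ref)
        while (pos > 1L &&
               substr(refseq, pos - 1L, pos - 1L) ==
               substr(refseq, pos + k - 1L, pos + k - 1L)) {
            pos <- pos - 1L
            ref <- substr(refseq, pos, pos + k - 1L)
        }
        list(pos = pos, ref = ref, alt = "")
    } else {                          # insertion anchored after ref[pos]
        while (pos > 0L &&
               substr(refseq, pos, pos) == substr(alt, nchar(alt), nchar(alt))) {
            alt <- paste0(substr(refseq, pos, pos),
                          substr(alt, 1L, nchar(alt) - 1L))
            pos <- pos - 1L
        }
        list(pos = pos, ref = "", alt = alt)
    }
}

#' Left-align all indels in a variant table against a reference
#' @param v A variant data.frame.
#' @param refseq Reference sequence as a character string.
#' @return The table with indels shifted to their leftmost equivalent
#'   representation (substitutions untouched), re-sorted.
#' @export
leftAlignVariants <- function(v, refseq) {
    refseq <- as.character(refseq)
    if (nrow(v) == 0L) return(v)
    for (i in seq_len(nrow(v))) {
        la <- leftAlignVariant(v$pos[i], v$ref[i], v$alt[i], refseq)
        v$pos[i] <- la$pos; v$ref[i] <- la$ref; v$alt[i] <- la$alt
    }
    v[order(v$pos, v$ref, v$alt), , drop = FALSE]
}

#' Apply candidate variants to a reference sequence
#'
#' Reconstructs the mutated sequence implied by a variant set. Variants must
#' be non-overlapping.
#'
#' @param refseq Reference sequence (character string or DNAString).
#' @param v A variant data.frame.
#' @return The edited sequence as a character string.
#' @export
applyVariants <- function(refseq, v) {
    s <- as.character(refseq)
    if (nrow(v) == 0L) return(s)
    v <- v[order(v$pos, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(v))) {
        p <- v$pos[i]; ref <- v$ref[i]; alt <- v$alt[i]
        if (nchar(ref) == 0L) {       # insertion after p
            s <- paste0(substr(s, 1L, p), alt, substr(s, p + 1L, nchar(s)))
        } else {
            s <- paste0(substr(s, 1L, p - 1L), alt,
                        substr(s, p + nchar(ref), nchar(s)))
        }
    }
    s
}

#' Jaccard index of two candidate-variant sets
#'
#' @param a,b Variant data.frames; identity is (pos, ref, alt).
#' @return |a intersect b| / |a union b|, defined as 1 when both sets are
#'   empty (two wild-type genotypes agree completely).
#' @export
jaccardIndex <- function(a, b) {
    ka <- unique(variantKey(a)); kb <- unique(variantKey(b))
    if (length(ka) == 0L && length(kb) == 0L) return(1)
    length(intersect(ka, kb)) / length(union(ka, kb))
}
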