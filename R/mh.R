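#' Microhomology at a deletion junction by placement ambiguity
#'
#' A deletion of `[del_start, del_end)` (0-based, half-open coordinates on
#' the reference) can often be placed at several distinct intervals that all
#' yield the identical product sequence: this happens exactly when the
#' sequence flanking the deletion shares terminal bases with the deleted
#' segment, i.e. when the junction carries microhomology (MH).  The MH length
#' is defined as the number of equivalent contiguous placements minus one,
#' which (in the left-aligned convention used throughout this package) equals
#' the length of the longest exact match between the sequence immediately 5'
#' of the left-aligned deletion and the 3' terminus of the deleted segment.
#'
#' @param reference reference sequence (single character string, A/C/G/T).
#' @param del_start,del_end 0-based half-open deletion interval.
#' @return A list with elements `mh_len` (integer), `mh_seq` (character),
#'   `del_start`, `del_end` (the left-aligned canonical placement) and
#'   `ambiguity_window`, an integer vector `c(lo, hi)` such that every
#'   placement start in `lo..hi` yields the same product
#'   (`hi - lo == mh_len`).
#' @examples
#' mh_length("AAAAAA", 2, 4)        # mh_len 4: five equivalent placements
#' mh_length("AAGCTGCTTT", 4, 7)    # mh_len 2: "AAGCTTT" three ways
#' @export
mh_length <- function(reference, del_start, del_end) {
    n <- nchar(reference)
    stopifnot(is.character(reference), length(reference) == 1L,
              del_start >= 0, del_start <= del_end, del_end <= n)
    del_start <- as.integer(del_start)
    del_end <- as.integer(del_end)
    if (del_start == del_end) {
        ## zero-length deletion: MH undefined, 0 by convention
        return(list(mh_len = 0L, mh_seq = "",
                    del_start = del_start, del_end = del_end,
                    ambiguity_window = c(del_start, del_start)))
    }
    r <- charToRaw(reference)
    s <- del_start
    e <- del_end
    ## left-align: shifting (s,e) -> (s-1,e-1) preserves the product iff the
    ## base entering the deletion on the left equals the one leaving it
    while (s > 0L && r[s] == r[e]) {
        s <- s - 1L
        e <- e - 1L
    }
    ## number of right shifts available from the left-aligned placement
    k <- 0L
    while (e + k < n && r[s + k + 1L] == r[e + k + 1L]) {
        k <- k + 1L
    }
    list(mh_len = k,
         mh_seq = if (k > 0L) substr(reference, s + 1L, s + k) else "",
         del_start = s, del_end = e,
         ambiguity_window = c(s, s + k))
}

#' Microhomology at a two-sided fusion junction
#'
#' For a chimeric junction joining `left_ref[0, left_end)` to
#' `right_ref[right_start, ...)` (0-based half-open), the junction placement
#' is ambiguous wherever bases match both partners.  The total MH length is
#' the number of equivalent junction placements minus one; unlike
#' [mh_length()] it is well defined (and frequently non-zero) for a junction
#' with no bases lost on either side.
#'
#' @param left_ref,right_ref the two partner reference sequences, already
#'   oriented so that the product is `left` followed by `right`.
#' @param left_end 0-based end (exclusive) of the retained left segment.
#' @param right_start 0-based start of the retained right segment.
#' @return list with `mh_len`, `mh_seq`, `fwd` and `back` (bases of ambiguity
#'   downstream/upstream of the nominal junction), and the right-maximal
#'   canonical placement `left_end`, `right_start` (ambiguous bases assigned
#'   to the left partner).
#' @export
junction_mh <- function(left_ref, left_end, right_ref, right_start) {
    la <- charToRaw(left_ref)
    rb <- charToRaw(right_ref)
    nl <- length(la)
    nr <- length(rb)
    left_end <- as.integer(left_end)
    right_start <- as.integer(right_start)
    ## forward: product bases beyond the junction match the left partner too
    fwd <- 0L
    while (left_end + fwd < nl && right_start + fwd < nr &&
           la[left_end + fwd + 1L] == rb[right_start + fwd + 1L]) {
        fwd <- fwd + 1L
    }
    ## backward: product bases before the junction match the right partner too
    back <- 0L
    while (left_end - back > 0L && right_start - back > 0L &&
           la[left_end - back] == rb[right_start - back]) {
        back <- back + 1L
    }
    mh <- fwd + back
    ce <- left_end + fwd   # canonical: ambiguous bases attributed to `left`
    mh_seq <- if (mh > 0L) substr(left_ref, ce - mh + 1L, ce) else ""
    list(mh_len = mh, mh_seq = mh_seq, fwd = fwd, back = back,
         left_end = ce, right_start = right_start + fwd)
}

#' Canonical placement of an indel event
#'
#' Normalizes a (possibly compound) event that deletes
#' `reference[del_start, del_end)` and inserts `inserted` at the junction, by
#' shifting it to the extreme equivalent placement (product-preserving).
#' `direction = "left"` gives the left-aligned convention used for
#' within-locus junction calls; `"right"` assigns ambiguous bases to the
#' upstream partner, the convention used at translocation and fusion
#' junctions.
#'
#' @param reference reference sequence (character scalar).
#' @param del_start,del_end 0-based half-open deletion interval (may be
#'   empty for a pure insertion).
#' @param inserted inserted sequence ("" for a pure deletion).
#' @param direction `"left"` or `"right"`.
#' @return list with canonical `del_start`, `del_end`, `inserted`, and for
#'   pure deletions the MH annotation of [mh_length()].
#' @export
canonical_event <- function(reference, del_start, del_end, inserted = "",
                            direction = c("left", "right")) {
    direction <- match.arg(direction)
    s <- as.integer(del_start)
    e <- as.integer(del_end)
    ins <- inserted %||% ""
    r <- charToRaw(reference)
    n <- length(r)
    k <- nchar(ins)
    ## shrink a compound event to its minimal representation: inserted
    ## bases equal to the deleted boundary bases are matched out
    while (k > 0L && e > s && substr(ins, 1L, 1L) == rawToChar(r[s + 1L])) {
        s <- s + 1L
        ins <- substr(ins, 2L, k)
        k <- k - 1L
    }
    while (k > 0L && e > s && substr(ins, k, k) == rawToChar(r[e])) {
        e <- e - 1L
        ins <- substr(ins, 1L, k - 1L)
        k <- k - 1L
    }
    if (direction == "left") {
        repeat {
            if (s <= 0L) break
            if (k > 0L) {
                ## shift left iff the inserted string ends with the base that
                ## re-enters the product on the right flank
                if (substr(ins, k, k) == rawToChar(r[e])) {
                    ins <- paste0(rawToChar(r[s]), substr(ins, 1L, k - 1L))
                    s <- s - 1L
                    e <- e - 1L
                } else break
            } else if (s < e && r[s] == r[e]) {
                s <- s - 1L
                e <- e - 1L
            } else if (s == e) break else break
        }
    } else {
        repeat {
            if (e >= n) break
            if (k > 0L) {
                if (substr(ins, 1L, 1L) == rawToChar(r[s + 1L])) {
                    ins <- paste0(substr(ins, 2L, k), rawToChar(r[e + 1L]))
                    s <- s + 1L
                    e <- e + 1L
                } else break
            } else if (s < e && r[s + 1L] == r[e + 1L]) {
                s <- s + 1L
                e <- e + 1L
            } else break
        }
    }
    out <- list(del_start = s, del_end = e, inserted = ins)
    if (k == 0L && e > s) {
        out <- c(out, mh_length(reference, s, e)[c("mh_len", "mh_seq",
                                                   "ambiguity_window")])
    } else {
        out$mh_len <- 0L
        out$mh_seq <- ""
        out$ambiguity_window <- c(s, s)
    }
    out
}
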