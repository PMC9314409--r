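#' Does a junction call restore GFP expression in the NHEJ reporter?
#'
#' In the NHEJ reporter, translation initiates at the strong Kozak start
#' codon (Koz-ATG) which lies out of frame with the downstream GFP coding
#' sequence by a 34-bp frameshift.  GFP is restored when scanning from
#' the first upstream ATG reaches an intact, in-frame GFP open reading
#' frame.  For a spacer indel that leaves both start codons intact this
#' reduces to the net-size congruence `net mod 3 == 2` (gains of 2, 5,
#' 8, ... bp; losses of 1, 4, 7, ... bp); an indel that disrupts the
#' Koz-ATG start codon restores GFP by letting scanning fall through to
#' the GFP ATG.  The implementation evaluates the general local rule —
#' rebuild the mutated sequence upstream of the GFP coding body, require
#' the codon feeding the body to be ATG, and require the first upstream
#' ATG to be in frame with it — which also resolves junction-created
#' start codons (e.g. a deletion splicing an upstream A onto a TG).
#'
#' Events that remove or interrupt GFP coding bases beyond the start
#' codon never restore GFP; complex events spanning the GFP start codon
#' are indeterminate (`NA`); unedited reads are `FALSE`.  The rule is
#' exact for constructs whose non-coding regions are free of incidental
#' start/stop codons (as built by [nhej_reporter_config()]) and for
#' inserted sequences that do not themselves create an ATG.
#'
#' @param call a junction call: list or one-row data.frame with fields
#'   `status`, `del_start`, `del_end`, `inserted_seq` (see
#'   [align_and_call()]); coordinates must be on the reporter, not a
#'   sub-window.
#' @param reporter an NHEJ `ReporterConstruct` from [build_reporter()].
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate/unaligned).
#' @seealso [translation_reports_gfp()], the independent ORF-scanning oracle.
#' @export
frame_restored <- function(call, reporter) {
    stopifnot(reporter$type == "nhej")
    status <- as.character(call$status)
    if (status == "unaligned") return(NA)
    if (status == "unedited") return(FALSE)
    cds <- reporter$gfp_cds            # [start, end) of the GFP CDS
    body <- cds[1] + 3L                # first base after the GFP ATG
    s <- as.integer(call$del_start)
    e <- as.integer(call$del_end)
    ins <- call$inserted_seq %||% ""
    if (is.na(ins)) ins <- ""
    is_insertion_only <- (s == e)

    spans_gfp_atg <- s < body && e > cds[1]
    if (status == "complex" && spans_gfp_atg) return(NA)

    ## events that start inside the coding body (or beyond) remove or
    ## interrupt GFP residues and never restore full-length GFP
    if (s >= body) return(FALSE)
    ## deletions reaching the C-terminal region truncate the peptide
    if (e >= cds[2] - 3L) return(FALSE)

    ## local scanning rule on the rebuilt sequence up to the first
    ## undamaged codon boundary b*: translation from the first upstream
    ## ATG must be in frame with b* and must decode the peptide residues
    ## preceding the undamaged suffix (junction codons may legitimately
    ## recode the residues the deletion removed)
    seq <- reporter$sequence
    bstar <- if (e <= body) body
             else cds[1] + 3L * as.integer(ceiling((e - cds[1]) / 3))
    k <- (bstar - cds[1]) %/% 3L       # peptide residues to check
    mut_pre <- paste0(substr(seq, 1L, s), ins,
                      substr(seq, e + 1L, bstar))
    q <- nchar(mut_pre)                # b* in mutated coordinates
    p <- regexpr("ATG", mut_pre, fixed = TRUE)[1] - 1L   # first ATG, 0-based
    if (p < 0L || ((q - p) %% 3L) != 0L || q - p < 3L) return(FALSE)
    orf <- substr(mut_pre, p + 1L, q)
    codons <- substring(orf, seq(1L, nchar(orf), 3L),
                        seq(3L, nchar(orf), 3L))
    res <- paste(Biostrings::GENETIC_CODE[codons], collapse = "")
    if (grepl("*", res, fixed = TRUE) || grepl("NA", res, fixed = TRUE))
        return(FALSE)
    endsWith(res, substr(reporter$gfp_peptide, 1L, k))
}

#' ORF-scanning oracle: does a sequence translate full-length GFP?
#'
#' Simulates cap-dependent scanning: translation starts at the first ATG of
#' each sequence and proceeds to the first stop codon; the sequence is
#' scored positive when the resulting peptide contains the complete GFP
#' peptide.  This is the mechanism-independent oracle against which the
#' rule-based [frame_restored()] is checked.
#'
#' @param seqs character vector of (mutated) construct sequences.
#' @param gfp_peptide the full GFP peptide (from
#'   `reporter$gfp_peptide`).
#' @return logical vector.
#' @export
translation_reports_gfp <- function(seqs, gfp_peptide) {
    atg <- regexpr("ATG", seqs, fixed = TRUE)
    out <- logical(length(seqs))
    has <- atg > 0L
    if (!any(has)) return(out)
    sub <- substring(seqs[has], atg[has])
    w <- (nchar(sub) %/% 3L) * 3L
    sub <- substr(sub, 1L, w)
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(sub),
                                             if.fuzzy.codon = "X"))
    aa <- sub("\\*.*$", "", aa)      # stop translation at the first stop
    out[has] <- vapply(aa, function(p) grepl(gfp_peptide, p, fixed = TRUE),
                       logical(1), USE.NAMES = FALSE)
    out
}

#' Apply an indel to a sequence
#'
#' Utility used by simulators and oracles: deletes
#' `[del_start, del_end)` (0-based half-open) and inserts `inserted` at the
#' junction.
#' @param reference sequence (character scalar).
#' @param del_start,del_end deletion interval; equal for a pure insertion.
#' @param inserted inserted sequence ("" for none).
#' @export
apply_indel <- function(reference, del_start, del_end, inserted = "") {
    paste0(substr(reference, 1L, del_start),
           inserted,
           substr(reference, del_end + 1L, nchar(reference)))
}
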