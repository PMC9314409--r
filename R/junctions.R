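#' Align one amplicon read and produce a canonical junction call
#'
#' Semi-global affine-gap alignment of the read against the reference
#' window, followed by canonicalization: all indel operations separated by
#' at most `merge_gap` matched bases are merged into a single event; a
#' single pure deletion or insertion is reported as such (left-aligned,
#' with its MH annotation from [mh_length()]); anything else with an indel
#' is `complex`.  Reads differing from the reference only by substitutions
#' are `unedited`; alignments below `min_identity` are `unaligned`.
#'
#' @param read read sequence (character scalar).
#' @param reference_window reference amplicon window.
#' @param cut_offset 0-based cut position within the window (recorded, not
#'   used to constrain the alignment).
#' @param merge_gap maximum number of matched bases between indel
#'   operations merged into one event.
#' @param min_identity minimum alignment identity, below which the read is
#'   `unaligned`.
#' @param anchor minimum read length is `2 * anchor`; reads shorter than
#'   this cannot anchor both flanks.
#' @return a one-row data.frame (`JunctionCall`): `status`, `del_start`,
#'   `del_end`, `del_len`, `inserted_seq`, `net_indel`, `mh_len`, `mh_seq`,
#'   `amb_lo`, `amb_hi`, `identity`.
#' @export
align_and_call <- function(read, reference_window, cut_offset = NA,
                           merge_gap = 5L, min_identity = 0.8,
                           anchor = 20L) {
    if (!nzchar(read)) stop("empty read")
    if (nchar(read) < 2L * anchor)
        stop("read shorter than twice the anchor length")
    calls <- call_junctions(setNames(read, "read"), reference_window,
                            cut_offset, merge_gap = merge_gap,
                            min_identity = min_identity, anchor = anchor)
    calls[, setdiff(names(calls), "read_id")]
}

#' Call junctions for a whole library of reads
#'
#' Vectorized version of [align_and_call()]: unique read sequences are
#' aligned once and calls propagated to duplicates.
#'
#' @param reads named character vector (names become `read_id`).
#' @param reference_window,cut_offset,merge_gap,min_identity,anchor see
#'   [align_and_call()].
#' @return data.frame of calls, one row per read.
#' @export
call_junctions <- function(reads, reference_window, cut_offset = NA,
                           merge_gap = 5L, min_identity = 0.8,
                           anchor = 20L) {
    if (is.null(names(reads)))
        names(reads) <- sprintf("read_%05d", seq_along(reads))
    uniq <- unique(unname(reads))
    idx <- match(unname(reads), uniq)

    ucalls <- vector("list", length(uniq))
    ## identity shortcut: reads equal to the reference
    is_ref <- uniq == reference_window
    for (i in which(is_ref)) ucalls[[i]] <- empty_call("unedited", 1)
    todo <- which(!is_ref)
    if (length(todo)) {
        aln <- Biostrings::pairwiseAlignment(
            pattern = Biostrings::DNAStringSet(uniq[todo]),
            subject = Biostrings::DNAString(reference_window),
            type = "global",
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
                match = 2, mismatch = -11, baseOnly = TRUE),
            gapOpening = 12, gapExtension = 1)
        oplists <- alignment_ops(aln, uniq[todo])
        ## identity = matched bases over read length, so both dense
        ## mismatch and poor coverage (gap-riddled alignments) disqualify
        ident <- Biostrings::nmatch(aln) / nchar(uniq[todo])
        for (k in seq_along(todo)) {
            ucalls[[todo[k]]] <- call_from_ops(
                oplists[[k]], ident[k], reference_window,
                merge_gap = merge_gap, min_identity = min_identity)
        }
    }
    out <- do.call(rbind, ucalls)[idx, , drop = FALSE]
    out <- cbind(read_id = names(reads), out, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

empty_call <- function(status, identity = NA_real_) {
    data.frame(status = status, del_start = NA_integer_,
               del_end = NA_integer_, del_len = 0L, inserted_seq = "",
               net_indel = 0L, mh_len = 0L, mh_seq = "",
               amb_lo = NA_integer_, amb_hi = NA_integer_,
               identity = identity, stringsAsFactors = FALSE)
}

## Extract indel operations (0-based reference coordinates, inserted
## sequences from the read) for every alignment in a PairwiseAlignments
## object, via the cheap insertion()/deletion() accessors: deletion ranges
## are 1-based closed on the subject; insertion ranges are projected onto
## the subject walk, with start - 1 the 0-based insertion point plus the
## deleted bases preceding it.
alignment_ops <- function(aln, reads) {
    ins <- Biostrings::insertion(aln)
    del <- Biostrings::deletion(aln)
    ins_s <- BiocGenerics::start(ins); ins_w <- BiocGenerics::width(ins)
    del_s <- BiocGenerics::start(del); del_w <- BiocGenerics::width(del)
    lapply(seq_along(reads), function(k) {
        ds <- del_s[[k]]; dw <- del_w[[k]]
        is_ <- ins_s[[k]]; iw <- ins_w[[k]]
        ## alignment-column order of the operations
        dcol <- ds + c(0L, cumsum(dw))[seq_along(ds)]
        icol <- is_ + c(0L, cumsum(iw))[seq_along(is_)]
        tab <- rbind(
            if (length(ds)) data.frame(type = "del", raw = ds, w = dw,
                                       col = dcol) else NULL,
            if (length(is_)) data.frame(type = "ins", raw = is_, w = iw,
                                        col = icol) else NULL)
        if (is.null(tab) || nrow(tab) == 0L) return(list())
        tab <- tab[order(tab$col), , drop = FALSE]
        ops <- vector("list", nrow(tab))
        cum_del <- 0L; cum_ins <- 0L
        for (j in seq_len(nrow(tab))) {
            if (tab$type[j] == "del") {
                s <- tab$raw[j] - 1L + cum_del - cum_ins
                ops[[j]] <- list(type = "del", s = s, e = s + tab$w[j],
                                 seq = "")
                cum_del <- cum_del + tab$w[j]
            } else {
                p <- tab$raw[j] - 1L
                rs <- p - cum_del + cum_ins
                ops[[j]] <- list(type = "ins", s = p, e = p,
                                 seq = substr(reads[k], rs + 1L,
                                              rs + tab$w[j]))
                cum_ins <- cum_ins + tab$w[j]
            }
        }
        ops
    })
}

## Merge operations separated by <= merge_gap matched bases and produce a
## canonical junction call.
call_from_ops <- function(ops, ident, reference, merge_gap = 5L,
                          min_identity = 0.8) {
    if (ident < min_identity) return(empty_call("unaligned", ident))
    if (length(ops) == 0L) return(empty_call("unedited", ident))

    ## merge operations separated by <= merge_gap reference-matched bases
    merged <- list(ops[[1L]])
    for (op in ops[-1L]) {
        last <- merged[[length(merged)]]
        gap_bases <- op$s - last$e
        if (gap_bases <= merge_gap) {
            ## retained reference bases between the events become inserted
            between <- if (gap_bases > 0)
                substr(reference, last$e + 1L, op$s) else ""
            merged[[length(merged)]] <- list(
                type = "merged", s = last$s, e = op$e,
                seq = paste0(last$seq, between, op$seq))
        } else merged[[length(merged) + 1L]] <- op
    }

    if (length(merged) > 1L) {
        s <- min(vapply(merged, `[[`, 0L, "s"))
        e <- max(vapply(merged, `[[`, 0L, "e"))
        ins <- paste(vapply(merged, `[[`, "", "seq"), collapse = "")
        out <- empty_call("complex", ident)
        out$del_start <- s; out$del_end <- e
        out$del_len <- e - s
        out$inserted_seq <- ins
        out$net_indel <- sum(vapply(merged, function(o)
            nchar(o$seq) - (o$e - o$s), 0L))
        return(out)
    }

    ev <- merged[[1L]]
    can <- canonical_event(reference, ev$s, ev$e, ev$seq, "left")
    has_del <- can$del_end > can$del_start
    has_ins <- nzchar(can$inserted)
    status <- if (has_del && has_ins) "complex"
              else if (has_del) "deletion" else "insertion"
    out <- empty_call(status, ident)
    out$del_start <- can$del_start
    out$del_end <- can$del_end
    out$del_len <- can$del_end - can$del_start
    out$inserted_seq <- can$inserted
    out$net_indel <- nchar(can$inserted) - out$del_len
    out$mh_len <- can$mh_len
    out$mh_seq <- can$mh_seq
    out$amb_lo <- can$ambiguity_window[1]
    out$amb_hi <- can$ambiguity_window[2]
    out
}

#' Editing efficiency from junction calls
#'
#' Fraction of aligned reads carrying an indel (deletion, insertion or
#' complex), normalized by transfection efficiency.  Substitution-only
#' reads count as unedited.  Values exceeding 1 after normalization are
#' capped with a warning.
#'
#' @param calls data.frame from [call_junctions()].
#' @param transfection_eff in (0, 1].
#' @return numeric fraction.
#' @export
editing_efficiency <- function(calls, transfection_eff = 1) {
    stopifnot(transfection_eff > 0, transfection_eff <= 1)
    aligned <- calls$status != "unaligned"
    if (!any(aligned)) stop("all reads unaligned")
    edited <- calls$status %in% c("deletion", "insertion", "complex")
    eff <- sum(edited) / sum(aligned) / transfection_eff
    if (eff > 1) {
        warning("normalized editing efficiency exceeds 1; capping")
        eff <- 1
    }
    eff
}

#' Summarize deletion junctions
#'
#' Median deletion length, the three size bins (1-10, 11-80, >= 81 bp),
#' microhomology usage (fraction of deletion junctions with MH >= 1 bp)
#' and the MH length distribution, over pure-deletion calls.
#'
#' @param calls data.frame from [call_junctions()].
#' @return list of class `DeletionSummary` with `n_total`, `n_edited`,
#'   `n_deletions`, `median_del_len`, `bin_fracs`, `mh_usage`,
#'   `mh_len_distribution`.
#' @export
summarize_deletions <- function(calls) {
    del <- calls[calls$status == "deletion", , drop = FALSE]
    n_del <- nrow(del)
    out <- list(n_total = nrow(calls),
                n_edited = sum(calls$status %in%
                               c("deletion", "insertion", "complex")),
                n_deletions = n_del)
    if (n_del == 0L) {
        out <- c(out, list(median_del_len = NA_real_,
                           bin_fracs = c(`1-10` = NA, `11-80` = NA,
                                         `>=81` = NA),
                           mh_usage = NA_real_,
                           mh_len_distribution = table(integer(0))))
        class(out) <- "DeletionSummary"
        return(out)
    }
    len <- del$del_len
    bins <- cut(len, c(0, 10, 80, Inf), labels = c("1-10", "11-80", ">=81"))
    out$median_del_len <- median(len)
    out$bin_fracs <- as.vector(table(bins)) / n_del
    names(out$bin_fracs) <- levels(bins)
    out$mh_usage <- mean(del$mh_len >= 1L)
    out$mh_len_distribution <- table(del$mh_len)
    class(out) <- "DeletionSummary"
    out
}

#' @export
print.DeletionSummary <- function(x, ...) {
    cat("DeletionSummary:", x$n_deletions, "deletions /", x$n_edited,
        "edited /", x$n_total, "reads\n")
    if (x$n_deletions > 0) {
        cat("  median deletion length:", x$median_del_len, "bp\n")
        cat("  size bins:", paste(names(x$bin_fracs),
                                  sprintf("%.3f", x$bin_fracs),
                                  collapse = " | "), "\n")
        cat("  MH usage:", sprintf("%.3f", x$mh_usage), "\n")
    }
    invisible(x)
}

#' Write junction calls as TSV
#' @param calls data.frame of calls.
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
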