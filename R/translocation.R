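#' Synthetic locus pair (plus internal control) for translocation assays
#'
#' Builds two random amplicon loci ("A" and "B", e.g. Eml4- and Alk-like
#' introns) with a cut site in the middle of each, and a control amplicon
#' (Gapdh-like) co-sequenced as internal PCR control.
#'
#' @param arm bases on each side of the cut in each locus amplicon.
#' @param control_len length of the control amplicon.
#' @param seed integer seed.
#' @return list of class `TranslocationLoci` with `locusA`, `locusB`
#'   (each `list(name, sequence, cut_pos)`) and `control`
#'   (`list(name, sequence)`).
#' @export
translocation_loci <- function(arm = 150L, control_len = 220L, seed = 11L) {
    with_seed(seed, {
        loci <- list(
            locusA = list(name = "locusA", sequence = random_dna(2L * arm),
                          cut_pos = arm),
            locusB = list(name = "locusB", sequence = random_dna(2L * arm),
                          cut_pos = arm),
            control = list(name = "control",
                           sequence = random_dna(control_len)))
        class(loci) <- "TranslocationLoci"
        loci
    })
}

## The four orientation types.  For "A^F" the junction read carries the
## Watson-strand sequence of locus A 5' of its cut; for "A^R" it carries
## the reverse complement of the sequence 3' of the cut (so the junction
## end is always at the cut).  Side B mirrors this 3' of the junction.
ORIENTATIONS <- c("FF", "FR", "RF", "RR")

## oriented left/right partner sequences for one orientation: the read is
## left_part (ending at cutA) + right_part (starting at cutB)
orientation_refs <- function(loci, orientation) {
    A <- loci$locusA; B <- loci$locusB
    a_side <- substr(orientation, 1L, 1L)
    b_side <- substr(orientation, 2L, 2L)
    left <- if (a_side == "F") substr(A$sequence, 1L, A$cut_pos)
            else revcomp(substr(A$sequence, A$cut_pos + 1L,
                                nchar(A$sequence)))
    leftref <- if (a_side == "F") A$sequence else revcomp(A$sequence)
    right <- if (b_side == "F")
        substr(B$sequence, B$cut_pos + 1L, nchar(B$sequence))
    else revcomp(substr(B$sequence, 1L, B$cut_pos))
    rightref <- if (b_side == "F") B$sequence else revcomp(B$sequence)
    ## junction coordinates on the oriented full references
    jl <- nchar(left)                 # cut position on oriented A
    jr <- nchar(rightref) - nchar(right)
    list(left = left, right = right, leftref = leftref,
         rightref = rightref, junction_left = jl, junction_right = jr,
         template = paste0(left, right))
}

#' Simulate a translocation junction sequencing library
#'
#' Chimeric junction reads between locus A and locus B in the four
#' orientation types, mixed with internal-control amplicon reads.  The
#' fraction of control reads follows the assay design: translocation and
#' control PCR products mixed `volume_ratio`:1 in volume, with the
#' translocation product at relative template abundance `trans_abundance`
#' per volume unit, so each read is a control read with probability
#' `1 / (1 + volume_ratio * trans_abundance)`.
#'
#' Per-side resection losses are drawn from `resection_law` (with
#' probability `p_precise` both are zero and no insertion occurs);
#' untemplated junction insertions occur with probability `p_insertion`.
#' Truth coordinates are canonicalized with ambiguous junction bases
#' attributed to locus A, the same convention as [call_translocations()].
#'
#' @param loci a [translocation_loci()] object.
#' @param orientation_mix named probabilities over `c("FF","FR","RF","RR")`.
#' @param n_reads total reads (junction + control).
#' @param volume_ratio translocation:control PCR volume mixing ratio.
#' @param trans_abundance relative template abundance of the translocation
#'   product (per volume unit, control = 1).
#' @param resection_law size law (see [outcome_mixture()]) for per-side
#'   losses, applied independently to each side.
#' @param p_precise probability of a precise end-to-end fusion.
#' @param p_insertion probability of an untemplated junction insertion
#'   (given not precise).
#' @param insertion_law size law for untemplated insertions.
#' @param error_rate per-base substitution rate.
#' @param seed integer seed.
#' @return list with `reads` (named character), `truth` (data.frame with
#'   `read_id`, `is_control`, `orientation`, `del_A`, `del_B`, `mh_len`,
#'   `inserted_seq`, `precise`), and the `loci`.
#' @export
simulate_translocation_library <- function(loci,
                                           orientation_mix = c(FF = 0.25,
                                                               FR = 0.25,
                                                               RF = 0.25,
                                                               RR = 0.25),
                                           n_reads = 1000L,
                                           volume_ratio = 10,
                                           trans_abundance = 0.01,
                                           resection_law = list(
                                               type = "geometric", mean = 4),
                                           p_precise = 0.2,
                                           p_insertion = 0.1,
                                           insertion_law = list(
                                               type = "geometric", mean = 2),
                                           error_rate = 0, seed = 1L) {
    if (abs(sum(orientation_mix) - 1) > 1e-8)
        stop("orientation probabilities must sum to 1")
    if (volume_ratio <= 0 || trans_abundance <= 0)
        stop("mixing parameters must be positive")
    p_control <- 1 / (1 + volume_ratio * trans_abundance)
    refs <- lapply(setNames(ORIENTATIONS, ORIENTATIONS),
                   function(o) orientation_refs(loci, o))
    with_seed(seed, {
        is_ctrl <- runif(n_reads) < p_control
        n <- n_reads
        truth <- data.frame(read_id = sprintf("tread_%05d", seq_len(n)),
                            is_control = is_ctrl,
                            orientation = NA_character_,
                            del_A = NA_integer_, del_B = NA_integer_,
                            mh_len = NA_integer_, inserted_seq = "",
                            precise = NA, stringsAsFactors = FALSE)
        reads <- character(n)
        oris <- sample(ORIENTATIONS, n, replace = TRUE,
                       prob = orientation_mix)
        for (i in seq_len(n)) {
            if (is_ctrl[i]) {
                reads[i] <- loci$control$sequence
                next
            }
            o <- oris[i]
            rf <- refs[[o]]
            precise <- runif(1) < p_precise
            if (precise) {
                rA <- 0L; rB <- 0L; ins <- ""
            } else {
                rA <- draw_sizes(resection_law, 1L)
                rB <- draw_sizes(resection_law, 1L)
                ## leave both anchors intact
                rA <- min(rA, rf$junction_left - 25L)
                rB <- min(rB, nchar(rf$right) - 25L)
                ins <- if (runif(1) < p_insertion) {
                    ## untemplated bases: sized and composed so the event
                    ## has a unique canonical decomposition (not
                    ## re-expressible via substitutions of resected bases)
                    if (rA + rB == 1L) {
                        if (rA == 1L) rA <- 2L else rB <- 2L
                    }
                    K <- max(2L, draw_sizes(insertion_law, 1L))
                    if (K == 2L && rA + rB == 2L) K <- 3L
                    if (rA + rB > 0L)
                        random_untethered(rf$template,
                                          rf$junction_left - rA,
                                          rf$junction_left + rB, K)
                    else random_dna(K)
                } else ""
            }
            left <- substr(rf$left, 1L, rf$junction_left - rA)
            right <- substr(rf$right, rB + 1L, nchar(rf$right))
            reads[i] <- paste0(left, ins, right)
            ## canonical annotation on the fused template: deletion of
            ## [jl - rA, jl + rB) on template coordinates, ambiguous bases
            ## attributed to locus A (right-shifted placement)
            tmpl <- rf$template
            can <- canonical_event(tmpl, rf$junction_left - rA,
                                   rf$junction_left + rB, ins, "right")
            j <- rf$junction_left
            dA <- max(0L, j - can$del_start)
            dB <- max(0L, can$del_end - j)
            mh <- if (can$del_end > can$del_start && !nzchar(can$inserted))
                mh_length(tmpl, can$del_start, can$del_end)$mh_len
            else if (can$del_end == can$del_start && !nzchar(can$inserted))
                junction_mh(rf$leftref, rf$junction_left - rA,
                            rf$rightref, rf$junction_right + rB)$mh_len
            else 0L
            truth$orientation[i] <- o
            truth$del_A[i] <- dA
            truth$del_B[i] <- dB
            truth$mh_len[i] <- mh
            truth$inserted_seq[i] <- can$inserted
            truth$precise[i] <- precise && !nzchar(ins)
        }
        reads <- inject_substitutions(reads, error_rate)
        names(reads) <- truth$read_id
        list(reads = reads, truth = truth, loci = loci)
    })
}

#' Call translocation junctions in a read library
#'
#' Each read is tested against the internal-control amplicon, then against
#' the eight candidate templates (four orientation types, read in both
#' orientations); the best global alignment is canonicalized at the
#' junction (ambiguous bases attributed to locus A), producing per-side
#' losses relative to each cut site, junction MH by placement ambiguity,
#' untemplated insertion and a `precise_join` flag.  Reads anchoring fewer
#' than `anchor` matched bases on either locus are reported as unanchored.
#'
#' @param reads named character vector.
#' @param loci a [translocation_loci()] object.
#' @param anchor minimum matched bases required on each side.
#' @param min_identity minimum alignment identity.
#' @return list with `calls` (data.frame: `read_id`, `orientation`,
#'   `del_A`, `del_B`, `mh_len`, `inserted_seq`, `precise`),
#'   `control_count`, `unanchored_count`.
#' @export
call_translocations <- function(reads, loci, anchor = 20L,
                                min_identity = 0.8) {
    refs <- lapply(setNames(ORIENTATIONS, ORIENTATIONS),
                   function(o) orientation_refs(loci, o))
    uniq <- unique(unname(reads))
    idx <- match(unname(reads), uniq)
    ctrl <- loci$control$sequence

    ## control reads: near-exact match to the control amplicon
    is_ctrl_u <- vapply(uniq, function(rd) {
        abs(nchar(rd) - nchar(ctrl)) <= 5 &&
            utils::adist(rd, ctrl) <= 0.1 * nchar(ctrl)
    }, logical(1), USE.NAMES = FALSE)

    ## align every junction candidate against the 8 oriented templates
    junc <- which(!is_ctrl_u)
    best_cfg <- integer(length(uniq))
    alns <- vector("list", 8L)
    qsets <- vector("list", 8L)
    if (length(junc)) {
        q_fwd <- uniq[junc]
        q_rc <- vapply(q_fwd, revcomp, "", USE.NAMES = FALSE)
        scores <- matrix(-Inf, nrow = 8L, ncol = length(junc))
        submat <- Biostrings::nucleotideSubstitutionMatrix(
            match = 2, mismatch = -11, baseOnly = TRUE)
        for (cfg in 1:8) {
            o <- ORIENTATIONS[(cfg - 1L) %/% 2L + 1L]
            rc <- cfg %% 2L == 0L
            qs <- if (rc) q_rc else q_fwd
            a <- Biostrings::pairwiseAlignment(
                pattern = Biostrings::DNAStringSet(qs),
                subject = Biostrings::DNAString(refs[[o]]$template),
                type = "global", substitutionMatrix = submat,
                gapOpening = 12, gapExtension = 1)
            alns[[cfg]] <- a
            qsets[[cfg]] <- qs
            scores[cfg, ] <- Biostrings::score(a)
        }
        best_cfg[junc] <- apply(scores, 2L, which.max)
    }

    classify_one <- function(u) {
        if (is_ctrl_u[u]) return(list(type = "control"))
        cfg <- best_cfg[u]
        k <- match(u, junc)
        o <- ORIENTATIONS[(cfg - 1L) %/% 2L + 1L]
        rf <- refs[[o]]
        a1 <- alns[[cfg]][k]
        call <- call_from_ops(
            alignment_ops(a1, qsets[[cfg]][k])[[1L]],
            Biostrings::nmatch(a1) / nchar(qsets[[cfg]][k]),
            rf$template, merge_gap = 5L, min_identity = min_identity)
        if (call$status == "unaligned") return(list(type = "unanchored"))
        j <- rf$junction_left
        if (call$status == "unedited") {
            s <- j; e <- j; ins <- ""
        } else {
            can <- canonical_event(rf$template, call$del_start,
                                   call$del_end, call$inserted_seq, "right")
            s <- can$del_start; e <- can$del_end; ins <- can$inserted
        }
        ## anchoring: matched bases retained on each locus
        if (min(s, j) < anchor ||
            nchar(rf$template) - max(e, j) < anchor)
            return(list(type = "unanchored"))
        dA <- max(0L, j - s)
        dB <- max(0L, e - j)
        mh <- if (e > s && !nzchar(ins))
            mh_length(rf$template, s, e)$mh_len
        else if (e == s && !nzchar(ins))
            junction_mh(rf$leftref, j - dA, rf$rightref,
                        rf$junction_right + dB)$mh_len
        else 0L
        list(type = "translocation", orientation = o,
             del_A = dA, del_B = dB, mh_len = mh, inserted_seq = ins,
             precise = (dA == 0L && dB == 0L && !nzchar(ins)))
    }

    res <- lapply(seq_along(uniq), classify_one)
    types <- vapply(res, `[[`, "", "type")[idx]
    control_count <- sum(types == "control")
    unanchored_count <- sum(types == "unanchored")
    keep <- which(types == "translocation")
    calls <- if (length(keep)) {
        do.call(rbind, lapply(keep, function(i) {
            r <- res[[idx[i]]]
            data.frame(read_id = names(reads)[i],
                       orientation = r$orientation, del_A = r$del_A,
                       del_B = r$del_B, mh_len = r$mh_len,
                       inserted_seq = r$inserted_seq, precise = r$precise,
                       stringsAsFactors = FALSE)
        }))
    } else data.frame(read_id = character(0), orientation = character(0),
                      del_A = integer(0), del_B = integer(0),
                      mh_len = integer(0), inserted_seq = character(0),
                      precise = logical(0), stringsAsFactors = FALSE)
    list(calls = calls, control_count = control_count,
         unanchored_count = unanchored_count)
}

#' Relative translocation level against the internal control
#'
#' `level = (translocation_reads / control_reads) / transfection_eff`,
#' reported in total and per orientation type; the constant PCR volume
#' mixing of the assay design cancels in fold changes between conditions.
#'
#' @param calls calls data.frame from [call_translocations()] (or a count).
#' @param control_count internal-control read count (> 0).
#' @param transfection_eff in (0, 1].
#' @return list of class `RelativeTranslocationLevel` with `level`,
#'   `by_orientation`, `translocation_reads`, `control_reads`,
#'   `transfection_eff`.
#' @export
relative_level <- function(calls, control_count, transfection_eff = 1) {
    if (control_count <= 0) stop("control read count must be positive")
    stopifnot(transfection_eff > 0, transfection_eff <= 1)
    n <- if (is.data.frame(calls)) nrow(calls) else as.integer(calls)
    by_o <- if (is.data.frame(calls))
        vapply(ORIENTATIONS, function(o)
            sum(calls$orientation == o) / control_count / transfection_eff,
            numeric(1))
    else NULL
    out <- list(level = n / control_count / transfection_eff,
                by_orientation = by_o,
                translocation_reads = n, control_reads = control_count,
                transfection_eff = transfection_eff)
    class(out) <- "RelativeTranslocationLevel"
    out
}

#' Fold change between two relative translocation levels
#' @param level_a,level_b `RelativeTranslocationLevel` objects (a / b).
#' @export
level_fold_change <- function(level_a, level_b) {
    if (level_b$level == 0) stop("comparator level is zero")
    level_a$level / level_b$level
}

#' Junction summary for translocation calls
#'
#' Median per-side and total deletion lengths, MH usage and the precise
#' join fraction, overall and per orientation.
#' @param calls calls data.frame from [call_translocations()].
#' @return list with `overall` and `by_orientation` data.frames.
#' @export
translocation_junction_summary <- function(calls) {
    if (nrow(calls) == 0) stop("no translocation calls")
    summ <- function(d) data.frame(
        n = nrow(d),
        median_del_A = median(d$del_A),
        median_del_B = median(d$del_B),
        median_del_total = median(d$del_A + d$del_B),
        mh_usage = mean(d$mh_len >= 1L),
        precise_fraction = mean(d$precise))
    by_o <- do.call(rbind, lapply(split(calls, calls$orientation), summ))
    by_o <- cbind(orientation = rownames(by_o), by_o)
    rownames(by_o) <- NULL
    list(overall = summ(calls), by_orientation = by_o)
}
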