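#' Reference invasion/termination amplicon for TD clone analysis
#'
#' The invasion amplicon (primer pair F1/R1 analog) spans the nested GFP
#' copy of a GFP-RFP+ tandem-duplication product; the termination amplicon
#' (F2/R2) spans the third GFP copy.  Both are represented by the reporter
#' window around `ISceGFP` with `flank` bases on each side.
#'
#' @param reporter an SCR `ReporterConstruct`.
#' @param flank flank length on each side of `ISceGFP`.
#' @return list with `seq`, `start` (0-based window start on the reporter)
#'   and `break_offset` (break position within the window).
#' @export
td_amplicon <- function(reporter, flank = 150L) {
    r <- feature_range(reporter, "ISceGFP")
    start <- r[1] - flank
    end <- r[2] + flank
    list(seq = substr(reporter$sequence, start + 1L, end),
         start = start,
         break_offset = reporter$break_pos - start)
}

## legal MH-entry windows for INV3 (0-based reporter coordinates of the
## fusion target): non-GFP sequence upstream of RFP exon B, split into a
## far-upstream window (entries upstream of the TrGFP repeat) and the
## TrGFP-to-exon-B gap, so the nested GFP is genuinely truncated
inv3_entry_windows <- function(reporter, tail_len, brk = reporter$break_pos,
                               span_range = c(8100L, 11900L)) {
    tr <- feature_range(reporter, "TrGFP")
    exB <- feature_range(reporter, "RFP_exonB")
    wins <- list(upstream = c(40L, tr[1] - tail_len - 10L),
                 gap = c(tr[2] + 50L, exB[1] - 50L))
    wins <- Filter(function(w) w[2] >= w[1], wins)
    ## clip to the span range the assay resolves (span = brk - entry)
    clip <- c(brk - span_range[2], brk - span_range[1])
    clipped <- Filter(function(w) w[2] >= w[1],
                      lapply(wins, function(w)
                          c(max(w[1], clip[1]), min(w[2], clip[2]))))
    if (length(clipped)) clipped else wins
}

#' Simulate paired TD clone amplicons (invasion + termination)
#'
#' Emits, per clone, a Sanger-style invasion amplicon and termination
#' amplicon with per-clone ground truth, drawn from a class mixture over
#' the INV1/INV2/INV3 x TER1/TER2/TER3 grid:
#' \itemize{
#'   \item INV1/TER1: the amplicon equals the reference (intact I-SceI
#'     site, no indel at the break point);
#'   \item INV2/TER2: the reference with an indel at the break point;
#'     an INV2xTER2 clone carries the identical indel at both junctions
#'     with probability `shared_indel_prob` (the two-round strand invasion
#'     signature), otherwise independent indels;
#'   \item INV3: the amplicon retains only the sequence 5' of the break,
#'     fused at a (possibly zero-length) microhomology to reporter
#'     sequence upstream of RFP exon B; TER3 mirrors this on the 3' side,
#'     fused to reporter sequence upstream of `ISceGFP`.
#' }
#' MH-entry points are chosen among positions whose natural junction
#' ambiguity equals the MH length drawn from `mh_entry_law` (falling back
#' to the nearest shorter length with available positions), so truth MH is
#' exactly the placement-ambiguity MH a classifier recovers.
#'
#' @param reporter SCR `ReporterConstruct`.
#' @param site `TargetSite` or 0-based break position (defaults to the
#'   reporter's I-SceI break point).
#' @param class_mix named probabilities over `"INV1.TER1"`, ...,
#'   `"INV3.TER3"` (names `INVi.TERj`); unnamed single numbers recycle.
#' @param n_clones number of clones.
#' @param mh_entry_law size law for INV3/TER3 fusion MH lengths
#'   (default geometric, mean 2, capped at 8).
#' @param processed_length_law size law minus 1 for bases lost from the
#'   invading end before the fusion (default geometric mean 5, so
#'   processed lengths start at 0).
#' @param indel_law size law for INV2/TER2 break-point indels.
#' @param shared_indel_prob probability an INV2xTER2 clone shares one
#'   identical indel across both junctions.
#' @param flank amplicon flank (see [td_amplicon()]).
#' @param error_rate per-base substitution rate.
#' @param seed integer seed.
#' @return list with `invasion`, `termination` (named character vectors),
#'   `truth` (data.frame) and `amplicon` (the [td_amplicon()] used).
#' @export
simulate_td_clones <- function(reporter, site = NULL,
                               class_mix = c(INV1.TER1 = 0.35,
                                             INV2.TER2 = 0.35,
                                             INV3.TER1 = 0.10,
                                             INV3.TER2 = 0.10,
                                             INV3.TER3 = 0.10),
                               n_clones = 50L,
                               mh_entry_law = list(type = "geometric",
                                                   mean = 2),
                               processed_length_law = list(
                                   type = "geometric", mean = 5),
                               indel_law = list(type = "geometric",
                                                mean = 2),
                               shared_indel_prob = 0.87,
                               flank = 150L, error_rate = 0, seed = 1L) {
    stopifnot(reporter$type == "scr_rfp")
    if (abs(sum(class_mix) - 1) > 1e-8)
        stop("class_mix must sum to 1")
    bad <- !grepl("^INV[123]\\.TER[123]$", names(class_mix))
    if (any(bad)) stop("class_mix names must be INVi.TERj")
    amp <- td_amplicon(reporter, flank)
    brk <- if (is.null(site)) reporter$break_pos
           else if (inherits(site, "TargetSite")) site$cut_pos
           else as.integer(site)
    brk_amp <- brk - amp$start
    ref <- reporter$sequence

    with_seed(seed, {
        cls <- sample(names(class_mix), n_clones, replace = TRUE,
                      prob = class_mix)
        inv_cls <- sub("\\..*", "", cls)
        ter_cls <- sub(".*\\.", "", cls)
        inv <- character(n_clones)
        ter <- character(n_clones)
        truth <- data.frame(
            clone_id = sprintf("clone_%04d", seq_len(n_clones)),
            inv_class = inv_cls, ter_class = ter_cls,
            inv_del_start = NA_integer_, inv_del_end = NA_integer_,
            inv_inserted = "", shared_indel = FALSE,
            mh_len = NA_integer_, processed_len = NA_integer_,
            entry_pos = NA_integer_, entry_distance = NA_integer_,
            td_span = NA_integer_, stringsAsFactors = FALSE)

        for (i in seq_len(n_clones)) {
            ## ---- invasion side
            if (inv_cls[i] == "INV1") {
                inv[i] <- amp$seq
            } else if (inv_cls[i] == "INV2") {
                ev <- draw_break_indel(amp$seq, brk_amp, indel_law)
                inv[i] <- apply_indel(amp$seq, ev$del_start, ev$del_end,
                                      ev$inserted)
                truth$inv_del_start[i] <- ev$del_start
                truth$inv_del_end[i] <- ev$del_end
                truth$inv_inserted[i] <- ev$inserted
            } else {    # INV3
                proc <- draw_sizes(processed_length_law, 1L) - 1L
                f <- brk_amp - proc
                tail_len <- nchar(amp$seq) - f
                wins <- inv3_entry_windows(reporter, tail_len, brk)
                m <- min(draw_sizes(mh_entry_law, 1L), 8L)
                pick <- pick_entry(amp$seq, f, ref, wins, m,
                                   side = "invasion")
                e <- pick$entry
                ## canonical (right-maximal) fusion placement
                jm <- junction_mh(amp$seq, f, ref, e)
                fs <- jm$left_end
                es <- jm$right_start
                inv[i] <- paste0(substr(amp$seq, 1L, f),
                                 substr(ref, e + 1L, e + tail_len))
                truth$mh_len[i] <- jm$mh_len
                truth$processed_len[i] <- brk_amp - fs
                truth$entry_pos[i] <- es
                truth$entry_distance[i] <- reporter$allelic_pos - es
                truth$td_span[i] <- brk - es
            }
            ## ---- termination side
            if (ter_cls[i] == "TER1") {
                ter[i] <- amp$seq
            } else if (ter_cls[i] == "TER2") {
                share <- inv_cls[i] == "INV2" &&
                    runif(1) < shared_indel_prob
                ev <- if (share)
                    list(del_start = truth$inv_del_start[i],
                         del_end = truth$inv_del_end[i],
                         inserted = truth$inv_inserted[i])
                else draw_break_indel(amp$seq, brk_amp, indel_law)
                ter[i] <- apply_indel(amp$seq, ev$del_start, ev$del_end,
                                      ev$inserted)
                truth$shared_indel[i] <- share
            } else {    # TER3: mirror fusion on the 5' side
                proc <- draw_sizes(processed_length_law, 1L) - 1L
                f <- brk_amp + proc          # retained suffix starts here
                head_len <- f
                tr <- feature_range(reporter, "TrGFP")
                isce <- feature_range(reporter, "ISceGFP")
                wins <- list(upstream = c(tr[2] + 50L + head_len,
                                          isce[1] - 200L))
                m <- min(draw_sizes(mh_entry_law, 1L), 8L)
                pick <- pick_entry(amp$seq, f, ref, wins, m,
                                   side = "termination")
                e <- pick$entry
                ter[i] <- paste0(substr(ref, e - head_len + 1L, e),
                                 substr(amp$seq, f + 1L, nchar(amp$seq)))
            }
        }
        inv <- inject_substitutions(inv, error_rate)
        ter <- inject_substitutions(ter, error_rate)
        names(inv) <- truth$clone_id
        names(ter) <- truth$clone_id
        list(invasion = inv, termination = ter, truth = truth,
             amplicon = amp)
    })
}

## indel at the break point whose canonical placement stays within the
## break window; terminal insertion bases chosen not to extend homology
draw_break_indel <- function(ref_amp, brk, law, window = 10L) {
    repeat {
        if (runif(1) < 0.7) {     # deletion
            L <- min(draw_sizes(law, 1L), window - 1L)
            u <- sample.int(L + 1L, 1L) - 1L
            can <- canonical_event(ref_amp, brk - u, brk - u + L, "")
            if (abs(can$del_start - brk) <= window &&
                abs(can$del_end - brk) <= window)
                return(list(del_start = can$del_start,
                            del_end = can$del_end, inserted = ""))
        } else {                  # insertion
            K <- draw_sizes(law, 1L)
            ins <- random_dna(K)
            can <- canonical_event(ref_amp, brk, brk, ins)
            if (abs(can$del_start - brk) <= window)
                return(list(del_start = can$del_start,
                            del_end = can$del_end,
                            inserted = can$inserted))
        }
    }
}

## choose a fusion entry point whose natural junction ambiguity equals m
## (falling back towards smaller m when no position qualifies)
pick_entry <- function(amp_seq, f, ref, windows, m, side) {
    positions <- unlist(lapply(windows, function(w)
        if (w[2] >= w[1]) seq.int(w[1], w[2]) else integer(0)))
    mh <- vapply(positions, function(e) {
        if (side == "invasion")
            junction_mh(amp_seq, f, ref, e)$mh_len
        else
            junction_mh(ref, e, amp_seq, f)$mh_len
    }, integer(1))
    for (mm in seq(m, 0L)) {
        cand <- positions[mh == mm]
        if (length(cand))
            return(list(entry = cand[sample.int(length(cand), 1L)],
                        mh = mm))
    }
    stop("no legal entry point")   # unreachable: m = 0 always has candidates
}

#' Classify the invasion junction of a TD clone
#'
#' INV1: the clone matches the reference invasion amplicon with no indel;
#' INV2: single indel whose canonical placement lies within
#' `break_window` bp of the break; INV3: chimeric clone retaining only the
#' amplicon sequence 5' of the break, fused (at a microhomology) to
#' reporter sequence upstream of RFP exon B.  For INV3 the fusion is
#' placed right-maximally (ambiguous bases assigned to the GFP side), and
#' `processed_len` (bases lost from the invading end relative to the
#' break), `entry_distance` (allelic break position minus fusion target;
#' positive = upstream) and `mh_len` are reported.
#'
#' @param clone_seq invasion amplicon sequence.
#' @param reporter SCR `ReporterConstruct`.
#' @param site `TargetSite` or break position (default: reporter break).
#' @param flank amplicon flank used when generating/sequencing the clones.
#' @param break_window INV2 break-point window (bp).
#' @param min_identity identity threshold for the whole-amplicon
#'   alignment.
#' @return list with `class` ("INV1", "INV2", "INV3" or "unclassified")
#'   and details (indel fields for INV2; `mh_len`, `processed_len`,
#'   `entry_pos`, `entry_distance` for INV3).
#' @export
classify_invasion <- function(clone_seq, reporter, site = NULL,
                              flank = 150L, break_window = 10L,
                              min_identity = 0.8) {
    classify_td_side(clone_seq, reporter, site, flank, break_window,
                     min_identity, side = "invasion")
}

#' Classify the termination junction of a TD clone
#'
#' Mirror of [classify_invasion()] on the third GFP copy: TER3 retains
#' only the amplicon sequence 3' of the break, fused on its 5' side to
#' reporter sequence upstream of `ISceGFP`.
#' @inheritParams classify_invasion
#' @export
classify_termination <- function(clone_seq, reporter, site = NULL,
                                 flank = 150L, break_window = 10L,
                                 min_identity = 0.8) {
    classify_td_side(clone_seq, reporter, site, flank, break_window,
                     min_identity, side = "termination")
}

classify_td_side <- function(clone_seq, reporter, site, flank,
                             break_window, min_identity, side) {
    amp <- td_amplicon(reporter, flank)
    brk <- if (is.null(site)) reporter$break_pos
           else if (inherits(site, "TargetSite")) site$cut_pos
           else as.integer(site)
    brk_amp <- brk - amp$start
    prefix <- if (side == "invasion") 1L else 3L   # class number suffix

    ## step 1: whole-amplicon alignment
    call <- tryCatch(
        align_and_call(clone_seq, amp$seq, brk_amp,
                       min_identity = min_identity),
        error = function(e) empty_call("unaligned"))
    if (call$status == "unedited")
        return(list(class = paste0(if (side == "invasion") "INV" else "TER",
                                   "1")))
    if (call$status %in% c("deletion", "insertion", "complex")) {
        ## a genuine break-point indel is small and near the break; large
        ## or distant events are candidate chimeric fusions (class 3)
        near <- !is.na(call$del_start) &&
            abs(call$del_start - brk_amp) <= break_window &&
            abs(call$del_end - brk_amp) <= break_window &&
            nchar(call$inserted_seq) <= 2L * break_window
        if (near)
            return(list(class = paste0(if (side == "invasion") "INV"
                                       else "TER", "2"),
                        del_start = call$del_start,
                        del_end = call$del_end,
                        inserted_seq = call$inserted_seq,
                        net_indel = call$net_indel))
    }

    ## step 2: split (fusion) analysis
    ref <- reporter$sequence
    if (side == "invasion") {
        f <- matched_prefix_len(clone_seq, amp$seq)
        if (f < 30L)
            return(list(class = "unclassified", reason = "no anchor"))
        tail_seq <- substr(clone_seq, f + 1L, nchar(clone_seq))
        if (nchar(tail_seq) < 24L)
            return(list(class = "unclassified", reason = "short tail"))
        seed <- substr(tail_seq, 1L, 24L)
        hit <- find_seed(seed, ref)
        if (is.na(hit))
            return(list(class = "unclassified", reason = "no fusion target"))
        e <- hit
        jm <- junction_mh(amp$seq, f, ref, e)
        fs <- jm$left_end
        es <- jm$right_start
        exB <- feature_range(reporter, "RFP_exonB")
        if (es >= exB[1])
            return(list(class = "unclassified",
                        reason = "fusion target not upstream of exon B"))
        return(list(class = "INV3", mh_len = jm$mh_len,
                    mh_seq = jm$mh_seq,
                    processed_len = brk_amp - fs,
                    entry_pos = es,
                    entry_distance = reporter$allelic_pos - es))
    } else {
        fl <- matched_suffix_len(clone_seq, amp$seq)
        if (fl < 30L)
            return(list(class = "unclassified", reason = "no anchor"))
        f <- nchar(amp$seq) - fl             # retained suffix start
        head_seq <- substr(clone_seq, 1L, nchar(clone_seq) - fl)
        if (nchar(head_seq) < 24L)
            return(list(class = "unclassified", reason = "short head"))
        seed <- substr(head_seq, nchar(head_seq) - 23L, nchar(head_seq))
        hit <- find_seed(seed, ref)
        if (is.na(hit))
            return(list(class = "unclassified", reason = "no fusion target"))
        e <- hit + 24L                       # fusion boundary (exclusive)
        jm <- junction_mh(ref, e, amp$seq, f)
        ## canonical (left-minimal): ambiguous bases assigned to the
        ## retained GFP suffix
        fs <- f - jm$back
        es <- e - jm$back
        isce <- feature_range(reporter, "ISceGFP")
        if (es >= isce[1])
            return(list(class = "unclassified",
                        reason = "fusion target not upstream of ISceGFP"))
        return(list(class = "TER3", mh_len = jm$mh_len,
                    mh_seq = jm$mh_seq,
                    processed_len = fs - brk_amp,
                    entry_pos = es))
    }
}

## longest matching prefix/suffix tolerating isolated substitutions:
## stops at the first window of dense mismatch (>= 8 of 16)
matched_prefix_len <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    av <- charToRaw(substr(a, 1L, n))
    bv <- charToRaw(substr(b, 1L, n))
    mism <- av != bv
    run_boundary(mism)
}

matched_suffix_len <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    av <- rev(charToRaw(substr(a, nchar(a) - n + 1L, nchar(a))))
    bv <- rev(charToRaw(substr(b, nchar(b) - n + 1L, nchar(b))))
    run_boundary(av != bv)
}

run_boundary <- function(mism, win = 16L, max_mm = 8L) {
    n <- length(mism)
    if (n == 0L) return(0L)
    cs <- cumsum(mism)
    for (i in seq_len(n)) {
        if (mism[i]) {
            hi <- min(n, i + win - 1L)
            dense <- cs[hi] - (if (i > 1L) cs[i - 1L] else 0L)
            if (dense >= max_mm || dense == hi - i + 1L)
                return(i - 1L)
        }
    }
    n
}

## locate a seed in the reference, allowing up to 2 mismatches
find_seed <- function(seed, ref) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(seed),
                                  Biostrings::DNAString(ref),
                                  max.mismatch = 2)
    if (length(m) == 0L) return(NA_integer_)
    ## prefer an exact hit when several
    if (length(m) > 1L) {
        ex <- Biostrings::matchPattern(Biostrings::DNAString(seed),
                                       Biostrings::DNAString(ref))
        if (length(ex) >= 1L) return(Biostrings::start(ex)[1L] - 1L)
    }
    Biostrings::start(m)[1L] - 1L
}

#' Classify a set of paired TD clones
#'
#' Runs [classify_invasion()] and [classify_termination()] on each clone
#' pair and annotates INV2/TER2 pairs carrying the identical indel
#' (`shared_indel_with_ter`).
#'
#' @param invasion,termination named character vectors (paired by name).
#' @param reporter,site,flank,break_window,min_identity see
#'   [classify_invasion()].
#' @return data.frame with one row per clone: classes, INV2 indel fields,
#'   INV3 MH/processing fields, `shared_indel_with_ter`, `td_span`.
#' @export
classify_td_clones <- function(invasion, termination, reporter,
                               site = NULL, flank = 150L,
                               break_window = 10L, min_identity = 0.8) {
    stopifnot(length(invasion) == length(termination))
    ids <- names(invasion) %||% sprintf("clone_%04d", seq_along(invasion))
    rows <- lapply(seq_along(invasion), function(i) {
        ci <- classify_invasion(invasion[[i]], reporter, site, flank,
                                break_window, min_identity)
        ct <- classify_termination(termination[[i]], reporter, site, flank,
                                   break_window, min_identity)
        shared <- identical(ci$class, "INV2") &&
            identical(ct$class, "TER2") &&
            identical(ci$del_start, ct$del_start) &&
            identical(ci$del_end, ct$del_end) &&
            identical(ci$inserted_seq, ct$inserted_seq)
        data.frame(clone_id = ids[i],
                   inv_class = ci$class, ter_class = ct$class,
                   inv_del_start = ci$del_start %||% NA_integer_,
                   inv_del_end = ci$del_end %||% NA_integer_,
                   inv_inserted = ci$inserted_seq %||% "",
                   mh_len = ci$mh_len %||% NA_integer_,
                   processed_len = ci$processed_len %||% NA_integer_,
                   entry_pos = ci$entry_pos %||% NA_integer_,
                   entry_distance = ci$entry_distance %||% NA_integer_,
                   shared_indel_with_ter = shared,
                   stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, rows)
    calls$td_span <- vapply(seq_len(nrow(calls)), function(i)
        tryCatch(td_span(calls[i, ], reporter, site),
                 error = function(e) NA_integer_), integer(1))
    calls
}

#' Tandem-duplication span of a classified TD product
#'
#' For repeat-directed products (INV1/INV2, two-round strand invasion
#' consistent) the span is the distance between the allelic positions of
#' the break in the two GFP repeats (~10 kb at full scale); for
#' MH-mediated products (INV3) the span is shifted by the entry distance:
#' `span = break_pos - entry_pos`.
#'
#' @param call one-row data.frame or list with `inv_class` (and
#'   `entry_pos` for INV3).
#' @param reporter SCR `ReporterConstruct`.
#' @param site optional `TargetSite`/break position override.
#' @return span in bp.
#' @export
td_span <- function(call, reporter, site = NULL) {
    brk <- if (is.null(site)) reporter$break_pos
           else if (inherits(site, "TargetSite")) site$cut_pos
           else as.integer(site)
    cls <- as.character(call$inv_class)
    if (is.na(cls) || cls == "unclassified")
        stop("cannot compute TD span for an unclassified call")
    if (cls %in% c("INV1", "INV2"))
        return(brk - reporter$allelic_pos)
    if (cls == "INV3") {
        if (is.na(call$entry_pos)) stop("INV3 call lacks an entry point")
        return(as.integer(brk - call$entry_pos))
    }
    stop("unknown invasion class: ", cls)
}

#' Per-class TD frequencies from an overall GFP-RFP+ frequency
#'
#' `class_freq = overall_rfp_only_freq x class proportion among analyzed
#' clones`: the absolute per-class cell frequency.
#'
#' @param overall_rfp_only_freq overall GFP-RFP+ cell frequency, in
#'   `[0, 1]` (or percent — units are preserved).
#' @param calls data.frame from [classify_td_clones()] (or any with
#'   `inv_class`/`ter_class`).
#' @return list of class `TDClassFrequency` with `class_counts`,
#'   `class_prop`, `class_freq`, `overall`.
#' @export
class_frequencies <- function(overall_rfp_only_freq, calls) {
    ok <- calls$inv_class != "unclassified" &
        calls$ter_class != "unclassified"
    calls <- calls[ok, , drop = FALSE]
    if (nrow(calls) == 0) stop("no classified clones")
    key <- paste(calls$inv_class, calls$ter_class, sep = ".")
    counts <- table(key)
    prop <- counts / sum(counts)
    out <- list(overall = overall_rfp_only_freq,
                n_clones = nrow(calls),
                class_counts = counts,
                class_prop = prop,
                class_freq = overall_rfp_only_freq * prop,
                inv_prop = table(calls$inv_class) / nrow(calls))
    class(out) <- "TDClassFrequency"
    out
}

#' @export
print.TDClassFrequency <- function(x, ...) {
    cat("TD class frequencies (overall GFP-RFP+ =", x$overall, ")\n")
    df <- data.frame(class = names(x$class_counts),
                     count = as.vector(x$class_counts),
                     proportion = round(as.vector(x$class_prop), 4),
                     frequency = signif(as.vector(x$class_freq), 4))
    print(df, row.names = FALSE)
    invisible(x)
}

#' Ratio of GFP-RFP+ (TD) to GFP+RFP+ (LTGC) frequencies
#' @param freq_rfp_only,freq_ltgc frequencies (same units).
#' @return the ratio; error when `freq_ltgc` is zero.
#' @export
rfp_to_ltgc_ratio <- function(freq_rfp_only, freq_ltgc) {
    if (any(freq_ltgc <= 0)) stop("LTGC frequency must be positive")
    freq_rfp_only / freq_ltgc
}
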