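#' Outcome mixture for simulated amplicon libraries
#'
#' Describes the distribution of repair outcomes at a cut/nick site:
#' the class mixture (unedited / deletion / insertion / complex), size laws
#' for deletions and insertions, the probability that deletion endpoints are
#' biased towards flanks carrying microhomology, and a per-base substitution
#' error rate emulating sequencing noise.
#'
#' The default deletion-size law is a two-component mixture: a short
#' geometric component (mean 4 bp) and a shifted "resection" tail starting
#' at 11 bp (mean 30 bp), emulating the contrast between sub-11-bp and
#' 11-80-bp deletion classes.  All parameters are configuration, not
#' constants.
#'
#' @param p_unedited,p_deletion,p_insertion,p_complex class probabilities
#'   (must sum to 1).
#' @param deletion_size_law list: `list(type = "mixture", p_short, short_mean,
#'   long_shift, long_mean)` or `list(type = "fixed", size)` or
#'   `list(type = "geometric", mean)`.
#' @param insertion_size_law list as above (default geometric, mean 2).
#' @param mh_bias probability that a deletion's placement is chosen, among
#'   the placements of its size at the cut, to carry >= 1 bp of flank MH.
#' @param error_rate per-base substitution probability.
#' @return object of class `OutcomeMixture`.
#' @export
outcome_mixture <- function(p_unedited = 0.3, p_deletion = 0.5,
                            p_insertion = 0.15, p_complex = 0.05,
                            deletion_size_law = list(type = "mixture",
                                                     p_short = 0.8,
                                                     short_mean = 4,
                                                     long_shift = 11,
                                                     long_mean = 30),
                            insertion_size_law = list(type = "geometric",
                                                      mean = 2),
                            mh_bias = 0.5,
                            error_rate = 0) {
    p <- c(p_unedited, p_deletion, p_insertion, p_complex)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("class probabilities must be non-negative and sum to 1")
    mix <- list(p_unedited = p_unedited, p_deletion = p_deletion,
                p_insertion = p_insertion, p_complex = p_complex,
                deletion_size_law = deletion_size_law,
                insertion_size_law = insertion_size_law,
                mh_bias = mh_bias, error_rate = error_rate)
    class(mix) <- "OutcomeMixture"
    mix
}

draw_sizes <- function(law, n) {
    if (n == 0L) return(integer(0))
    out <- switch(law$type,
        fixed = rep(as.integer(law$size), n),
        geometric = rgeom(n, 1 / law$mean) + 1L,
        mixture = {
            short <- rgeom(n, 1 / law$short_mean) + 1L
            shift <- law$long_shift %||% 11L
            long_mean <- law$long_mean %||% 30
            long <- shift + rgeom(n, 1 / (long_mean - shift + 1))
            ifelse(runif(n) < law$p_short, short, long)
        },
        stop("unknown size law type: ", law$type))
    as.integer(out)
}

#' Simulate an amplicon sequencing library around a cut site
#'
#' Emits `n_reads` amplicon reads spanning `window` bases on each side of
#' the cut, drawn from an [outcome_mixture()], together with a per-read
#' ground-truth table.  Deletions span the cut (uniformly positioned over
#' the placements covering it, optionally biased towards MH-bearing
#' placements); insertions are placed at the cut; complex events combine a
#' deletion with an untemplated insertion whose terminal bases are chosen
#' not to extend flank homology, so every truth record has a unique
#' canonical placement.  Truth coordinates are canonicalized with
#' [canonical_event()] (left-aligned), i.e. the same convention the caller
#' reports.
#'
#' @param reference reference sequence (character) or `ReporterConstruct`.
#' @param site `TargetSite` (or a bare 0-based cut position).
#' @param mix an [outcome_mixture()].
#' @param n_reads number of reads.
#' @param window bases retained on each side of the cut (>= 150
#'   recommended).
#' @param seed integer seed; same seed and configuration give byte-identical
#'   output.
#' @return list with `reads` (named character vector), `truth` (data.frame:
#'   `read_id`, `class`, `del_start`, `del_end`, `del_len`, `inserted_seq`,
#'   `net_indel`, `mh_len`; coordinates relative to `reference_window`),
#'   `reference_window`, `cut_offset` and `window_start` (offset of the
#'   window on the full reference).
#' @export
simulate_amplicon_library <- function(reference, site, mix, n_reads,
                                      window = 150L, seed = 1L) {
    if (inherits(reference, "ReporterConstruct"))
        reference <- reference$sequence
    cut <- if (inherits(site, "TargetSite")) site$cut_pos else as.integer(site)
    n <- nchar(reference)
    if (cut - window < 0 || cut + window > n)
        stop("amplicon window exceeds the reference")
    if (n_reads < 1) stop("n_reads must be >= 1")
    win_start <- cut - window
    ref_win <- substr(reference, win_start + 1L, cut + window)
    cut_off <- window   # cut position within the window

    with_seed(seed, {
        classes <- sample(c("unedited", "deletion", "insertion", "complex"),
                          n_reads, replace = TRUE,
                          prob = c(mix$p_unedited, mix$p_deletion,
                                   mix$p_insertion, mix$p_complex))
        reads <- character(n_reads)
        truth <- data.frame(
            read_id = sprintf("read_%05d", seq_len(n_reads)),
            class = classes,
            del_start = NA_integer_, del_end = NA_integer_,
            del_len = 0L, inserted_seq = "", net_indel = 0L,
            mh_len = 0L, stringsAsFactors = FALSE)

        max_del <- 2L * window - 40L   # keep >= 20 bp anchors on both sides
        for (i in seq_len(n_reads)) {
            cl <- classes[i]
            if (cl == "unedited") {
                reads[i] <- ref_win
                next
            }
            if (cl == "deletion" || cl == "complex") {
                L <- min(draw_sizes(mix$deletion_size_law, 1L), max_del)
                ## compound (delins) events need >= 3 bp lost so the
                ## alignment cannot re-express them as substitutions
                if (cl == "complex") L <- max(L, 3L)
                ## candidate placements covering (or abutting) the cut
                us <- 0:L
                starts <- pmax(20L, pmin(cut_off - us, 2L * window - 20L - L))
                starts <- unique(starts)
                if (cl == "deletion" && runif(1) < mix$mh_bias) {
                    mhs <- vapply(starts, function(s)
                        mh_length(ref_win, s, s + L)$mh_len, integer(1))
                    cand <- starts[mhs >= 1L]
                    s <- if (length(cand))
                        cand[sample.int(length(cand), 1L)]
                    else starts[sample.int(length(starts), 1L)]
                } else {
                    s <- starts[sample.int(length(starts), 1L)]
                }
                e <- s + L
                ins <- ""
                if (cl == "complex") {
                    K <- max(3L, draw_sizes(mix$insertion_size_law, 1L) + 1L)
                    if (K == L) K <- K + 1L      # net 0 would be pure subs
                    ins <- random_untethered(ref_win, s, e, K)
                }
                ev <- canonical_event(ref_win, s, e, ins)
                reads[i] <- apply_indel(ref_win, s, e, ins)
                truth$del_start[i] <- ev$del_start
                truth$del_end[i] <- ev$del_end
                truth$del_len[i] <- L
                truth$inserted_seq[i] <- ev$inserted
                truth$net_indel[i] <- nchar(ins) - L
                truth$mh_len[i] <- ev$mh_len
            } else {            # insertion
                K <- draw_sizes(mix$insertion_size_law, 1L)
                ins <- random_dna(K)
                ev <- canonical_event(ref_win, cut_off, cut_off, ins)
                reads[i] <- apply_indel(ref_win, cut_off, cut_off, ins)
                truth$del_start[i] <- ev$del_start
                truth$del_end[i] <- ev$del_end
                truth$inserted_seq[i] <- ev$inserted
                truth$net_indel[i] <- K
            }
        }
        pre_error <- reads
        reads <- inject_substitutions(reads, mix$error_rate)
        names(reads) <- truth$read_id
        list(reads = reads, truth = truth, reference_window = ref_win,
             cut_offset = cut_off, window_start = win_start,
             pre_error_reads = setNames(pre_error, truth$read_id))
    })
}

## untemplated insertion for a compound event deleting [s, e): every
## inserted base differs from the reference base it could mismatch-align
## to at either gap boundary, and the terminal bases do not extend flank
## homology, so the event has a unique canonical decomposition
random_untethered <- function(ref, s, e, k) {
    bases <- c("A", "C", "G", "T")
    n <- nchar(ref)
    avoid_at <- function(i) {
        ## 0-based reference positions the i-th inserted base (1-based)
        ## would face when aligned at the left or right gap boundary
        p <- c(s + i - 1L, e - k + i - 1L)
        p <- p[p >= 0L & p < n]
        substring(ref, p + 1L, p + 1L)
    }
    ch <- vapply(seq_len(k), function(i)
        sample(setdiff(bases, avoid_at(i)), 1L), character(1))
    ## terminal non-extension of flank homology
    left_flank <- if (s > 0) substr(ref, s, s) else ""
    after <- if (e < n) substr(ref, e + 1L, e + 1L) else ""
    first_deleted <- substr(ref, s + 1L, s + 1L)
    last_deleted <- substr(ref, e, e)
    ch[1] <- sample(setdiff(bases, c(avoid_at(1L), after, first_deleted)), 1L)
    ch[k] <- sample(setdiff(bases, c(avoid_at(k), left_flank,
                                     last_deleted)), 1L)
    paste(ch, collapse = "")
}

#' Write reads as FASTQ (constant Q40 qualities)
#'
#' @param reads named character vector or `DNAStringSet`.
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
    dna <- Biostrings::DNAStringSet(reads)
    qual <- Biostrings::BStringSet(vapply(Biostrings::width(dna),
                                          function(w) strrep("I", w),
                                          character(1)))
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = qual)
    invisible(path)
}

#' Read a FASTQ file as a named character vector
#' @param path FASTQ path.
#' @export
read_fastq <- function(path) {
    dna <- Biostrings::readDNAStringSet(path, format = "fastq")
    setNames(as.character(dna), names(dna))
}

#' Simulate FACS event counts for a reporter assay
#'
#' Cells are transfected with probability `transfection_eff`; transfected
#' cells acquire each reporter event (GFP+RFP-, GFP+RFP+, GFP-RFP+) with
#' the corresponding `true_freqs` probability, and all cells additionally
#' show background events at `background_freqs`.  A parallel untransfected
#' background sample of `n_background` cells is drawn from
#' `background_freqs` alone.  Downstream background correction and
#' transfection-efficiency normalization ([normalize_frequency()]) are
#' unbiased for `true_freqs` under this model.
#'
#' @param true_freqs named numeric: `stgc` (GFP+RFP-), `ltgc` (GFP+RFP+),
#'   `rfp_only` (GFP-RFP+); frequencies among transfected cells.
#' @param n_cells cells acquired in the transfected sample.
#' @param background_freqs same shape; background event frequencies.
#' @param transfection_eff fraction of cells transfected, in (0, 1].
#' @param n_background cells acquired in the background sample.
#' @param seed integer seed.
#' @return data.frame with one row per sample (`transfected`,
#'   `background`) and columns `n_gfp_rfpneg`, `n_gfp_rfppos`,
#'   `n_gfpneg_rfp`, `n_total`, `transfection_eff`.
#' @export
simulate_facs <- function(true_freqs, n_cells,
                          background_freqs = c(stgc = 0, ltgc = 0,
                                               rfp_only = 0),
                          transfection_eff = 1, n_background = n_cells,
                          seed = 1L) {
    stopifnot(all(true_freqs >= 0), all(true_freqs <= 1),
              transfection_eff > 0, transfection_eff <= 1)
    tf <- true_freqs[c("stgc", "ltgc", "rfp_only")]
    bg <- background_freqs[c("stgc", "ltgc", "rfp_only")]
    if (sum(tf) > 1 || sum(bg) > 1)
        stop("event frequencies sum above 1")
    p_main <- transfection_eff * tf + bg
    if (sum(p_main) > 1) stop("combined event frequencies sum above 1")
    with_seed(seed, {
        main <- as.integer(rmultinom(1L, n_cells,
                                     c(p_main, 1 - sum(p_main))))
        bgs <- as.integer(rmultinom(1L, n_background, c(bg, 1 - sum(bg))))
        data.frame(sample = c("transfected", "background"),
                   n_gfp_rfpneg = c(main[1], bgs[1]),
                   n_gfp_rfppos = c(main[2], bgs[2]),
                   n_gfpneg_rfp = c(main[3], bgs[3]),
                   n_total = c(n_cells, n_background),
                   transfection_eff = c(transfection_eff, NA),
                   stringsAsFactors = FALSE)
    })
}
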