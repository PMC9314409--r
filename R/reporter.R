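#' Configuration for the sister-chromatid recombination (SCR) reporter
#'
#' Parameterizes a synthetic single-copy recombination reporter carrying two
#' homologous GFP copies: a 5'-truncated copy (`TrGFP`) and a full copy
#' interrupted by an 18-bp I-SceI recognition site (`ISceGFP`), separated by
#' a cassette of two artificial RFP exons (exon B upstream of exon A).
#' Short-tract gene conversion (STGC) at a break in `ISceGFP` yields
#' GFP+RFP- cells; long-tract gene conversion (LTGC) duplicates the RFP
#' exon B/A cassette (GFP+RFP+), a repeat-directed tandem duplication whose
#' span is the distance between the allelic positions of the break in the
#' two GFP repeats.
#'
#' The default full-scale geometry reproduces a ~10 kb duplication span; a
#' scaled-down geometry for fast tests is obtained by shrinking
#' `repeat_spacing` and the pads.
#'
#' @param name construct identifier.
#' @param gfp_len length (bp) of the shared GFP sequence.
#' @param trunc5 number of 5' bases missing from `TrGFP`.
#' @param isce_offset offset (bp, 0-based) within the GFP sequence at which
#'   the I-SceI site is inserted in `ISceGFP`; also the default break point.
#' @param upstream_pad bases upstream of `TrGFP`.
#' @param exonB_offset distance from the start of `TrGFP` to RFP exon B.
#' @param exon_len length of each RFP exon.
#' @param repeat_spacing distance from the start of `TrGFP` to the start of
#'   `ISceGFP`; the repeat-directed TD span is
#'   `repeat_spacing + trunc5 + (18-bp site length) - ... ` computed from the
#'   allelic mapping (10,000 bp at the defaults).
#' @param exonA_gap gap between the end of RFP exon A and `ISceGFP`.
#' @param downstream_pad bases downstream of `ISceGFP`.
#' @param emx1_insert optional extra insert (e.g. a 44-bp human EMX1
#'   fragment) knocked in immediately 5' of the I-SceI site, providing
#'   additional nickase target sites; `NULL` for none.
#' @param min_homology minimum acceptable perfect homology (bp) between the
#'   GFP repeats; configurations below this are rejected.
#' @param seed integer seed controlling the (otherwise arbitrary) background
#'   sequence, so a given configuration always builds the same construct.
#' @return a list of class `scr_reporter_config` for [build_reporter()].
#' @export
scr_reporter_config <- function(name = "SCR_RFP",
                                gfp_len = 720L, trunc5 = 20L,
                                isce_offset = 360L,
                                upstream_pad = 2500L,
                                exonB_offset = 2700L,
                                exon_len = 600L,
                                repeat_spacing = 9980L,
                                exonA_gap = 200L,
                                downstream_pad = 800L,
                                emx1_insert = NULL,
                                min_homology = 200L,
                                seed = 1202L) {
    cfg <- list(type = "scr_rfp", name = name,
                gfp_len = as.integer(gfp_len), trunc5 = as.integer(trunc5),
                isce_offset = as.integer(isce_offset),
                upstream_pad = as.integer(upstream_pad),
                exonB_offset = as.integer(exonB_offset),
                exon_len = as.integer(exon_len),
                repeat_spacing = as.integer(repeat_spacing),
                exonA_gap = as.integer(exonA_gap),
                downstream_pad = as.integer(downstream_pad),
                emx1_insert = emx1_insert,
                min_homology = as.integer(min_homology),
                seed = as.integer(seed))
    class(cfg) <- "scr_reporter_config"
    cfg
}

ISCE_SITE <- "TAGGGATAACAGGGTAAT"   # 18-bp I-SceI recognition site

#' Configuration for the NHEJ (frame-restoration) reporter
#'
#' A GFP expression cassette in which translation initiates at a strong
#' artificial Kozak start codon (`Koz-ATG`) placed out of frame with the
#' downstream GFP coding sequence by a 34-bp frameshift spacer, so the
#' unedited construct is GFP-negative.  Mutagenic end joining at a cut in
#' the spacer can restore GFP either by shifting Koz-ATG into frame (net
#' indel of +2, +5, ... or -1, -4, ... bp, i.e. net = 2 mod 3) or by
#' destroying the Koz-ATG start codon, in which case scanning falls through
#' to the native GFP ATG.
#'
#' The promoter, spacer and trailing pad are built from A/C only so that no
#' incidental start or stop codon can arise at indel junctions; the GFP-like
#' coding sequence is stop-free in frame.
#'
#' @param name construct identifier.
#' @param gfp_cds_len length of the GFP-like CDS including start and stop
#'   codons; must be a multiple of 3.
#' @param promoter_len length of the promoter region (upstream of Koz-ATG).
#' @param frameshift_len distance (bp) from the Koz-ATG A to the GFP ATG;
#'   the default 34 reproduces a +1 frameshift (34 = 3n + 1).
#' @param downstream_pad bases after the CDS.
#' @param seed integer seed for the arbitrary portions of the sequence.
#' @export
nhej_reporter_config <- function(name = "NHEJ_GFP",
                                 gfp_cds_len = 720L,
                                 promoter_len = 300L,
                                 frameshift_len = 34L,
                                 downstream_pad = 60L,
                                 seed = 77L) {
    stopifnot(gfp_cds_len %% 3 == 0, gfp_cds_len >= 30,
              frameshift_len >= 10)
    cfg <- list(type = "nhej", name = name,
                gfp_cds_len = as.integer(gfp_cds_len),
                promoter_len = as.integer(promoter_len),
                frameshift_len = as.integer(frameshift_len),
                downstream_pad = as.integer(downstream_pad),
                seed = as.integer(seed))
    class(cfg) <- "nhej_reporter_config"
    cfg
}

## A/C-only filler: contains no T or G, hence no ATG and no stop codon in
## any reading frame, and none can be created at an indel junction.
random_ac <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                               collapse = "")

## stop-free random coding sequence: ATG + codons free of TAA/TAG/TGA + TAA
random_cds <- function(len) {
    stops <- c("TAA", "TAG", "TGA")
    ncod <- len / 3L - 2L
    codons <- character(0)
    bases <- c("A", "C", "G", "T")
    while (length(codons) < ncod) {
        cand <- paste0(sample(bases, 64, TRUE), sample(bases, 64, TRUE),
                       sample(bases, 64, TRUE))
        cand <- cand[!cand %in% stops]
        codons <- c(codons, cand)
    }
    paste0("ATG", paste(codons[seq_len(ncod)], collapse = ""), "TAA")
}

#' Build a reporter construct from a configuration
#'
#' @param config a [scr_reporter_config()] or [nhej_reporter_config()].
#' @return an object of class `ReporterConstruct`: a list with `name`,
#'   `sequence` (character), `features` (data.frame with `label`, `start`,
#'   `end`, `strand`; 0-based half-open on the Watson strand),
#'   `origin_direction_for_ltgc`, and type-specific anchors (`break_pos`,
#'   `allelic_pos` for the SCR reporter; `kozatg_atg`, `gfp_cds`,
#'   `gfp_peptide` for the NHEJ reporter).
#' @export
build_reporter <- function(config) {
    switch(config$type,
           scr_rfp = build_scr_reporter(config),
           nhej = build_nhej_reporter_impl(config),
           stop("unknown reporter config type: ", config$type))
}

build_scr_reporter <- function(cfg) {
    with_seed(cfg$seed, {
        homology <- cfg$gfp_len - cfg$trunc5
        if (homology < cfg$min_homology)
            stop("homology region between GFP repeats is ", homology,
                 " bp; at least ", cfg$min_homology, " bp required")
        if (cfg$isce_offset <= cfg$trunc5 || cfg$isce_offset >= cfg$gfp_len)
            stop("I-SceI insertion point must fall inside the shared homology")
        emx <- cfg$emx1_insert %||% ""
        insert <- paste0(emx, ISCE_SITE)
        isce_gfp_len <- cfg$gfp_len + nchar(insert)

        tr_start <- cfg$upstream_pad
        tr_len <- homology
        tr_end <- tr_start + tr_len
        exonB_start <- tr_start + cfg$exonB_offset
        exonB_end <- exonB_start + cfg$exon_len
        isce_start <- tr_start + cfg$repeat_spacing
        exonA_end <- isce_start - cfg$exonA_gap
        exonA_start <- exonA_end - cfg$exon_len
        isce_end <- isce_start + isce_gfp_len
        total <- isce_end + cfg$downstream_pad

        if (exonB_start < tr_end)
            stop("RFP exon B overlaps TrGFP; increase exonB_offset")
        if (exonA_start < exonB_end)
            stop("RFP exon cassette has non-positive length: ",
                 "the reporter needs a positive span between the exons")
        if (cfg$exon_len <= 0)
            stop("zero-length RFP cassette is a degenerate geometry")

        gfp <- random_cds(cfg$gfp_len %/% 3L * 3L)
        gfp <- paste0(gfp, random_dna(cfg$gfp_len - nchar(gfp)))
        trgfp_seq <- substr(gfp, cfg$trunc5 + 1L, cfg$gfp_len)
        isce_gfp_seq <- paste0(substr(gfp, 1L, cfg$isce_offset), insert,
                               substr(gfp, cfg$isce_offset + 1L, cfg$gfp_len))

        seq <- paste0(random_dna(tr_start), trgfp_seq,
                      random_dna(isce_start - tr_end), isce_gfp_seq,
                      random_dna(cfg$downstream_pad))
        stopifnot(nchar(seq) == total)

        site_start <- isce_start + cfg$isce_offset + nchar(emx)
        features <- data.frame(
            label = c("TrGFP", "RFP_exonB", "RFP_exonA", "ISceGFP",
                      "ISceI_site"),
            start = c(tr_start, exonB_start, exonA_start, isce_start,
                      site_start),
            end = c(tr_end, exonB_end, exonA_end, isce_end,
                    site_start + 18L),
            strand = "+", stringsAsFactors = FALSE)
        if (nchar(emx) > 0) {
            features <- rbind(features, data.frame(
                label = "EMX1_insert", start = isce_start + cfg$isce_offset,
                end = site_start, strand = "+"))
        }

        ## break point: the I-SceI/sgRNA target position, and its allelic
        ## position transposed onto the TrGFP repeat
        break_pos <- isce_start + cfg$isce_offset
        allelic_pos <- tr_start + (cfg$isce_offset - cfg$trunc5)

        rep <- list(name = cfg$name, sequence = seq, features = features,
                    origin_direction_for_ltgc = "rightward",
                    type = "scr_rfp",
                    break_pos = break_pos, allelic_pos = allelic_pos,
                    gfp_len = cfg$gfp_len, trunc5 = cfg$trunc5,
                    insert_len = nchar(insert), config = cfg)
        class(rep) <- "ReporterConstruct"
        validate_reporter(rep)
        rep
    })
}

KOZATG <- "GCCACCATGG"   # Kozak context; the start codon is at offset 6..9

build_nhej_reporter_impl <- function(cfg) {
    with_seed(cfg$seed, {
        promoter <- random_ac(cfg$promoter_len)
        koz_start <- cfg$promoter_len
        atg_start <- koz_start + 6L
        ## frameshift spacer: the Kozak trailing G plus A/C filler, sized so
        ## that the GFP ATG sits frameshift_len bases after the Koz-ATG A
        spacer_len <- cfg$frameshift_len - 4L   # ATG (3) + trailing G (1)
        spacer <- random_ac(spacer_len)
        gfp_start <- atg_start + cfg$frameshift_len
        cds <- random_cds(cfg$gfp_cds_len)
        seq <- paste0(promoter, KOZATG, spacer, cds,
                      random_ac(cfg$downstream_pad))
        stopifnot(substr(seq, gfp_start + 1L, gfp_start + 3L) == "ATG")

        features <- data.frame(
            label = c("PGK_promoter", "KozATG", "ATG_GFP"),
            start = c(0L, koz_start, gfp_start),
            end = c(koz_start, koz_start + 10L, gfp_start + cfg$gfp_cds_len),
            strand = "+", stringsAsFactors = FALSE)

        pep <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
        pep <- sub("\\*$", "", pep)

        rep <- list(name = cfg$name, sequence = seq, features = features,
                    origin_direction_for_ltgc = "rightward",
                    type = "nhej",
                    kozatg_atg = c(atg_start, atg_start + 3L),
                    gfp_cds = c(gfp_start, gfp_start + cfg$gfp_cds_len),
                    gfp_peptide = pep,
                    cut_pos = atg_start + 12L,   # default target in spacer
                    config = cfg)
        class(rep) <- "ReporterConstruct"
        validate_reporter(rep)
        rep
    })
}

#' Validate a reporter construct's feature geometry
#'
#' Checks the interval invariants (0 <= start < end <= length, mandatory
#' non-overlaps, minimum GFP homology, I-SceI site containment).
#' @param reporter a `ReporterConstruct`.
#' @return the reporter, invisibly; errors on violation.
#' @export
validate_reporter <- function(reporter) {
    f <- reporter$features
    n <- nchar(reporter$sequence)
    if (any(f$start < 0) || any(f$end > n) || any(f$start >= f$end))
        stop("feature intervals must satisfy 0 <= start < end <= length")
    if (reporter$type == "scr_rfp") {
        tr <- f[f$label == "TrGFP", ]
        isce <- f[f$label == "ISceGFP", ]
        site <- f[f$label == "ISceI_site", ]
        if (tr$end > isce$start)
            stop("TrGFP and ISceGFP must not overlap")
        if (site$start < isce$start || site$end > isce$end)
            stop("ISceI_site must lie inside ISceGFP")
        homology <- tr$end - tr$start
        if (homology < reporter$config$min_homology)
            stop("GFP homology below the configured minimum")
        ## the homologous region must be a perfect repeat
        tr_seq <- substr(reporter$sequence, tr$start + 1L, tr$end)
        gfp3 <- feature_seq(reporter, "ISceGFP")
        gfp3 <- paste0(substr(gfp3, 1L, reporter$break_pos - isce$start),
                       substr(gfp3,
                              reporter$break_pos - isce$start +
                                  reporter$insert_len + 1L,
                              isce$end - isce$start))
        if (substr(gfp3, reporter$trunc5 + 1L, nchar(gfp3)) != tr_seq)
            stop("GFP repeats are not perfectly homologous")
    }
    invisible(reporter)
}

#' @export
print.ReporterConstruct <- function(x, ...) {
    cat("ReporterConstruct <", x$name, "> (", x$type, "), ",
        nchar(x$sequence), " bp\n", sep = "")
    print(x$features, row.names = FALSE)
    invisible(x)
}

feature_range <- function(reporter, label) {
    f <- reporter$features
    r <- f[f$label == label, ]
    if (nrow(r) == 0) stop("no feature labelled ", label)
    c(r$start[1], r$end[1])
}

feature_seq <- function(reporter, label) {
    r <- feature_range(reporter, label)
    substr(reporter$sequence, r[1] + 1L, r[2])
}

#' Repeat-directed tandem-duplication span of a reporter
#'
#' Distance from the allelic position of the break in `TrGFP` to the break
#' in `ISceGFP`: the unit duplicated by repeat-directed (LTGC/TRSI) TDs.
#' @param reporter an SCR `ReporterConstruct`.
#' @return span in bp (10,000 for the full-scale default geometry).
#' @export
repeat_td_span <- function(reporter) {
    stopifnot(reporter$type == "scr_rfp")
    reporter$break_pos - reporter$allelic_pos
}

#' Write a reporter to FASTA and BED
#'
#' Feature coordinates are stored 0-based half-open internally and written
#' through [rtracklayer::export()] in standard BED convention, so a
#' write/read round trip reproduces identical coordinates.
#' @param reporter a `ReporterConstruct`.
#' @param fasta,bed output paths.
#' @export
write_reporter <- function(reporter, fasta, bed) {
    dna <- Biostrings::DNAStringSet(setNames(reporter$sequence,
                                             reporter$name))
    Biostrings::writeXStringSet(dna, fasta)
    gr <- GenomicRanges::GRanges(
        seqnames = reporter$name,
        ranges = IRanges::IRanges(start = reporter$features$start + 1L,
                                  end = reporter$features$end),
        strand = reporter$features$strand,
        name = reporter$features$label)
    rtracklayer::export(gr, bed, format = "BED")
    invisible(c(fasta = fasta, bed = bed))
}

#' Read a reporter back from FASTA + BED
#'
#' Reconstructs the sequence and 0-based feature table; type-specific
#' anchors are not recomputed (this is an IO round trip, not a re-build).
#' @param fasta,bed paths written by [write_reporter()].
#' @return a list with `name`, `sequence` and a 0-based `features` table.
#' @export
read_reporter <- function(fasta, bed) {
    dna <- Biostrings::readDNAStringSet(fasta)
    gr <- rtracklayer::import(bed, format = "BED")
    features <- data.frame(
        label = gr$name,
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*",
                        "+", as.character(GenomicRanges::strand(gr))),
        stringsAsFactors = FALSE)
    list(name = names(dna)[1], sequence = as.character(dna[[1]]),
         features = features)
}
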