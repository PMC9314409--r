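test_that("full-scale SCR reporter has the expected geometry", {
    r <- scr_fixture()
    expect_s3_class(r, "ReporterConstruct")
    expect_identical(repeat_td_span(r), 10000L)
    f <- r$features
    expect_true(all(f$start >= 0 & f$start < f$end &
                    f$end <= nchar(r$sequence)))
    ## GFP repeats share >= 200 bp of perfect homology (validated on build)
    tr <- f[f$label == "TrGFP", ]
    expect_gte(tr$end - tr$start, 200)
    ## I-SceI site inside ISceGFP
    isce <- f[f$label == "ISceGFP", ]
    site <- f[f$label == "ISceI_site", ]
    expect_true(site$start >= isce$start && site$end <= isce$end)
})

test_that("degenerate reporter geometries are rejected", {
    expect_error(build_reporter(scr_reporter_config(exon_len = 0L)),
                 "degenerate|positive")
    expect_error(build_reporter(scr_reporter_config(gfp_len = 150L,
                                                    trunc5 = 20L,
                                                    isce_offset = 75L)),
                 "homology")
})

test_that("scaled reporter span follows the configured arithmetic", {
    cfg <- scr_reporter_config(gfp_len = 320L, trunc5 = 20L,
                               isce_offset = 160L, upstream_pad = 400L,
                               exonB_offset = 500L, exon_len = 200L,
                               repeat_spacing = 1640L, exonA_gap = 100L,
                               downstream_pad = 200L)
    r <- build_reporter(cfg)
    ## span = repeat_spacing - (isce_offset - trunc5) + isce_offset
    expect_identical(repeat_td_span(r),
                     r$break_pos - r$allelic_pos)
    expect_identical(r$break_pos - r$allelic_pos,
                     cfg$repeat_spacing + cfg$trunc5)
    ## recompute the span from the emitted feature table alone
    f <- r$features
    tr_start <- f$start[f$label == "TrGFP"]
    isce_start <- f$start[f$label == "ISceGFP"]
    span <- (isce_start + cfg$isce_offset) -
        (tr_start + cfg$isce_offset - cfg$trunc5)
    expect_identical(repeat_td_span(r), span)
})

test_that("FASTA + BED round trip preserves coordinates exactly", {
    r <- scr_fixture()
    fa <- tempfile(fileext = ".fa")
    bed <- tempfile(fileext = ".bed")
    write_reporter(r, fa, bed)
    back <- read_reporter(fa, bed)
    expect_identical(back$sequence, r$sequence)
    got <- back$features[order(back$features$start), ]
    want <- r$features[order(r$features$start), ]
    expect_identical(got$start, as.integer(want$start))
    expect_identical(got$end, as.integer(want$end))
    expect_setequal(got$label, want$label)
    unlink(c(fa, bed))
})

test_that("nickase-to-nicked-strand rule follows the enzyme chemistry", {
    ## D10A cuts the sgRNA-paired (target) strand: complement of the PAM
    expect_identical(nicked_strand("Cas9D", "Watson"), "Crick")
    expect_identical(nicked_strand("Cas9D", "Crick"), "Watson")
    ## H840A cuts the displaced (non-target) strand: the PAM strand
    expect_identical(nicked_strand("Cas9H", "Watson"), "Watson")
    expect_identical(nicked_strand("Cas9H", "Crick"), "Crick")
    expect_identical(nicked_strand("Cas9", "Watson"), "both")
    expect_identical(nicked_strand("dCas9", "Crick"), "none")
})

test_that("collision class truth table and double-mirror symmetry hold", {
    expect_identical(collision_class("Crick", "rightward"), "lead")
    expect_identical(collision_class("Watson", "rightward"), "lag")
    expect_identical(collision_class("Watson", "leftward"), "lead")
    expect_identical(collision_class("both", "rightward"), "none")
    expect_identical(collision_class("none", "leftward"), "none")

    tab <- collision_table()
    expect_identical(nrow(tab), 8L)
    ## mirroring both the PAM strand and the fork direction leaves the
    ## collision class unchanged
    other <- c(Watson = "Crick", Crick = "Watson")
    flip <- c(rightward = "leftward", leftward = "rightward")
    for (i in seq_len(nrow(tab))) {
        j <- which(tab$nickase == tab$nickase[i] &
                   tab$pam_strand == other[tab$pam_strand[i]] &
                   tab$fork_direction == flip[tab$fork_direction[i]])
        expect_identical(tab$collision_class[i], tab$collision_class[j])
    }
})

test_that("sites derive, validate and load from YAML", {
    r <- scr_fixture()
    st <- site_from_position(r, "test_site", r$break_pos, "Watson", "Cas9")
    expect_s3_class(st, "TargetSite")
    expect_lt(abs(st$cut_pos - r$break_pos), 60)
    ## mangling the protospacer fails validation
    expect_error(target_site("bad",
                             paste0("AAAA", substr(st$protospacer, 5, 20)),
                             st$pam_strand, "Cas9", st$cut_pos,
                             reference = r$sequence),
                 "protospacer")

    path <- system.file("extdata", "sites.yaml", package = "nickrepair")
    sites <- load_sites(path, r$sequence)
    expect_length(sites, 10L)
    expect_true(all(vapply(sites, function(s)
        abs(s$cut_pos - r$break_pos) < 80, logical(1))))
    ## collision context derives from the loaded fields
    ctx <- collision_context(
        target_site("x", sites[["gHR1b"]]$protospacer, "Watson", "Cas9D",
                    sites[["gHR1b"]]$cut_pos),
        "rightward")
    expect_identical(ctx$collision_class, "lead")
})
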