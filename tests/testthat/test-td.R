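test_that("constructed INV/TER classes are recognized", {
    rep <- scr_fixture()
    amp <- td_amplicon(rep)
    brk <- amp$break_offset

    ## INV1: the reference amplicon itself
    expect_identical(classify_invasion(amp$seq, rep)$class, "INV1")
    expect_identical(classify_termination(amp$seq, rep)$class, "TER1")

    ## INV2: a 2-bp deletion at the break point; the classifier returns
    ## the indel itself
    clone2 <- apply_indel(amp$seq, brk - 1, brk + 1)
    r2 <- classify_invasion(clone2, rep)
    expect_identical(r2$class, "INV2")
    expect_identical(r2$del_end - r2$del_start, 2L)
    ## +1 insertion at the break point is also class 2
    cloneI <- apply_indel(amp$seq, brk, brk, "T")
    expect_identical(classify_invasion(cloneI, rep)$class, "INV2")

    ## an unrelated sequence is unclassified
    expect_identical(classify_invasion(strrep("ACGT", 250), rep)$class,
                     "unclassified")
})

test_that("a hand-built INV3 fusion is recovered with its MH, processing and entry", {
    rep <- scr_fixture()
    amp <- td_amplicon(rep)
    brk <- amp$break_offset
    ## fuse the amplicon 6 bp short of the break to reporter sequence
    ## 120 bp upstream of the allelic break position
    processed <- 6L
    f <- brk - processed
    entry <- rep$allelic_pos - 120L
    clone <- paste0(substr(amp$seq, 1, f),
                    substr(rep$sequence, entry + 1,
                           entry + nchar(amp$seq) - f))
    res <- classify_invasion(clone, rep)
    expect_identical(res$class, "INV3")
    ## canonical (right-maximal) values from the junction ambiguity
    jm <- junction_mh(amp$seq, f, rep$sequence, entry)
    expect_identical(res$mh_len, jm$mh_len)
    expect_identical(res$processed_len, processed - jm$fwd)
    expect_identical(res$entry_distance, 120L - jm$fwd)

    ## TER3 mirror: upstream partner fused to the amplicon 3' of the break
    head_len <- f
    e <- rep$allelic_pos + 800L      # non-GFP, upstream of ISceGFP
    ter <- paste0(substr(rep$sequence, e - head_len + 1, e),
                  substr(amp$seq, f + 1, nchar(amp$seq)))
    rt <- classify_termination(ter, rep)
    expect_identical(rt$class, "TER3")
})

test_that("simulated clone sets are classified with full truth recovery", {
    rep <- scr_fixture()
    sim <- simulate_td_clones(rep, n_clones = 60, seed = 12)
    calls <- classify_td_clones(sim$invasion, sim$termination, rep)
    expect_identical(td_class_recovery(sim$truth, calls), 1)
    m <- merge(sim$truth, calls, by = "clone_id", suffixes = c(".t", ".c"))
    i3 <- m[m$inv_class.t == "INV3", ]
    expect_gt(nrow(i3), 3)
    expect_identical(i3$mh_len.t, i3$mh_len.c)
    expect_identical(i3$processed_len.t, i3$processed_len.c)
    expect_identical(i3$entry_distance.t, i3$entry_distance.c)
    expect_identical(i3$td_span.t, i3$td_span.c)
})

test_that("shared indels between INV2 and TER2 junctions are flagged", {
    rep <- scr_fixture()
    amp <- td_amplicon(rep)
    brk <- amp$break_offset
    shared <- apply_indel(amp$seq, brk - 2, brk + 1)
    other <- apply_indel(amp$seq, brk, brk + 3)
    calls <- classify_td_clones(
        invasion = c(a = shared, b = shared),
        termination = c(a = shared, b = other), rep)
    expect_true(calls$shared_indel_with_ter[calls$clone_id == "a"])
    expect_false(calls$shared_indel_with_ter[calls$clone_id == "b"])
})

test_that("TD spans follow the reporter geometry", {
    rep <- scr_fixture()
    ## repeat-directed products: the distance between the GFP repeats
    expect_identical(td_span(list(inv_class = "INV1"), rep), 10000L)
    expect_identical(td_span(list(inv_class = "INV2"), rep), 10000L)
    ## INV3: span shifts by exactly the entry distance
    e1 <- rep$allelic_pos - 1000L
    expect_identical(td_span(list(inv_class = "INV3", entry_pos = e1), rep),
                     11000L)
    expect_error(td_span(list(inv_class = "unclassified"), rep),
                 "unclassified")

    ## scaled reporter: span equals the configured cassette arithmetic
    small <- build_reporter(scr_reporter_config(
        gfp_len = 320L, trunc5 = 20L, isce_offset = 160L,
        upstream_pad = 400L, exonB_offset = 500L, exon_len = 200L,
        repeat_spacing = 1640L, exonA_gap = 100L, downstream_pad = 200L))
    expect_identical(td_span(list(inv_class = "INV1"), small),
                     1640L + 20L)
})

test_that("class frequencies follow overall x proportion", {
    calls <- data.frame(
        inv_class = c(rep("INV1", 7), rep("INV2", 15), rep("INV3", 14)),
        ter_class = c(rep("TER1", 7), rep("TER2", 15), rep("TER1", 14)))
    cf <- class_frequencies(0.002, calls)
    expect_equal(unname(cf$inv_prop[["INV3"]]), 14 / 36)
    expect_equal(sum(cf$class_freq), 0.002)
    ## worked arithmetic: overall 0.2%, 32.5% INV3 -> 0.065%
    expect_equal(0.2 * 0.325, 0.065)
    calls1 <- data.frame(inv_class = "INV3", ter_class = "TER1")
    cf1 <- class_frequencies(0.31, calls1)
    expect_equal(unname(cf1$class_freq[[1]]), 0.31)
    expect_error(class_frequencies(0.1, calls1[0, ]), "no classified")
})

test_that("multinomial class proportions are recovered at clone scale", {
    rep <- scr_fixture()
    mixp <- c(INV1.TER1 = 0.4, INV2.TER2 = 0.35, INV3.TER1 = 0.25)
    sim <- simulate_td_clones(rep, class_mix = mixp, n_clones = 200,
                              seed = 31)
    calls <- classify_td_clones(sim$invasion, sim$termination, rep)
    cf <- class_frequencies(1, calls)
    for (k in names(mixp)) {
        p <- mixp[[k]]
        obs <- if (k %in% names(cf$class_prop)) cf$class_prop[[k]] else 0
        expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 200))
    }
})

test_that("RFP+/LTGC ratio arithmetic", {
    expect_equal(rfp_to_ltgc_ratio(0.001, 0.005), 0.2)
    expect_equal(rfp_to_ltgc_ratio(0.3, 0.3), 1)
    expect_error(rfp_to_ltgc_ratio(0.1, 0), "positive")
})
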