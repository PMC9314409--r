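test_that("align_and_call handles the canonical small examples", {
    ## identity
    ref <- paste0(strrep("ACGTT", 10), "GATTACAGGAT", strrep("TGCAA", 10))
    call <- align_and_call(ref, ref, 25)
    expect_identical(call$status, "unedited")
    expect_identical(call$net_indel, 0L)

    ## unique 2-bp deletion
    read <- paste0(substr(ref, 1, 30), substr(ref, 33, nchar(ref)))
    call <- align_and_call(read, ref, 30)
    expect_identical(call$status, "deletion")
    expect_identical(call$del_len, 2L)

    ## empty and too-short reads error
    expect_error(align_and_call("", ref), "empty")
    expect_error(align_and_call("ACGT", ref), "anchor")
})

test_that("deletion calls carry the enumeration-oracle MH annotation", {
    set.seed(31)
    core <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    for (trial in 1:25) {
        L <- sample(1:8, 1)
        s <- sample(40:70, 1)
        read <- apply_indel(core, s, s + L)
        call <- align_and_call(read, core, 55)
        expect_identical(call$status, "deletion")
        expect_identical(call$del_len, L)
        expect_identical(call$mh_len, mh_oracle(core, call$del_start,
                                                call$del_end))
        ## left-aligned: no equivalent placement further left
        if (call$del_start > 0)
            expect_false(apply_indel(core, call$del_start - 1,
                                     call$del_start - 1 + L) == read)
    }
})

test_that("re-calling a reconstructed read is idempotent", {
    rep <- nhej_fixture()
    mix <- outcome_mixture(error_rate = 0)
    lib <- simulate_amplicon_library(rep, rep$cut_pos, mix, 150, seed = 21)
    calls <- call_junctions(lib$reads, lib$reference_window,
                            lib$cut_offset)
    edited <- calls[calls$status %in% c("deletion", "insertion", "complex"), ]
    for (i in head(seq_len(nrow(edited)), 40)) {
        rec <- apply_indel(lib$reference_window, edited$del_start[i],
                           edited$del_end[i], edited$inserted_seq[i])
        re <- align_and_call(rec, lib$reference_window, lib$cut_offset)
        expect_identical(re$status, edited$status[i])
        expect_identical(re$del_start, edited$del_start[i])
        expect_identical(re$del_end, edited$del_end[i])
        expect_identical(re$inserted_seq, edited$inserted_seq[i])
    }
})

test_that("substitution-only reads are unedited; garbage is unaligned", {
    ref <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
    read <- ref
    substr(read, 40, 40) <- "A"
    substr(read, 41, 41) <- "T"   # non-adjacent double change would be
    call <- align_and_call(read, ref, 50)
    expect_identical(call$status, "unedited")

    junk <- paste(rep("A", 100), collapse = "")
    call2 <- align_and_call(junk, ref, 50)
    expect_identical(call2$status, "unaligned")
})

test_that("editing efficiency arithmetic and errors", {
    calls <- data.frame(status = c(rep("deletion", 200),
                                   rep("insertion", 50),
                                   rep("complex", 50),
                                   rep("unedited", 700)))
    expect_equal(editing_efficiency(calls, 0.6), 0.3 / 0.6)
    expect_equal(editing_efficiency(data.frame(status = rep("unedited", 10))),
                 0)
    expect_warning(
        out <- editing_efficiency(data.frame(status = rep("deletion", 10)),
                                  transfection_eff = 0.5),
        "capping")
    expect_equal(out, 1)
    expect_error(editing_efficiency(data.frame(status = rep("unaligned", 5))),
                 "unaligned")
})

test_that("deletion summaries bin, median and count MH as specified", {
    calls <- data.frame(status = c("deletion", "deletion", "deletion",
                                   "unedited"),
                        del_len = c(2L, 5L, 20L, 0L),
                        mh_len = c(0L, 2L, 0L, 0L))
    s <- summarize_deletions(calls)
    expect_equal(s$median_del_len, 5)
    expect_equal(unname(s$bin_fracs), c(2 / 3, 1 / 3, 0))
    expect_equal(s$mh_usage, 1 / 3)
    expect_equal(sum(s$bin_fracs), 1)

    ## all-zero MH
    calls$mh_len <- 0L
    expect_equal(summarize_deletions(calls)$mh_usage, 0)

    ## no deletions: explicit n = 0 marker
    s0 <- summarize_deletions(data.frame(status = "unedited",
                                         del_len = 0L, mh_len = 0L))
    expect_identical(s0$n_deletions, 0L)
    expect_true(is.na(s0$median_del_len))
})

test_that("summary median tracks the generating size law", {
    rep <- nhej_fixture()
    law <- list(type = "geometric", mean = 6)
    mix <- outcome_mixture(0, 1, 0, 0, deletion_size_law = law,
                           mh_bias = 0, error_rate = 0)
    lib <- simulate_amplicon_library(rep, rep$cut_pos, mix, 4000, seed = 13)
    calls <- call_junctions(lib$reads, lib$reference_window,
                            lib$cut_offset)
    s <- summarize_deletions(calls)
    ## resampling oracle: median of fresh draws from the same law
    set.seed(99)
    meds <- replicate(200, median(rgeom(4000, 1 / 6) + 1))
    expect_lte(abs(s$median_del_len - median(meds)),
               3 * max(sd(meds), 0.5))
})
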