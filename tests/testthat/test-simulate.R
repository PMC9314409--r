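test_that("identical seed and configuration give byte-identical outputs", {
    rep <- nhej_fixture()
    mix <- outcome_mixture(error_rate = 0.002)
    a <- simulate_amplicon_library(rep, rep$cut_pos, mix, 200, seed = 9)
    b <- simulate_amplicon_library(rep, rep$cut_pos, mix, 200, seed = 9)
    expect_identical(a$reads, b$reads)
    expect_identical(a$truth, b$truth)
    fa <- tempfile(); fb <- tempfile()
    write_fastq(a$reads, fa); write_fastq(b$reads, fb)
    expect_identical(readLines(fa), readLines(fb))
    unlink(c(fa, fb))
    ## a different seed changes the library
    c_ <- simulate_amplicon_library(rep, rep$cut_pos, mix, 200, seed = 10)
    expect_false(identical(a$reads, c_$reads))
})

test_that("degenerate mixtures produce the promised libraries", {
    rep <- nhej_fixture()
    ## identity mixture: every read equals the reference window
    lib <- simulate_amplicon_library(rep, rep$cut_pos,
                                     outcome_mixture(1, 0, 0, 0), 50,
                                     seed = 1)
    expect_true(all(lib$reads == lib$reference_window))

    ## fixed-size deletion law: all truth records are 5-bp deletions
    mix <- outcome_mixture(0, 1, 0, 0,
                           deletion_size_law = list(type = "fixed",
                                                    size = 5),
                           mh_bias = 0, error_rate = 0)
    lib5 <- simulate_amplicon_library(rep, rep$cut_pos, mix, 300, seed = 7)
    expect_true(all(lib5$truth$class == "deletion"))
    expect_true(all(lib5$truth$del_len == 5L))

    ## window exceeding the reference errors
    expect_error(simulate_amplicon_library(rep, 10, mix, 10, window = 150),
                 "window")
    expect_error(outcome_mixture(0.5, 0.2, 0.2, 0.2), "sum to 1")
})

test_that("truth records reconstruct the emitted reads (round trip)", {
    rep <- nhej_fixture()
    mix <- outcome_mixture(error_rate = 0.003)
    lib <- simulate_amplicon_library(rep, rep$cut_pos, mix, 400, seed = 3)
    rebuilt <- vapply(seq_len(nrow(lib$truth)), function(i) {
        t <- lib$truth[i, ]
        if (t$class == "unedited") lib$reference_window
        else apply_indel(lib$reference_window, t$del_start, t$del_end,
                         t$inserted_seq)
    }, character(1))
    expect_identical(unname(lib$pre_error_reads), rebuilt)
})

test_that("MH-biased deletion placement matches the enumeration expectation", {
    rep <- nhej_fixture()
    mix <- outcome_mixture(0, 1, 0, 0,
                           deletion_size_law = list(type = "fixed", size = 5),
                           mh_bias = 0.6, error_rate = 0)
    n <- 10000
    lib <- simulate_amplicon_library(rep, rep$cut_pos, mix, n, seed = 11)
    p_exp <- expected_mh_fraction(lib$reference_window, lib$cut_offset,
                                  5L, 0.6)
    p_obs <- mean(lib$truth$mh_len >= 1)
    expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("FACS simulation is unbiased under normalization", {
    truef <- c(stgc = 0.05, ltgc = 0.004, rfp_only = 0.001)
    n <- 1e6
    f <- simulate_facs(truef, n, transfection_eff = 1, seed = 5)
    fr <- facs_frequencies(f)
    sd_stgc <- sqrt(truef["stgc"] * (1 - truef["stgc"]) / n)
    expect_lt(abs(fr[["stgc"]] - truef[["stgc"]]), 3 * sd_stgc)

    ## all-zero frequencies give zero event counts beyond background
    f0 <- simulate_facs(c(stgc = 0, ltgc = 0, rfp_only = 0), 1e5, seed = 1)
    expect_identical(sum(f0$n_gfp_rfpneg + f0$n_gfp_rfppos +
                         f0$n_gfpneg_rfp), 0L)

    ## transfection efficiency cancels after normalization
    f70 <- simulate_facs(truef, n, transfection_eff = 0.7, seed = 8)
    fr70 <- facs_frequencies(f70)
    sd70 <- sqrt(0.7 * truef["stgc"] / n) / 0.7
    expect_lt(abs(fr70[["stgc"]] - fr[["stgc"]]), 4 * sd70)

    expect_error(simulate_facs(c(stgc = 0.7, ltgc = 0.4, rfp_only = 0),
                               100), "sum above 1")
})

test_that("translocation library honours mixing and orientation laws", {
    loci <- translocation_loci(seed = 2)
    ## control fraction follows the configured volume mixing
    n <- 8000
    tl <- simulate_translocation_library(loci, n_reads = n,
                                         volume_ratio = 10,
                                         trans_abundance = 0.01, seed = 4)
    p_ctrl <- 1 / (1 + 10 * 0.01)
    obs <- mean(tl$truth$is_control)
    expect_lt(abs(obs - p_ctrl), 3 * sqrt(p_ctrl * (1 - p_ctrl) / n))

    ## four equal orientations: each close to a quarter of junction reads
    tl2 <- simulate_translocation_library(loci, n_reads = 8000,
                                          trans_abundance = 10, seed = 6)
    jt <- tl2$truth[!tl2$truth$is_control, ]
    tab <- table(jt$orientation)
    expect_setequal(names(tab), c("FF", "FR", "RF", "RR"))
    exp_each <- nrow(jt) / 4
    expect_true(all(abs(tab - exp_each) <
                    3 * sqrt(nrow(jt) * 0.25 * 0.75)))

    ## concentrated mix with forced precise joins: exact fusions only
    tl3 <- simulate_translocation_library(
        loci, orientation_mix = c(FF = 1, FR = 0, RF = 0, RR = 0),
        n_reads = 300, trans_abundance = 100, p_precise = 1, seed = 8)
    jt3 <- tl3$truth[!tl3$truth$is_control, ]
    expect_true(all(jt3$orientation == "FF"))
    expect_true(all(jt3$precise))
    expect_error(simulate_translocation_library(
        loci, orientation_mix = c(FF = 0.6, FR = 0.6, RF = 0, RR = 0)),
        "sum to 1")
})

test_that("TD clone constructions satisfy the class definitions", {
    rep <- scr_fixture()
    amp <- td_amplicon(rep)
    ## INV1/TER1: amplicons equal the reference end to end
    s1 <- simulate_td_clones(rep, class_mix = c(INV1.TER1 = 1),
                             n_clones = 5, seed = 1)
    expect_true(all(s1$invasion == amp$seq))
    expect_true(all(s1$termination == amp$seq))

    ## INV3: truth MH/entry re-derivable by manual split alignment
    s3 <- simulate_td_clones(rep, class_mix = c(INV3.TER1 = 1),
                             n_clones = 10, seed = 2)
    for (i in 1:10) {
        t <- s3$truth[i, ]
        cl <- s3$invasion[[i]]
        f <- amp$break_offset - t$processed_len     # canonical fusion
        expect_identical(substr(cl, 1, f), substr(amp$seq, 1, f))
        ## the clone continues with reporter sequence at the entry point
        expect_identical(substr(cl, f + 1, f + 30),
                         substr(rep$sequence, t$entry_pos + 1,
                                t$entry_pos + 30))
        ## the recorded MH equals the junction ambiguity at the fusion
        jm <- junction_mh(amp$seq, f, rep$sequence, t$entry_pos)
        expect_identical(jm$fwd, 0L)      # canonical is right-maximal
        expect_identical(t$mh_len, jm$mh_len)
        expect_identical(t$td_span, rep$break_pos - t$entry_pos)
        expect_identical(t$entry_distance, rep$allelic_pos - t$entry_pos)
    }
})
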