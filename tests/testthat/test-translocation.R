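test_that("exact fusions are called precise with the constructed orientation", {
    loci <- translocation_loci(seed = 17)
    A <- loci$locusA$sequence; B <- loci$locusB$sequence
    ca <- loci$locusA$cut_pos; cb <- loci$locusB$cut_pos
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    reads <- c(
        FF = paste0(substr(A, 1, ca), substr(B, cb + 1, nchar(B))),
        FR = paste0(substr(A, 1, ca), rc(substr(B, 1, cb))),
        RF = paste0(rc(substr(A, ca + 1, nchar(A))),
                    substr(B, cb + 1, nchar(B))),
        RR = paste0(rc(substr(A, ca + 1, nchar(A))), rc(substr(B, 1, cb))))
    res <- call_translocations(reads, loci)
    expect_identical(nrow(res$calls), 4L)
    expect_identical(res$calls$orientation,
                     c("FF", "FR", "RF", "RR"))
    expect_true(all(res$calls$del_A == 0 & res$calls$del_B == 0))
    expect_true(all(res$calls$precise))

    ## control reads are counted, not called
    res2 <- call_translocations(c(x = loci$control$sequence), loci)
    expect_identical(res2$control_count, 1L)
    expect_identical(nrow(res2$calls), 0L)
})

test_that("planted per-side losses and junction MH are recovered by split alignment", {
    loci <- translocation_loci(seed = 17)
    A <- loci$locusA$sequence; B <- loci$locusB$sequence
    ca <- loci$locusA$cut_pos; cb <- loci$locusB$cut_pos
    ## 7 bp lost on side A, nothing on side B
    read <- paste0(substr(A, 1, ca - 7), substr(B, cb + 1, nchar(B)))
    res <- call_translocations(c(r1 = read), loci)
    call <- res$calls[1, ]
    expect_identical(call$orientation, "FF")
    ## manual split-alignment oracle for the expected junction
    tmpl <- paste0(substr(A, 1, ca), substr(B, cb + 1, nchar(B)))
    want <- canonical_event(tmpl, ca - 7, ca, "", "right")
    expect_identical(call$del_A + call$del_B, 7L)
    expect_identical(call$del_A, ca - want$del_start)
    expect_identical(call$mh_len,
                     mh_length(tmpl, want$del_start, want$del_end)$mh_len)
    expect_false(call$precise)
})

test_that("orientation calls are invariant under read reverse-complementation", {
    loci <- translocation_loci(seed = 23)
    tl <- simulate_translocation_library(loci, n_reads = 400,
                                         trans_abundance = 5, seed = 2)
    jt <- tl$reads[!tl$truth$is_control][1:25]
    fwd <- call_translocations(jt, loci)
    rc <- vapply(jt, function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x))), "")
    bwd <- call_translocations(setNames(rc, names(jt)), loci)
    m <- merge(fwd$calls, bwd$calls, by = "read_id")
    expect_identical(nrow(m), nrow(fwd$calls))
    expect_identical(m$orientation.x, m$orientation.y)
    expect_identical(m$del_A.x, m$del_A.y)
    expect_identical(m$mh_len.x, m$mh_len.y)
})

test_that("relative levels normalize and scale as ratios", {
    expect_equal(relative_level(50, 500, 1)$level, 0.1)
    expect_equal(relative_level(50, 500, 0.5)$level, 0.2)
    ## scale invariance: multiplying both counts leaves the level unchanged
    expect_equal(relative_level(500, 5000, 1)$level,
                 relative_level(50, 500, 1)$level)
    expect_error(relative_level(10, 0), "positive")
    ## fold change between conditions
    a <- relative_level(90, 300, 1)
    b <- relative_level(30, 300, 1)
    expect_equal(level_fold_change(a, b), 3)
})

test_that("junction summaries report medians, MH usage and precise fraction", {
    calls <- data.frame(read_id = sprintf("r%d", 1:3),
                        orientation = "FF",
                        del_A = c(0L, 4L, 10L), del_B = c(0L, 0L, 2L),
                        mh_len = c(2L, 0L, 1L),
                        inserted_seq = "",
                        precise = c(TRUE, FALSE, FALSE))
    s <- translocation_junction_summary(calls)
    expect_equal(s$overall$median_del_A, 4)
    expect_equal(s$overall$precise_fraction, 1 / 3)
    expect_equal(s$overall$mh_usage, 2 / 3)

    allp <- data.frame(read_id = "r", orientation = "RR", del_A = 0L,
                       del_B = 0L, mh_len = 0L, inserted_seq = "",
                       precise = TRUE)
    s2 <- translocation_junction_summary(allp)
    expect_equal(s2$overall$median_del_total, 0)
    expect_equal(s2$overall$precise_fraction, 1)
    expect_error(translocation_junction_summary(calls[0, ]), "no")
})
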