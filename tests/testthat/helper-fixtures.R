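## Shared fixtures and independent oracles for the test suite.

## memoized constructs (building is deterministic but not free)
fixture_env <- new.env(parent = emptyenv())

scr_fixture <- function() {
    if (is.null(fixture_env$scr))
        fixture_env$scr <- build_reporter(scr_reporter_config())
    fixture_env$scr
}

nhej_fixture <- function() {
    if (is.null(fixture_env$nhej))
        fixture_env$nhej <- build_reporter(nhej_reporter_config())
    fixture_env$nhej
}

## compact NHEJ construct for exhaustive frame scans
nhej_small_fixture <- function() {
    if (is.null(fixture_env$nhej_small))
        fixture_env$nhej_small <- build_reporter(nhej_reporter_config(
            gfp_cds_len = 240L, promoter_len = 60L, downstream_pad = 30L,
            seed = 99L))
    fixture_env$nhej_small
}

## ---- brute-force MH oracle: enumerate every same-length deletion and
## count the placements producing the identical product
mh_oracle <- function(reference, del_start, del_end) {
    L <- del_end - del_start
    n <- nchar(reference)
    starts <- 0:(n - L)
    products <- vapply(starts, function(s)
        paste0(substr(reference, 1, s), substr(reference, s + L + 1, n)),
        character(1))
    target <- products[starts == del_start]
    sum(products == target) - 1L
}

## expected MH>=1 fraction for a fixed-size deletion law at a cut,
## by enumerating the simulator's candidate placements
expected_mh_fraction <- function(ref_win, cut_off, L, mh_bias) {
    us <- 0:L
    starts <- unique(pmax(20L, pmin(cut_off - us,
                                    2L * cut_off - 20L - L)))
    mhs <- vapply(starts, function(s) mh_length(ref_win, s, s + L)$mh_len,
                  integer(1))
    p_acc <- mean(mhs >= 1L)
    has_cand <- any(mhs >= 1L)
    mh_bias * (if (has_cand) 1 else p_acc) + (1 - mh_bias) * p_acc
}

## exact-recovery comparison between a truth table and junction calls
junction_recovery <- function(truth, calls) {
    m <- merge(truth, calls, by = "read_id", suffixes = c(".t", ".c"))
    class_ok <- m$class == m$status
    coord_ok <- class_ok & (m$class == "unedited" |
        (m$del_start.t == m$del_start.c & m$del_end.t == m$del_end.c &
         m$inserted_seq.t == m$inserted_seq.c))
    coord_ok[is.na(coord_ok)] <- m$class[is.na(coord_ok)] == "unedited"
    list(class = mean(class_ok), exact = mean(coord_ok))
}

translocation_recovery <- function(truth, res) {
    jt <- truth[!truth$is_control, ]
    m <- merge(jt, res$calls, by = "read_id", suffixes = c(".t", ".c"))
    ok <- m$orientation.t == m$orientation.c & m$del_A.t == m$del_A.c &
        m$del_B.t == m$del_B.c & m$mh_len.t == m$mh_len.c &
        m$inserted_seq.t == m$inserted_seq.c
    sum(ok) / nrow(jt)
}

td_class_recovery <- function(truth, calls) {
    m <- merge(truth, calls, by = "clone_id", suffixes = c(".t", ".c"))
    mean(m$inv_class.t == m$inv_class.c & m$ter_class.t == m$ter_class.c)
}
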