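#' Background-corrected, transfection-normalized event frequency
#'
#' `((raw/total) - (background/background_total)) / transfection_eff`,
#' clamped at zero (with a warning) when background correction goes
#' negative from small-count noise.
#'
#' @param raw_count,total event and total cell counts in the sample.
#' @param background_count,background_total same for the background
#'   (untransfected/mock) sample.
#' @param transfection_eff fraction of transfected cells, in (0, 1].
#' @return numeric frequency (vectorized).
#' @export
normalize_frequency <- function(raw_count, total, background_count = 0,
                                background_total = 1,
                                transfection_eff = 1) {
    if (any(transfection_eff <= 0) || any(transfection_eff > 1))
        stop("transfection efficiency must be in (0, 1]")
    if (any(total <= 0) || any(background_total <= 0))
        stop("totals must be positive")
    f <- (raw_count / total - background_count / background_total) /
        transfection_eff
    if (any(f < 0)) {
        warning("negative background-corrected frequency clamped to 0")
        f <- pmax(f, 0)
    }
    f
}

#' Derived frequencies from a FACS count table
#'
#' Applies [normalize_frequency()] to the three gates of a
#' [simulate_facs()]-shaped table (rows `transfected` and `background`).
#'
#' @param counts data.frame as returned by [simulate_facs()].
#' @return named numeric: `stgc`, `ltgc`, `rfp_only`, `ltgc_bias`.
#' @export
facs_frequencies <- function(counts) {
    tr <- counts[counts$sample == "transfected", ]
    bg <- counts[counts$sample == "background", ]
    eff <- tr$transfection_eff
    f <- vapply(c(stgc = "n_gfp_rfpneg", ltgc = "n_gfp_rfppos",
                  rfp_only = "n_gfpneg_rfp"),
                function(col) normalize_frequency(tr[[col]], tr$n_total,
                                                  bg[[col]], bg$n_total,
                                                  eff),
                numeric(1))
    c(f, ltgc_bias = ltgc_bias(f[["stgc"]], f[["ltgc"]]))
}

#' LTGC bias: long-tract share of gene-conversion events
#'
#' Defined here as `ltgc / (stgc + ltgc)`, the proportion of HR events
#' resolved as long-tract gene conversion.  Scale-invariant in the two
#' frequencies.
#'
#' @param stgc_freq,ltgc_freq STGC and LTGC frequencies (same units).
#' @return bias in `[0, 1]`; `NA` with a warning when both are zero.
#' @export
ltgc_bias <- function(stgc_freq, ltgc_freq) {
    tot <- stgc_freq + ltgc_freq
    out <- ifelse(tot > 0, ltgc_freq / tot, NA_real_)
    if (any(is.na(out)))
        warning("LTGC bias undefined where STGC + LTGC = 0")
    out
}

#' Scale per-genotype values relative to the wild-type mean
#'
#' Each value is divided by the mean of the wild-type group and expressed
#' in percent, so the wild-type group averages 100.
#'
#' @param values numeric vector of per-replicate measurements.
#' @param genotype factor/character; which group is wild type is given by
#'   `wildtype`.
#' @param wildtype label of the reference genotype.
#' @return numeric vector of percentages.
#' @export
relative_to_wildtype <- function(values, genotype, wildtype = "Brca1_wt") {
    wt <- values[genotype == wildtype]
    if (length(wt) == 0 || mean(wt) <= 0)
        stop("wild-type mean must be positive")
    100 * values / mean(wt)
}

#' Strand-asymmetry report for a metric across collision classes
#'
#' For each (site, nickase) the fold change mutant/wild-type of the metric
#' is computed from replicate means, attributed to its collision class
#' (lead or lag collapse), and the classes are aggregated as means of
#' per-site folds.  When sites contribute one fold to each class (the
#' D10A/H840A pairing at a shared protospacer region) the class contrast
#' is tested by a paired two-tailed t test, otherwise unpaired.
#'
#' @param per_site data.frame with columns `site_id`, `nickase`,
#'   `genotype` (`"Brca1_wt"`/`"Brca1_mut"`), `value` (one row per
#'   replicate).
#' @param contexts data.frame with `site_id`, `nickase`,
#'   `collision_class` (`"lead"`/`"lag"`).
#' @return list of class `AsymmetryTable`: `folds` (per site x nickase),
#'   `class_means`, `test` (htest) and `paired` flag.
#' @export
asymmetry_report <- function(per_site, contexts) {
    key <- interaction(per_site$site_id, per_site$nickase, drop = TRUE)
    folds <- do.call(rbind, lapply(split(per_site, key), function(d) {
        wt <- mean(d$value[d$genotype == "Brca1_wt"])
        mut <- mean(d$value[d$genotype == "Brca1_mut"])
        data.frame(site_id = d$site_id[1], nickase = d$nickase[1],
                   fold = mut / wt, stringsAsFactors = FALSE)
    }))
    folds <- merge(folds, contexts, by = c("site_id", "nickase"))
    folds <- folds[folds$collision_class %in% c("lead", "lag"), ]
    if (nrow(folds) == 0) stop("no sites with a lead/lag collision class")
    cm <- tapply(folds$fold, folds$collision_class, mean)
    missing_class <- setdiff(c("lead", "lag"), names(cm))
    test <- NULL
    paired <- FALSE
    if (length(missing_class) == 0) {
        lead <- folds[folds$collision_class == "lead", ]
        lag <- folds[folds$collision_class == "lag", ]
        shared <- intersect(lead$site_id, lag$site_id)
        paired <- length(shared) == nrow(lead) &&
            nrow(lead) == nrow(lag) && length(shared) >= 2
        test <- tryCatch(
            if (paired) {
                o <- order(lead$site_id)
                o2 <- order(lag$site_id)
                t.test(lag$fold[o2], lead$fold[o], paired = TRUE)
            } else if (nrow(lead) >= 2 && nrow(lag) >= 2) {
                t.test(lag$fold, lead$fold)
            } else NULL,
            error = function(e) NULL)   # e.g. zero-variance folds
    } else {
        warning("collision class without sites: ",
                paste(missing_class, collapse = ", "),
                "; partial report")
    }
    out <- list(folds = folds, class_means = cm, test = test,
                paired = paired)
    class(out) <- "AsymmetryTable"
    out
}

#' @export
print.AsymmetryTable <- function(x, ...) {
    cat("Strand-asymmetry report (fold change mutant/wild-type)\n")
    print(x$folds, row.names = FALSE)
    cat("class means:", paste(names(x$class_means),
                              sprintf("%.3f", x$class_means),
                              collapse = " | "), "\n")
    if (!is.null(x$test))
        cat(sprintf("%s t test: t = %.3f, p = %.4g\n",
                    if (x$paired) "paired" else "unpaired",
                    x$test$statistic, x$test$p.value))
    invisible(x)
}

#' Group comparison with the study's standard tests
#'
#' Thin provenance-recording wrapper over `stats`: two-tailed Student's t
#' (pooled variance), Welch t, two-tailed Mann-Whitney (Wilcoxon rank
#' sum), or one-way ANOVA with Tukey's multiple comparisons.
#'
#' @param values numeric measurements.
#' @param group group labels (2 groups for the two-sample tests; any
#'   number for `anova_tukey`).
#' @param test one of `"t_two_tailed"`, `"welch_t"`, `"mann_whitney"`,
#'   `"anova_tukey"`.
#' @return list with `test`, `statistic`, `p_value` and the underlying
#'   object (`fit`); for `anova_tukey`, `tukey` holds the pairwise table.
#' @export
compare_groups <- function(values, group,
                           test = c("t_two_tailed", "welch_t",
                                    "mann_whitney", "anova_tukey")) {
    test <- match.arg(test)
    group <- factor(group)
    if (test != "anova_tukey" && nlevels(group) != 2)
        stop("two-sample test requires exactly two groups")
    split_v <- split(values, group)
    out <- switch(test,
        t_two_tailed = {
            ht <- t.test(split_v[[1]], split_v[[2]], var.equal = TRUE)
            list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 fit = ht)
        },
        welch_t = {
            ht <- t.test(split_v[[1]], split_v[[2]])
            list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 fit = ht)
        },
        mann_whitney = {
            ht <- wilcox.test(split_v[[1]], split_v[[2]], exact = FALSE)
            list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 fit = ht)
        },
        anova_tukey = {
            fit <- aov(values ~ group)
            tk <- TukeyHSD(fit)
            pv <- summary(fit)[[1]][["Pr(>F)"]][1]
            list(statistic = summary(fit)[[1]][["F value"]][1],
                 p_value = pv, fit = fit, tukey = tk$group)
        })
    c(list(test = test), out)
}
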