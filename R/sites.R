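#' Target sites, nicked strands and replication-collision classes
#'
#' `target_site()` describes a protospacer for Cas9 or a Cas9 nickase
#' (D10A, "Cas9D"; H840A, "Cas9H") on a reporter or locus.  Coordinates are
#' 0-based on the Watson strand; `cut_pos` is the between-base index of the
#' blunt cut (or nick), placed 3 nt 5' of the PAM on the protospacer strand.
#'
#' @param site_id identifier.
#' @param protospacer 20-nt protospacer sequence (on `pam_strand`).
#' @param pam_strand `"Watson"` or `"Crick"`: strand carrying the NGG PAM.
#' @param nickase one of `"Cas9"`, `"Cas9D"`, `"Cas9H"`, `"dCas9"`,
#'   `"ISceI"`.
#' @param cut_pos 0-based between-base cut/nick index on Watson.
#' @param reference optional reference sequence; when given, the protospacer
#'   and NGG PAM are verified to occur at `cut_pos` on `pam_strand`.
#' @return an object of class `TargetSite`.
#' @export
target_site <- function(site_id, protospacer, pam_strand = c("Watson", "Crick"),
                        nickase = c("Cas9", "Cas9D", "Cas9H", "dCas9", "ISceI"),
                        cut_pos, reference = NULL) {
    pam_strand <- match.arg(pam_strand)
    nickase <- match.arg(nickase)
    site <- list(site_id = site_id, protospacer = toupper(protospacer),
                 pam_strand = pam_strand, nickase = nickase,
                 cut_pos = as.integer(cut_pos))
    class(site) <- "TargetSite"
    if (!is.null(reference)) validate_site(site, reference)
    site
}

#' @export
print.TargetSite <- function(x, ...) {
    cat("TargetSite", x$site_id, ":", x$nickase, "| PAM on", x$pam_strand,
        "| cut at", x$cut_pos, "\n")
    invisible(x)
}

## verify protospacer + NGG at the stated cut position
validate_site <- function(site, reference) {
    if (site$nickase == "ISceI") return(invisible(site))
    if (nchar(site$protospacer) != 20L)
        stop("protospacer must be 20 nt")
    if (site$pam_strand == "Watson") {
        proto_start <- site$cut_pos - 17L       # cut 3 nt 5' of PAM
        obs <- substr(reference, proto_start + 1L, proto_start + 20L)
        pam <- substr(reference, proto_start + 21L, proto_start + 23L)
    } else {
        proto_end <- site$cut_pos + 17L         # 0-based end (exclusive)
        obs <- revcomp(substr(reference, proto_end - 19L, proto_end))
        pam <- revcomp(substr(reference, proto_end - 22L, proto_end - 20L))
    }
    if (obs != site$protospacer)
        stop("protospacer does not occur at the stated cut position (",
             site$site_id, ")")
    if (substr(pam, 2L, 3L) != "GG")
        stop("no NGG PAM adjacent to protospacer (", site$site_id, ")")
    invisible(site)
}

#' Derive a target site from a desired cut position
#'
#' Scans the reference near `target_cut` for NGG PAMs on the requested
#' strand and returns the [target_site()] whose blunt-cut position (3 nt 5'
#' of the PAM) is nearest the requested cut.
#'
#' @param reference reference sequence (character) or `ReporterConstruct`.
#' @param site_id identifier for the new site.
#' @param target_cut desired 0-based cut position.
#' @param pam_strand strand to search for the PAM.
#' @param nickase enzyme for the site.
#' @param search_window how far from `target_cut` to search.
#' @export
site_from_position <- function(reference, site_id, target_cut,
                               pam_strand = c("Watson", "Crick"),
                               nickase = "Cas9", search_window = 80L) {
    pam_strand <- match.arg(pam_strand)
    if (inherits(reference, "ReporterConstruct"))
        reference <- reference$sequence
    n <- nchar(reference)
    lo <- max(24L, target_cut - search_window)
    hi <- min(n - 24L, target_cut + search_window)
    region <- substr(reference, lo + 1L, hi)
    strand_seq <- if (pam_strand == "Watson") region else revcomp(region)
    gg <- gregexpr("GG", strand_seq)[[1L]]
    if (gg[1L] == -1L) stop("no NGG PAM near requested position")
    gg <- as.integer(gg)
    cuts <- if (pam_strand == "Watson") lo + gg - 5L else hi - gg + 5L
    ## need 20 nt of protospacer on the PAM-proximal side
    ok <- if (pam_strand == "Watson") cuts - 17L >= 0L & cuts + 3L <= n - 3L
          else cuts + 17L <= n & cuts - 6L >= 0L
    gg <- gg[ok]; cuts <- cuts[ok]
    if (length(cuts) == 0) stop("no usable PAM near requested position")
    i <- which.min(abs(cuts - target_cut))
    cut <- cuts[i]
    proto <- if (pam_strand == "Watson")
        substr(reference, cut - 16L, cut + 3L)
    else revcomp(substr(reference, cut - 2L, cut + 17L))
    target_site(site_id, proto, pam_strand, nickase, cut,
                reference = reference)
}

#' Strand nicked by a Cas9 variant
#'
#' The D10A nickase (RuvC-dead) cuts the target strand, i.e. the strand
#' base-paired with the sgRNA: the complement of the PAM strand.  The H840A
#' nickase (HNH-dead) cuts the non-target strand: the PAM strand itself.
#' Catalytically active Cas9 cuts both strands; dCas9 cuts none; I-SceI
#' makes a two-ended DSB ("both").
#'
#' @param nickase `"Cas9"`, `"Cas9D"`, `"Cas9H"`, `"dCas9"` or `"ISceI"`
#'   (vectorized).
#' @param pam_strand `"Watson"` or `"Crick"` (vectorized).
#' @return `"Watson"`, `"Crick"`, `"both"` or `"none"`.
#' @examples
#' nicked_strand("Cas9D", "Watson")  # "Crick"
#' nicked_strand("Cas9H", "Watson")  # "Watson"
#' @export
nicked_strand <- function(nickase, pam_strand) {
    stopifnot(all(nickase %in% c("Cas9", "Cas9D", "Cas9H", "dCas9", "ISceI")),
              all(pam_strand %in% c("Watson", "Crick")))
    other <- c(Watson = "Crick", Crick = "Watson")
    out <- character(max(length(nickase), length(pam_strand)))
    nickase <- rep_len(nickase, length(out))
    pam_strand <- rep_len(pam_strand, length(out))
    out[nickase %in% c("Cas9", "ISceI")] <- "both"
    out[nickase == "dCas9"] <- "none"
    out[nickase == "Cas9D"] <- other[pam_strand[nickase == "Cas9D"]]
    out[nickase == "Cas9H"] <- pam_strand[nickase == "Cas9H"]
    out
}

#' Replication-collision class of a nick
#'
#' A nick is converted into a one-ended DSB when a replication fork runs
#' into it.  If the nicked strand serves as the leading-strand template of
#' that fork the collapse is a "lead" collapse; if it is the lagging-strand
#' template, a "lag" collapse.  With the fixed convention that the Crick
#' strand is the leading-strand template of a rightward-moving fork (and
#' Watson of a leftward fork), the class is determined by the pair
#' (nicked strand, fork direction).  Two-ended or absent lesions
#' (`"both"`/`"none"`) have no collision class.
#'
#' @param nicked_strand `"Watson"`, `"Crick"`, `"both"` or `"none"`
#'   (vectorized).
#' @param fork_direction `"rightward"` or `"leftward"` (vectorized).
#' @return `"lead"`, `"lag"` or `"none"`.
#' @examples
#' collision_class("Crick", "rightward")   # "lead"
#' collision_class("Watson", "rightward")  # "lag"
#' @export
collision_class <- function(nicked_strand, fork_direction) {
    stopifnot(all(nicked_strand %in% c("Watson", "Crick", "both", "none")),
              all(fork_direction %in% c("rightward", "leftward")))
    n <- max(length(nicked_strand), length(fork_direction))
    nicked_strand <- rep_len(nicked_strand, n)
    fork_direction <- rep_len(fork_direction, n)
    leading_template <- ifelse(fork_direction == "rightward",
                               "Crick", "Watson")
    out <- rep("none", n)
    single <- nicked_strand %in% c("Watson", "Crick")
    out[single] <- ifelse(nicked_strand[single] == leading_template[single],
                          "lead", "lag")
    out
}

#' Full nickase x PAM-strand x fork-direction collision table
#'
#' Enumerates all eight (nickase, PAM strand, fork direction) combinations
#' for the two nickases and derives nicked strand and collision class.
#' @return data.frame with columns `nickase`, `pam_strand`,
#'   `fork_direction`, `nicked_strand`, `collision_class`.
#' @export
collision_table <- function() {
    g <- expand.grid(nickase = c("Cas9D", "Cas9H"),
                     pam_strand = c("Watson", "Crick"),
                     fork_direction = c("rightward", "leftward"),
                     stringsAsFactors = FALSE)
    g$nicked_strand <- nicked_strand(g$nickase, g$pam_strand)
    g$collision_class <- collision_class(g$nicked_strand, g$fork_direction)
    g
}

#' Collision context for a target site
#'
#' @param site a `TargetSite`.
#' @param fork_direction fork relevant to the measured product
#'   (`"rightward"` for the SCR reporter's LTGC/TD-visible products).
#' @return list of class `CollisionContext`.
#' @export
collision_context <- function(site, fork_direction = c("rightward",
                                                       "leftward")) {
    fork_direction <- match.arg(fork_direction)
    ns <- nicked_strand(site$nickase, site$pam_strand)
    ctx <- list(site = site, fork_direction = fork_direction,
                nicked_strand = ns,
                collision_class = collision_class(ns, fork_direction))
    class(ctx) <- "CollisionContext"
    ctx
}

#' Load target sites from a YAML configuration
#'
#' The file holds a list of records with fields `site_id`, `protospacer`,
#' `pam_strand`, `nickase`, `cut_pos` and optionally `fork_direction`.
#' sgRNA-to-PAM-strand assignments are data, not constants, and are meant
#' to be edited per experiment.
#'
#' @param path YAML file.
#' @param reference optional reference for validation.
#' @return list of `TargetSite` objects (named by `site_id`), each with a
#'   `fork_direction` attribute when present in the file.
#' @export
load_sites <- function(path, reference = NULL) {
    recs <- yaml::read_yaml(path)
    sites <- lapply(recs, function(r) {
        s <- target_site(r$site_id, r$protospacer, r$pam_strand, r$nickase,
                         r$cut_pos, reference = reference)
        if (!is.null(r$fork_direction))
            attr(s, "fork_direction") <- r$fork_direction
        s
    })
    names(sites) <- vapply(sites, `[[`, "", "site_id")
    sites
}
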