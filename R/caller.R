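CANONICAL_POSITIONS <- c("NOTCH2", "NOTCH2NLR", "NOTCH2NLA", "NOTCH2NLB",
                         "NOTCH2NLC")

#' Haplotype configuration catalog
#'
#' One row per configuration (H1-H10), one column per canonical position
#' holding the identity state at that position: a paralog label, a
#' converted-label (`NOTCH2NLA` at the NLB position for a B-to-A conversion,
#' `NOTCH2tv` at the NLR position), `absent`, or `hybrid`. `deletion_class`
#' flags the configurations representing deletion events.
#'
#' The default encodes: H1 canonical; H2/H4/H8/H9 deletion-class; H3/H6
#' NOTCH2tv; H4/H5/H6/H9 B-to-A; H7/H8 lacking NLC; H10 an NLC A/B hybrid.
#' The NLR deletion on H10 and the full H9 composition (NLR and NLC deleted,
#' B-to-A) are catalog choices where the published constraints alone do not
#' pin down a unique, mutually distinct set of templates; the catalog is an
#' editable table precisely so alternative compositions can be swapped in.
#'
#' @return data.frame with columns `config_label`, the five canonical
#'   positions, and `deletion_class`
#' @export
config_catalog <- function() {
  catalog <- data.frame(
    config_label = paste0("H", 1:10),
    NOTCH2 = "NOTCH2",
    NOTCH2NLR = c("NOTCH2NLR", "absent", "NOTCH2tv", "absent", "NOTCH2NLR",
                  "NOTCH2tv", "NOTCH2NLR", "absent", "absent", "absent"),
    NOTCH2NLA = "NOTCH2NLA",
    NOTCH2NLB = c("NOTCH2NLB", "NOTCH2NLB", "NOTCH2NLB", "NOTCH2NLA",
                  "NOTCH2NLA", "NOTCH2NLA", "NOTCH2NLB", "NOTCH2NLB",
                  "NOTCH2NLA", "NOTCH2NLB"),
    NOTCH2NLC = c("NOTCH2NLC", "NOTCH2NLC", "NOTCH2NLC", "NOTCH2NLC",
                  "NOTCH2NLC", "NOTCH2NLC", "absent", "absent", "absent",
                  "hybrid"),
    deletion_class = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                       TRUE, FALSE),
    stringsAsFactors = FALSE)
  validate_catalog(catalog)
  catalog
}

validate_catalog <- function(catalog) {
  stopifnot(all(c("config_label", CANONICAL_POSITIONS, "deletion_class") %in%
                  names(catalog)))
  if (anyDuplicated(catalog$config_label)) stop("duplicate config labels")
  keys <- apply(catalog[, CANONICAL_POSITIONS], 1, paste, collapse = "|")
  if (anyDuplicated(keys)) stop("configuration templates must be distinct")
  invisible(catalog)
}

catalog_positions <- function(catalog) CANONICAL_POSITIONS

catalog_states <- function(catalog, label) {
  row <- catalog[catalog$config_label == label, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown configuration label: ", label)
  as.list(row[1, CANONICAL_POSITIONS])
}

#' Read / write a configuration catalog as TSV
#'
#' @param file path
#' @return the catalog data.frame (`read_catalog`)
#' @export
read_catalog <- function(file) {
  catalog <- read.delim(file, stringsAsFactors = FALSE)
  catalog$deletion_class <- as.logical(catalog$deletion_class)
  validate_catalog(catalog)
}

#' @rdname read_catalog
#' @param catalog a catalog data.frame
#' @export
write_catalog <- function(catalog, file) {
  validate_catalog(catalog)
  write.table(catalog, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Integrate the three identity signals into a paralog call
#'
#' Rules, applied in order: (1) transcript = clade = location: a clean call;
#' (2) transcript = clade but both differ from location: an interlocus
#' gene-conversion call, donor from the sequence signals and acceptor from
#' the map location -- the special case of a NOTCH2 donor at the NOTCH2NLR
#' location is the NOTCH2tv state; (3) a tied NOTCH2NLA/NOTCH2NLB transcript
#' at the NOTCH2NLC location is the A/B-hybrid state; (4) disagreement
#' between transcript and clade leaves the call ambiguous (tract delineation
#' can still be attempted). An ambiguous map location also leaves the call
#' ambiguous, since the acceptor position is then unknown.
#'
#' @param triplet a list with `locus`, `transcript` (a `transcript_match`),
#'   `clade` (a `clade_assignment`), `location` (from [assign_location()]),
#'   and optionally `deleted`
#' @return a `paralog_call`: list with `locus`, `position`, `status` (one of
#'   clean/igc/ambiguous/deleted), `consensus_label`, `igc`, `donor_label`,
#'   `acceptor_label`, `tract`
#' @export
call_paralog <- function(triplet) {
  call <- list(locus = triplet$locus, position = triplet$location$label,
               status = "ambiguous", consensus_label = NA_character_,
               igc = FALSE, donor_label = NA_character_,
               acceptor_label = NA_character_, tract = NULL,
               transcript = triplet$transcript, clade = triplet$clade,
               location = triplet$location)
  if (isTRUE(triplet$deleted)) {
    call$status <- "deleted"
    call$position <- triplet$position
    call$consensus_label <- "absent"
    return(structure(call, class = "paralog_call"))
  }
  tl <- triplet$transcript$best_label
  cl <- triplet$clade$clade_label
  ll <- triplet$location$label
  if (ll == "ambiguous") {
    return(structure(call, class = "paralog_call"))
  }
  if (tl == cl && tl == ll) {
    call$status <- "clean"
    call$consensus_label <- tl
  } else if (tl == cl && tl != "ambiguous") {
    call$status <- "igc"
    call$igc <- TRUE
    call$donor_label <- tl
    call$acceptor_label <- ll
    call$consensus_label <-
      if (tl == "NOTCH2" && ll == "NOTCH2NLR") "NOTCH2tv" else tl
  } else if (tl == "ambiguous" &&
             setequal(triplet$transcript$tied, c("NOTCH2NLA", "NOTCH2NLB")) &&
             ll == "NOTCH2NLC") {
    call$status <- "igc"
    call$igc <- TRUE
    call$donor_label <- "NOTCH2NLA|NOTCH2NLB"
    call$acceptor_label <- ll
    call$consensus_label <- "hybrid"
  }
  structure(call, class = "paralog_call")
}

#' @export
print.paralog_call <- function(x, ...) {
  cat(sprintf("<paralog_call> %s at %s: %s%s\n", x$locus, x$position, x$status,
              if (x$igc) sprintf(" (%s -> %s)", x$donor_label,
                                 x$acceptor_label) else ""))
  invisible(x)
}

#' Delineate a gene-conversion tract from a window identity profile
#'
#' The tract is the maximal run of at least `min_run` consecutive windows in
#' which identity to the expected donor both exceeds identity to the
#' location's own reference and reaches the profile's threshold.
#'
#' @param profile a `window_profile` over `c(donor, location_ref)`
#' @param donor,location_ref candidate names inside the profile
#' @param min_run minimum run length in windows (3 by default)
#' @return `c(start, end)` in acceptor coordinates, or `NULL` when no run
#'   qualifies
#' @export
delineate_tract <- function(profile, donor, location_ref, min_run = 3) {
  stopifnot(donor %in% names(profile), location_ref %in% names(profile))
  threshold <- attr(profile, "threshold")
  idd <- profile[[donor]]
  idr <- profile[[location_ref]]
  fav <- !is.na(idd) & idd >= threshold & (is.na(idr) | idd > idr)
  r <- rle(fav)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= min_run)
  if (length(good) == 0) return(NULL)
  gi <- good[which.max(r$lengths[good])]
  c(profile$window_start[starts[gi]], profile$window_end[ends[gi]])
}

#' Classify a haplotype into a configuration
#'
#' Builds the per-position state vector from the paralog calls and matches
#' it against the catalog; a haplotype matching no template is `"novel"`.
#' Positions with no call are treated as absent.
#'
#' @param calls list of `paralog_call`s for one haplotype
#' @param catalog a configuration catalog
#' @return a `haplotype_configuration`: list with `haplotype_id`, `states`
#'   (named by canonical position) and `config_label`
#' @export
classify_haplotype <- function(calls, catalog = config_catalog()) {
  positions <- catalog_positions(catalog)
  states <- setNames(rep("absent", length(positions)), positions)
  seen <- character()
  hap <- NA_character_
  for (call in calls) {
    pos <- call$position
    if (is.na(pos) || !pos %in% positions) next
    if (pos %in% seen) stop("two calls at canonical position ", pos)
    seen <- c(seen, pos)
    if (!is.null(call$haplotype)) hap <- call$haplotype
    states[pos] <- switch(call$status,
                          clean = call$consensus_label,
                          igc = call$consensus_label,
                          deleted = "absent",
                          "ambiguous")
  }
  tmpl <- catalog[, positions, drop = FALSE]
  hit <- which(apply(tmpl, 1, function(row) all(row == states)))
  label <- if (length(hit) == 1) catalog$config_label[hit] else "novel"
  structure(list(haplotype_id = hap, states = states, config_label = label),
            class = "haplotype_configuration")
}

#' @export
print.haplotype_configuration <- function(x, ...) {
  cat(sprintf("<haplotype_configuration> %s: %s (%s)\n", x$haplotype_id,
              x$config_label, paste(x$states, collapse = ", ")))
  invisible(x)
}

# identity-count bookkeeping for one state vector
state_identities <- function(states) {
  v <- states[states != "absent" & states != "ambiguous"]
  table(factor(v, levels = c("NOTCH2", "NOTCH2NLR", "NOTCH2tv", "NOTCH2NLA",
                             "NOTCH2NLB", "NOTCH2NLC", "hybrid")))
}

#' Summarize a cohort of haplotype configurations
#'
#' Counts and integer percentages per configuration (rounded half away from
#' zero), the fraction lacking NOTCH2NLR (deleted or converted away), the
#' fraction in deletion-class configurations, the fractions with a B-to-A
#' conversion, with NOTCH2tv, and with at least one interlocus
#' gene-conversion event (union: haplotypes carrying both count once),
#' per-paralog identity copy numbers, and flags for any haplotype violating
#' the constancy of the combined NOTCH2NLA + NOTCH2NLB copy number (2 in all
#' human haplotypes).
#'
#' @param configs list of `haplotype_configuration`s
#' @param catalog the catalog the configurations were classified against
#' @return a `cohort_summary` list; see `print()` for the structured report
#' @export
cohort_summary <- function(configs, catalog = config_catalog()) {
  if (length(configs) == 0) stop("empty cohort")
  n <- length(configs)
  labels <- vapply(configs, `[[`, character(1), "config_label")
  states <- do.call(rbind, lapply(configs, `[[`, "states"))
  pct <- function(k) round_half_away(100 * k / n)
  counts <- table(factor(labels, levels = c(catalog$config_label, "novel")))
  lacking_nlr <- states[, "NOTCH2NLR"] != "NOTCH2NLR"
  deletion <- labels %in% catalog$config_label[catalog$deletion_class]
  b_to_a <- states[, "NOTCH2NLB"] == "NOTCH2NLA"
  tv <- states[, "NOTCH2NLR"] == "NOTCH2tv"
  igc_union <- b_to_a | tv
  ids <- t(apply(states, 1, state_identities))
  ab_sum <- ids[, "NOTCH2NLA"] + ids[, "NOTCH2NLB"]
  # the A+B=2 constraint applies to every haplotype: hybrid NLC and deleted
  # NLR/NLC do not feed into it, so only A/B-position anomalies flag
  flags <- which(ab_sum != 2)
  structure(list(
    n = n,
    config_counts = counts,
    config_percent = setNames(pct(as.numeric(counts)), names(counts)),
    lacking_nlr_count = sum(lacking_nlr),
    lacking_nlr_percent = pct(sum(lacking_nlr)),
    deletion_count = sum(deletion),
    deletion_percent = pct(sum(deletion)),
    b_to_a_count = sum(b_to_a),
    b_to_a_percent = pct(sum(b_to_a)),
    notch2tv_count = sum(tv),
    notch2tv_percent = pct(sum(tv)),
    igc_union_count = sum(igc_union),
    igc_union_percent = pct(sum(igc_union)),
    both_igc_count = sum(b_to_a & tv),
    copy_numbers = colSums(ids),
    ab_sum_violations = flags),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary over %d haplotypes\n", x$n))
  cat("  configurations:\n")
  for (l in names(x$config_counts)) {
    if (x$config_counts[[l]] == 0) next
    cat(sprintf("    %-6s %3d (%d%%)\n", l, x$config_counts[[l]],
                x$config_percent[[l]]))
  }
  cat(sprintf("  lacking NOTCH2NLR: %d (%d%%)\n", x$lacking_nlr_count,
              x$lacking_nlr_percent))
  cat(sprintf("  deletion-class configurations: %d (%d%%)\n",
              x$deletion_count, x$deletion_percent))
  cat(sprintf("  B-to-A conversion: %d (%d%%)\n", x$b_to_a_count,
              x$b_to_a_percent))
  cat(sprintf("  NOTCH2tv: %d (%d%%)\n", x$notch2tv_count,
              x$notch2tv_percent))
  cat(sprintf("  any gene conversion (union): %d (%d%%), both: %d\n",
              x$igc_union_count, x$igc_union_percent, x$both_igc_count))
  cat(sprintf("  A+B copy-number violations: %d\n",
              length(x$ab_sum_violations)))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test (hypergeometric) with the conditional
#' maximum-likelihood odds ratio, as used for testing population enrichment
#' of a haplotype class.
#'
#' @param tab 2x2 non-negative integer matrix
#' @return list with `odds_ratio` and `p_value`
#' @export
enrichment_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must hold non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all-zero margin")
  }
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
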