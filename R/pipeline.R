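#' Reference panel for the tripartite identity workflow
#'
#' Extracts, from a simulated (or assembled) paralog family, the three
#' reference resources the workflow compares against: the CDS panel for the
#' best-transcript-match signal, the intron panel (plus outgroup) for the
#' phylogenetic-clade signal, and the duplicon barcodes for the map-location
#' signal.
#'
#' @param family a `paralog_family`
#' @param intron which intron carries the phylogenetic signal (2 by default)
#' @return list with `cds`, `introns`, `outgroup_intron`, `barcodes`,
#'   `records`, `outgroup`
#' @export
reference_panel <- function(family, intron = 2) {
  recs <- family$records
  cds <- vapply(recs, extract_cds, character(1))
  introns <- vapply(recs, extract_intron, character(1), which = intron)
  barcodes <- lapply(recs, function(r) {
    extract_barcode(r$tokens, c(min(r$exons$start), max(r$exons$end)),
                    window = nchar(r$seq), locus_label = r$label)
  })
  list(cds = cds, introns = introns,
       outgroup_intron = extract_intron(family$outgroup, which = intron),
       outgroup_label = family$outgroup$label,
       barcodes = barcodes, records = recs, outgroup = family$outgroup,
       intron = intron)
}

#' Compute the three identity signals for one locus
#'
#' Best transcript match of the extracted CDS against the panel;
#' neighbor-joining clade of the intron sequence within the panel tree
#' (outgroup included); map location by nearest duplicon barcode.
#'
#' @param record a `locus_record`
#' @param panel from [reference_panel()]
#' @param window barcode window in bp (defaults to the whole record)
#' @return an evidence triplet: list with `locus`, `transcript`, `clade`,
#'   `location`
#' @export
locus_evidence <- function(record, panel, window = NULL) {
  if (is.null(window)) window <- nchar(record$seq)
  transcript <- best_transcript_match(extract_cds(record), panel$cds)
  seqs <- c(setNames(list(extract_intron(record, which = panel$intron)),
                     "query"),
            as.list(panel$introns),
            setNames(list(panel$outgroup_intron), panel$outgroup_label))
  seqs <- vapply(seqs, identity, character(1))
  tree <- nj_tree(jc69_matrix(seqs))
  clade <- assign_clade(tree, "query", names(panel$introns))
  qbc <- extract_barcode(record$tokens,
                         c(min(record$exons$start), max(record$exons$end)),
                         window = window,
                         locus_label = record$label)
  location <- assign_location(qbc, panel$barcodes)
  list(locus = paste0(record$haplotype, "|", record$position),
       haplotype = record$haplotype, transcript = transcript, clade = clade,
       location = location)
}

# window-profile based tract delineation for one conversion call
delineate_call_tract <- function(record, call, panel, window_size = 1000,
                                 threshold = 99.9, min_run = 3, ...) {
  donor <- call$donor_label
  if (is.na(donor) || !donor %in% names(panel$records)) return(NULL)
  loc <- call$acceptor_label
  if (is.na(loc) || !loc %in% names(panel$records)) return(NULL)
  cands <- c(setNames(locus_seq(panel$records[[donor]]), donor),
             setNames(locus_seq(panel$records[[loc]]), loc))
  wp <- window_identity(locus_seq(record), cands, window_size = window_size,
                        threshold = threshold, ...)
  delineate_tract(wp, donor, loc, min_run = min_run)
}

#' Run the tripartite workflow over a cohort
#'
#' For every assembled locus: compute the evidence triplet, integrate it into
#' a paralog call, and (for gene-conversion calls with a single donor)
#' delineate the conversion tract from a windowed identity profile. Canonical
#' positions claimed by no locus are called deleted. Haplotypes are then
#' classified against the configuration catalog and summarized.
#'
#' @param cohort a `sim_cohort` (or the result of [read_cohort()])
#' @param panel a [reference_panel()]; defaults to the cohort's own family
#' @param catalog a configuration catalog
#' @param window_size,threshold,min_run tract delineation parameters
#' @param delineate attempt tract delineation on conversion calls
#' @return list with `calls` (data.frame), `configs` (list of
#'   `haplotype_configuration`), `summary` (a `cohort_summary`)
#' @export
call_cohort <- function(cohort, panel = NULL, catalog = config_catalog(),
                        window_size = 1000, threshold = 99.9, min_run = 3,
                        delineate = TRUE) {
  if (is.null(panel)) {
    if (is.null(cohort$family)) {
      stop("no panel given and the cohort carries no family; build one with reference_panel()")
    }
    panel <- reference_panel(cohort$family)
  }
  positions <- catalog_positions(catalog)
  rows <- list()
  configs <- list()
  for (hap_id in names(cohort$haplotypes)) {
    loci <- cohort$haplotypes[[hap_id]]
    calls <- list()
    for (rec in loci) {
      ev <- locus_evidence(rec, panel)
      call <- call_paralog(ev)
      call$haplotype <- hap_id
      if (delineate && call$igc && call$consensus_label != "hybrid") {
        call$tract <- delineate_call_tract(rec, call, panel,
                                           window_size = window_size,
                                           threshold = threshold,
                                           min_run = min_run)
      }
      calls[[length(calls) + 1L]] <- call
    }
    claimed <- vapply(calls, function(x) x$position, character(1))
    for (pos in setdiff(positions, claimed)) {
      call <- call_paralog(list(locus = paste0(hap_id, "|", pos),
                                position = pos, deleted = TRUE))
      call$haplotype <- hap_id
      calls[[length(calls) + 1L]] <- call
    }
    configs[[hap_id]] <- classify_haplotype(calls, catalog)
    configs[[hap_id]]$haplotype_id <- hap_id
    for (call in calls) {
      rows[[length(rows) + 1L]] <- data.frame(
        haplotype = hap_id, locus = call$locus, position = call$position,
        transcript = if (is.null(call$transcript)) NA_character_ else
          call$transcript$best_label,
        transcript_margin = if (is.null(call$transcript)) NA_real_ else
          call$transcript$margin,
        clade = if (is.null(call$clade)) NA_character_ else
          call$clade$clade_label,
        clade_margin = if (is.null(call$clade)) NA_real_ else
          call$clade$patristic_margin,
        location = if (is.null(call$location)) call$position else
          call$location$label,
        location_margin = if (is.null(call$location)) NA_real_ else
          call$location$margin,
        status = call$status, consensus = call$consensus_label,
        donor = call$donor_label, acceptor = call$acceptor_label,
        tract_start = if (is.null(call$tract)) NA_integer_ else call$tract[1],
        tract_end = if (is.null(call$tract)) NA_integer_ else call$tract[2],
        stringsAsFactors = FALSE)
    }
  }
  list(calls = do.call(rbind, rows), configs = configs,
       summary = cohort_summary(configs, catalog))
}
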