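#' Annotate duplicon tokens along a sequence
#'
#' Places library elements on the sequence by approximate pattern matching
#' (both orientations, repeats included), keeping non-overlapping
#' best-scoring placements that reach `min_identity`. Each candidate hit is
#' re-aligned globally with unit costs to score its identity. A stand-in for
#' an external duplicon masker, sufficient for token libraries of a few
#' hundred bp.
#'
#' @param sequence character scalar
#' @param library named character vector of token consensus sequences
#' @param min_identity minimum percent identity of a reported placement
#' @return data.frame(start, end, token_id, strand, identity) sorted by
#'   coordinate (0-based half-open)
#' @export
annotate_duplicons <- function(sequence, library, min_identity = 90) {
  stopifnot(length(library) >= 1, !is.null(names(library)))
  subject <- Biostrings::DNAString(sequence)
  hits <- list()
  for (id in names(library)) {
    for (strand in c("+", "-")) {
      tok <- if (strand == "+") library[[id]] else revcomp(library[[id]])
      max_mm <- ceiling((1 - min_identity / 100) * nchar(tok))
      m <- Biostrings::matchPattern(Biostrings::DNAString(tok), subject,
                                    max.mismatch = max_mm, with.indels = TRUE)
      for (i in seq_along(m)) {
        s0 <- Biostrings::start(m)[i] - 1L
        e0 <- Biostrings::end(m)[i]
        al <- nw_align(tok, substr(sequence, s0 + 1, e0))
        idy <- alignment_identity(al$matches, al$mismatches, al$cigar)
        if (is.na(idy) || idy < min_identity) next
        hits[[length(hits) + 1L]] <- data.frame(
          start = s0, end = e0, token_id = id, strand = strand,
          identity = idy, score = al$matches, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      token_id = character(), strand = character(),
                      identity = numeric()))
  }
  hits <- do.call(rbind, hits)
  # resolve overlaps on the sequence by score, ties leftmost
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  occ <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(hits))) {
    if (nrow(occ) > 0 && any(hits$start[i] < occ[, 2] & hits$end[i] > occ[, 1])) next
    keep[i] <- TRUE
    occ <- rbind(occ, c(hits$start[i], hits$end[i]))
  }
  hits <- hits[keep, c("start", "end", "token_id", "strand", "identity")]
  hits[order(hits$start), , drop = FALSE]
}

#' Extract the duplicon barcode around a gene
#'
#' Tokens whose midpoint lies within `window` bp of the gene interval, in
#' coordinate order: the ordered, oriented duplicon context that identifies a
#' locus's long-range genomic position.
#'
#' @param tokens data.frame(start, end, token_id, strand)
#' @param gene_interval `c(start, end)`, 0-based half-open
#' @param window bp on each side of the gene (1 Mbp for full-scale regions;
#'   use the simulated flank length for synthetic cohorts)
#' @param locus_label label carried on the barcode
#' @return an `sd_barcode`: data.frame(token_id, strand) with attributes
#' @export
extract_barcode <- function(tokens, gene_interval, window = 1e6,
                            locus_label = "locus") {
  stopifnot(window >= 0, length(gene_interval) == 2)
  if (nrow(tokens) == 0 || window == 0) {
    tk <- data.frame(token_id = character(), strand = character())
  } else {
    mid <- (tokens$start + tokens$end) / 2
    keep <- mid >= gene_interval[1] - window & mid <= gene_interval[2] + window
    tk <- tokens[keep, c("token_id", "strand"), drop = FALSE]
    tk <- tk[order(tokens$start[keep]), , drop = FALSE]
    rownames(tk) <- NULL
  }
  structure(tk, class = c("sd_barcode", "data.frame"),
            locus_label = locus_label, window = window)
}

#' @export
print.sd_barcode <- function(x, ...) {
  cat(sprintf("<sd_barcode> %s: %s\n", attr(x, "locus_label"),
              paste(paste0(x$token_id, x$strand), collapse = " ")))
  invisible(x)
}

# each distinct (token_id, strand) pair is one symbol of the barcode alphabet
barcode_symbols <- function(...) {
  bcs <- list(...)
  toks <- unique(unlist(lapply(bcs, function(b) paste0(b$token_id, b$strand))))
  lapply(bcs, function(b) {
    match(paste0(b$token_id, b$strand), toks)
  })
}

#' Edit distance between two duplicon barcodes
#'
#' Unit-cost Levenshtein distance over token symbols; two tokens match iff
#' both `token_id` and orientation agree (token lengths are ignored). A
#' proper metric: symmetric, zero iff equal, triangle inequality holds.
#'
#' @param b1,b2 `sd_barcode` objects (or data.frames with `token_id`,
#'   `strand`)
#' @return non-negative integer
#' @export
barcode_distance <- function(b1, b2) {
  sym <- barcode_symbols(b1, b2)
  # map symbol integers to unicode points and use base adist
  s1 <- intToUtf8(sym[[1]] + 64L)
  s2 <- intToUtf8(sym[[2]] + 64L)
  as.integer(adist(s1, s2))
}

#' Assign a locus to its map location by nearest reference barcode
#'
#' @param query an `sd_barcode`
#' @param references named list of reference `sd_barcode`s (the canonical
#'   positions)
#' @return list with `label` (reference with minimum distance, or
#'   `"ambiguous"` on a tie), `margin` (second-minimum minus minimum) and the
#'   per-reference `distances`
#' @export
assign_location <- function(query, references) {
  if (length(references) == 0) stop("at least one reference barcode required")
  stopifnot(!is.null(names(references)))
  d <- vapply(references, function(r) barcode_distance(query, r), numeric(1))
  ord <- order(d, names(references))
  margin <- if (length(d) > 1) d[ord[2]] - d[ord[1]] else Inf
  label <- if (length(d) > 1 && margin == 0) "ambiguous" else names(references)[ord[1]]
  list(label = label, margin = unname(margin), distances = d)
}
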