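#' Extract the coding sequence of a locus record
#'
#' Exons are concatenated in transcription order; minus-strand gene models
#' are reverse-complemented. Exon coordinates are record coordinates, 0-based
#' half-open.
#'
#' @param record a `locus_record`
#' @return character scalar CDS
#' @export
extract_cds <- function(record) {
  stopifnot(inherits(record, "locus_record"))
  if (nrow(record$exons) == 0) stop("no gene model on record")
  if (any(record$exons$end > nchar(record$seq)) || any(record$exons$start < 0)) {
    stop("exon beyond sequence bounds")
  }
  parts <- vapply(seq_len(nrow(record$exons)), function(i) {
    substr(record$seq, record$exons$start[i] + 1, record$exons$end[i])
  }, character(1))
  cds <- paste(parts, collapse = "")
  if (identical(record$strand, "-")) revcomp(cds) else cds
}

#' Extract an intron from a locus record
#'
#' @param record a `locus_record`
#' @param which intron number (2 by default: the intron used for the
#'   phylogenetic identity signal)
#' @return character scalar
#' @export
extract_intron <- function(record, which = 2) {
  ex <- record$exons
  if (nrow(ex) < which + 1) stop("record has no intron ", which)
  substr(record$seq, ex$end[which] + 1, ex$start[which + 1])
}

#' Best transcript match of a CDS against a reference panel
#'
#' Global alignment with unit costs against every panel entry; mismatches are
#' substitutions plus indel bases. The best label has the fewest mismatches;
#' a tie returns label `"ambiguous"` with the tied labels attached (the
#' signature of an A/B-hybrid coding sequence).
#'
#' @param cds query coding sequence (non-empty)
#' @param panel named character vector of reference CDS
#' @return a `transcript_match`: list with `best_label`, `mismatches`,
#'   `margin`, `tied`, `per_label`
#' @export
best_transcript_match <- function(cds, panel) {
  if (!nzchar(cds)) stop("empty CDS")
  stopifnot(length(panel) >= 1, !is.null(names(panel)))
  mm <- vapply(panel, function(ref) {
    al <- nw_align(cds, ref)
    al$mismatches + al$insertions + al$deletions
  }, numeric(1))
  ord <- order(mm, names(panel))
  best <- mm[ord[1]]
  margin <- if (length(mm) > 1) mm[ord[2]] - best else Inf
  tied <- names(mm)[mm == best]
  label <- if (length(tied) > 1) "ambiguous" else names(panel)[ord[1]]
  structure(list(best_label = label, mismatches = unname(best),
                 margin = unname(margin), tied = sort(tied), per_label = mm),
            class = "transcript_match")
}

#' @export
print.transcript_match <- function(x, ...) {
  cat(sprintf("<transcript_match> %s (mismatches %d, margin %s)\n",
              x$best_label, x$mismatches,
              ifelse(is.finite(x$margin), x$margin, "inf")))
  invisible(x)
}

#' Proportion of differing sites between two aligned sequences
#'
#' Sites where either sequence carries a non-ACGT symbol (N, gap) are
#' excluded from both numerator and denominator.
#'
#' @param a,b aligned sequences of equal length
#' @return p, the fraction of comparable sites that differ
#' @export
p_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites")
  mean(x[ok] != y[ok])
}

#' Jukes-Cantor distance from a p-distance
#'
#' `d = -(3/4) * log(1 - (4/3) p)`; monotone in p on `[0, 0.75)`; errors at
#' saturation (`p >= 0.75`).
#'
#' @param p proportion of differing sites
#' @return substitutions per site under JC69
#' @export
jc69_distance <- function(p) {
  if (any(p >= 0.75)) stop("p >= 0.75: saturated, JC69 distance undefined")
  if (any(p < 0)) stop("p must be >= 0")
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix of aligned sequences
#'
#' @param seqs named character vector of equal-length aligned sequences
#' @return symmetric distance matrix
#' @export
jc69_matrix <- function(seqs) {
  n <- length(seqs)
  labels <- names(seqs)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      D[i, j] <- D[j, i] <- jc69_distance(p_distance(seqs[[i]], seqs[[j]]))
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via ape), with taxa ordered by label for a
#' deterministic tie-break, and negative branch lengths clamped to zero.
#'
#' @param D symmetric non-negative distance matrix with >= 3 labelled taxa
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("at least 3 taxa required")
  if (is.null(rownames(D))) stop("distance matrix must be labelled")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is asymmetric")
  if (any(D < 0)) stop("distances must be non-negative")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Assign a query leaf to the nearest reference clade
#'
#' The clade label is the reference leaf at minimum patristic distance to the
#' query; `monophyletic` is TRUE iff the smallest clade containing the query
#' and that reference holds no other reference label; a patristic tie flags
#' the assignment ambiguous.
#'
#' @param tree a `phylo`
#' @param query_leaf tip label of the query
#' @param reference_labels tip labels of the references (>= 2)
#' @return a `clade_assignment`: list with `clade_label`,
#'   `patristic_margin`, `monophyletic`, `distances`
#' @export
assign_clade <- function(tree, query_leaf, reference_labels) {
  stopifnot(length(reference_labels) >= 2)
  if (!query_leaf %in% tree$tip.label) stop("query leaf absent from tree")
  missing <- setdiff(reference_labels, tree$tip.label)
  if (length(missing) > 0) {
    stop("reference leaves absent from tree: ", paste(missing, collapse = ", "))
  }
  pat <- ape::cophenetic.phylo(tree)
  d <- pat[query_leaf, reference_labels]
  ord <- order(d, reference_labels)
  best <- reference_labels[ord[1]]
  margin <- d[ord[2]] - d[ord[1]]
  ambiguous <- margin == 0
  mono <- FALSE
  if (!ambiguous) {
    mrca <- ape::getMRCA(tree, c(query_leaf, best))
    clade_tips <- ape::extract.clade(tree, mrca)$tip.label
    mono <- !any(setdiff(reference_labels, best) %in% clade_tips)
  }
  structure(list(clade_label = if (ambiguous) "ambiguous" else best,
                 patristic_margin = unname(margin), monophyletic = mono,
                 distances = d),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf("<clade_assignment> %s (patristic margin %.4g, monophyletic %s)\n",
              x$clade_label, x$patristic_margin, x$monophyletic))
  invisible(x)
}

#' Strict-clock divergence time from distances
#'
#' `T = (d_pair / d_outgroup) * calibration`: constant-rate assumption, with
#' the outgroup split time as the calibration point. Scale-invariant in the
#' distances.
#'
#' @param d_pair distance between the two lineages
#' @param d_outgroup mean distance of the two lineages to the outgroup
#' @param calibration outgroup split time (15.2 MYA by default, a
#'   human-orangutan scale calibration)
#' @return estimated divergence time (same units as `calibration`)
#' @export
clock_time <- function(d_pair, d_outgroup, calibration = 15.2) {
  if (d_outgroup <= 0) stop("outgroup distance must be positive")
  (d_pair / d_outgroup) * calibration
}

#' Date a pairwise divergence under a strict clock
#'
#' JC69 distances are computed positionally from the aligned pair and
#' outgroup; the point estimate is `clock_time()` and the confidence interval
#' is a percentile bootstrap (2.5/97.5) over alignment columns, resampling
#' the pair and outgroup comparisons jointly so their correlation is
#' preserved.
#'
#' @param pair character vector of 2 aligned sequences (the split to date)
#' @param outgroup aligned outgroup sequence (same length)
#' @param calibration outgroup split time in MYA
#' @param n_bootstrap bootstrap replicates (columns resampled with
#'   replacement)
#' @return a `time_estimate`: list with `time`, `ci_low`, `ci_high`,
#'   `calibration`, `d_pair`, `d_outgroup`
#' @export
date_divergence <- function(pair, outgroup, calibration = 15.2,
                            n_bootstrap = 1000) {
  stopifnot(length(pair) == 2)
  L <- nchar(pair[[1]])
  stopifnot(nchar(pair[[2]]) == L, nchar(outgroup) == L, L >= 1)
  x <- strsplit(toupper(pair[[1]]), "")[[1]]
  y <- strsplit(toupper(pair[[2]]), "")[[1]]
  o <- strsplit(toupper(outgroup), "")[[1]]
  is_base <- function(v) v %in% c("A", "C", "G", "T")
  bx <- is_base(x); by <- is_base(y); bo <- is_base(o)
  cmp_xy <- bx & by; cmp_xo <- bx & bo; cmp_yo <- by & bo
  m_xy <- cmp_xy & (x != y)
  m_xo <- cmp_xo & (x != o)
  m_yo <- cmp_yo & (y != o)
  est <- function(idx) {
    pxy <- sum(m_xy[idx]) / sum(cmp_xy[idx])
    pxo <- sum(m_xo[idx]) / sum(cmp_xo[idx])
    pyo <- sum(m_yo[idx]) / sum(cmp_yo[idx])
    if (any(!is.finite(c(pxy, pxo, pyo))) || max(pxy, pxo, pyo) >= 0.75) {
      return(NA_real_)
    }
    d_out <- mean(c(jc69_distance(pxo), jc69_distance(pyo)))
    if (d_out <= 0) return(NA_real_)
    clock_time(jc69_distance(pxy), d_out, calibration)
  }
  all_idx <- seq_len(L)
  d_out0 <- mean(c(jc69_distance(sum(m_xo) / sum(cmp_xo)),
                   jc69_distance(sum(m_yo) / sum(cmp_yo))))
  if (!is.finite(d_out0) || d_out0 <= 0) stop("outgroup distance is zero")
  t0 <- est(all_idx)
  boots <- vapply(seq_len(n_bootstrap), function(b) {
    est(sample.int(L, L, replace = TRUE))
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  ci <- if (length(boots) > 0) {
    unname(quantile(boots, c(0.025, 0.975)))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(time = t0, ci_low = ci[1], ci_high = ci[2],
                 calibration = calibration,
                 d_pair = jc69_distance(sum(m_xy) / sum(cmp_xy)),
                 d_outgroup = d_out0, n_bootstrap = n_bootstrap),
            class = "time_estimate")
}

#' @export
print.time_estimate <- function(x, ...) {
  cat(sprintf("<time_estimate> %.2f MYA (95%% CI %.2f-%.2f), calibration %.1f MYA\n",
              x$time, x$ci_low, x$ci_high, x$calibration))
  invisible(x)
}
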