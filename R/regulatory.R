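#' Percent actuation of an accessible chromatin element
#'
#' The percentage of sequenced fibers mapping to a location that carry an
#' inferred regulatory element (an accessibility call on the single
#' molecule). Undefined (`NA`) when no fibers map.
#'
#' @param fibers_fire,fibers_total non-negative counts (vectorized)
#' @return percent actuation, `100 * fire / total`
#' @export
percent_actuation <- function(fibers_fire, fibers_total) {
  if (any(fibers_fire < 0) || any(fibers_total < 0)) {
    stop("fiber counts must be non-negative")
  }
  if (any(fibers_fire > fibers_total)) {
    stop("fibers_fire cannot exceed fibers_total")
  }
  out <- 100 * fibers_fire / fibers_total
  out[fibers_total == 0] <- NA_real_
  out
}

# map an interval through a block's alignment path
# from = "query" maps query coords to target coords (and vice versa)
project_through_block <- function(block, start, end, from = "query") {
  path <- parse_cigar(block$cigar)
  qpos <- block$qstart
  tpos <- if (block$strand == "-") block$tlen - block$tend else block$tstart
  # walk in (query fwd, target strand-direction) space
  a_lo <- NA_integer_; a_hi <- NA_integer_
  for (r in seq_len(nrow(path))) {
    op <- path$op[r]; ln <- path$len[r]
    dq <- if (op %in% c("=", "X", "I")) ln else 0L
    dt <- if (op %in% c("=", "X", "D")) ln else 0L
    src0 <- if (from == "query") qpos else tpos
    ds <- if (from == "query") dq else dt
    dd <- if (from == "query") dt else dq
    dst0 <- if (from == "query") tpos else qpos
    if (ds > 0) {
      s0 <- max(start, src0); s1 <- min(end, src0 + ds)
      if (s1 > s0 && dd > 0) { # aligned segment (op "=" or "X")
        o_lo <- dst0 + (s0 - src0)
        o_hi <- dst0 + (s1 - src0)
        if (is.na(a_lo) || o_lo < a_lo) a_lo <- o_lo
        if (is.na(a_hi) || o_hi > a_hi) a_hi <- o_hi
      }
    }
    qpos <- qpos + dq; tpos <- tpos + dt
  }
  if (is.na(a_lo)) return(NULL)
  if (from == "query" && block$strand == "-") {
    c(block$tlen - a_hi, block$tlen - a_lo)
  } else {
    c(a_lo, a_hi)
  }
}

#' Project an accessible element through syntenic blocks
#'
#' The element is lifted through every block whose query side overlaps it;
#' projections covering less than `min_cover` of the element are dropped
#' (the operational definition of "shares duplicated sequence").
#'
#' @param element list with `region`, `start`, `end` (0-based half-open)
#' @param blocks list of computed `synteny_block`s; blocks are used whenever
#'   either side matches the element's region
#' @param min_cover minimum fraction of the element inside the block
#' @return data.frame(region, start, end, covered_fraction), one row per
#'   retained projection
#' @export
project_element <- function(element, blocks, min_cover = 0.5) {
  len <- element$end - element$start
  stopifnot(len > 0)
  out <- list()
  for (b in blocks) {
    sides <- list()
    if (b$query_id == element$region) {
      sides[[length(sides) + 1L]] <- list(from = "query", other = b$target_id,
                                          lo = b$qstart, hi = b$qend)
    }
    if (b$target_id == element$region) {
      sides[[length(sides) + 1L]] <- list(from = "target", other = b$query_id,
                                          lo = b$tstart, hi = b$tend)
    }
    for (sd in sides) {
      ov <- min(element$end, sd$hi) - max(element$start, sd$lo)
      if (ov <= 0) next
      frac <- ov / len
      if (frac < min_cover) next
      src <- if (sd$from == "target" && b$strand == "-") {
        # express the interval in the strand-direction target space
        c(b$tlen - min(element$end, sd$hi), b$tlen - max(element$start, sd$lo))
      } else {
        c(max(element$start, sd$lo), min(element$end, sd$hi))
      }
      proj <- project_through_block(b, src[1], src[2], from = sd$from)
      if (is.null(proj)) next
      out[[length(out) + 1L]] <- data.frame(
        region = sd$other, start = proj[1], end = proj[2],
        covered_fraction = frac, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(region = character(), start = integer(),
                      end = integer(), covered_fraction = numeric()))
  }
  do.call(rbind, out)
}

#' Categorize an accessible element by duplicate-sequence sharing
#'
#' `UNIQUE`: no retained projection (paralog-specific sequence).
#' `XCHR_ONLY`: every projection lands outside the paralog region set (the
#' duplicate sequence lives on a different chromosome only).
#' `SHARED_MULTI_ACCESSIBLE`: some within-set projected site overlaps an
#' accessibility peak there (>= 1 bp). `SHARED_SINGLE_ACCESSIBLE`: duplicate
#' sequence exists within the set but no paralogous site is accessible.
#'
#' @param element list with `region`, `start`, `end`
#' @param projections from [project_element()]
#' @param peaks_by_region named list of data.frame(start, end) peak tables
#' @param paralog_regions character vector naming the paralog region set
#' @return one of the four category strings
#' @export
categorize_element <- function(element, projections, peaks_by_region,
                               paralog_regions) {
  if (nrow(projections) == 0) return("UNIQUE")
  inset <- projections$region %in% paralog_regions
  if (!any(inset)) return("XCHR_ONLY")
  within <- projections[inset, , drop = FALSE]
  for (i in seq_len(nrow(within))) {
    pk <- peaks_by_region[[within$region[i]]]
    if (is.null(pk) || nrow(pk) == 0) next
    if (any(within$start[i] < pk$end & within$end[i] > pk$start)) {
      return("SHARED_MULTI_ACCESSIBLE")
    }
  }
  "SHARED_SINGLE_ACCESSIBLE"
}

ELEMENT_CATEGORIES <- c("UNIQUE", "SHARED_MULTI_ACCESSIBLE",
                        "SHARED_SINGLE_ACCESSIBLE", "XCHR_ONLY")

#' Summarize categorized accessible elements
#'
#' Fractions per category over the elements within `window` bp of their
#' region's transcription start site (all elements when no TSS map is
#' given), plus per-region counts of paralog-specific (`UNIQUE`) elements.
#' Exact fractions sum to 100 before rounding; the reported percentages are
#' rounded half away from zero.
#'
#' @param elements data.frame with at least `region` and `category`; element
#'   `start`/`end` required when filtering by TSS distance
#' @param tss optional named vector of TSS coordinates per region
#' @param window bp around the TSS retained (300 kbp by default)
#' @return list with `n`, `fractions` (exact percent), `percent` (rounded),
#'   `unique_by_region`
#' @export
summarize_elements <- function(elements, tss = NULL, window = 3e5) {
  stopifnot(nrow(elements) >= 1)
  if (!is.null(tss)) {
    mid <- (elements$start + elements$end) / 2
    keep <- abs(mid - tss[elements$region]) <= window
    elements <- elements[keep, , drop = FALSE]
    if (nrow(elements) == 0) stop("no elements within the TSS window")
  }
  n <- nrow(elements)
  cat_counts <- table(factor(elements$category, levels = ELEMENT_CATEGORIES))
  fractions <- 100 * as.numeric(cat_counts) / n
  names(fractions) <- ELEMENT_CATEGORIES
  uniq <- elements[elements$category == "UNIQUE", , drop = FALSE]
  list(n = n,
       counts = setNames(as.integer(cat_counts), ELEMENT_CATEGORIES),
       fractions = fractions,
       percent = setNames(round_half_away(fractions), ELEMENT_CATEGORIES),
       unique_by_region = table(uniq$region))
}
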