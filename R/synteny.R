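#' Find exact-match anchors between two sequences
#'
#' Seeds are k-mers that occur exactly once in each sequence (counting both
#' strands of each); every seed is extended to a maximal exact match and
#' duplicates are removed. Both orientations are searched; minus-strand
#' anchors report target coordinates on the forward strand. All coordinates
#' are 0-based half-open.
#'
#' @param query,target character scalars (DNA)
#' @param k k-mer size; at least 8 (shorter seeds produce spurious matches)
#' @return a data.frame with columns `qstart`, `qend`, `tstart`, `tend`,
#'   `len`, `strand`, sorted by query position
#' @export
find_anchors <- function(query, target, k = 21) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query),
            is.character(target), length(target) == 1L, nzchar(target))
  if (k < 8) stop("k must be >= 8 (spurious-match guard)")
  .find_anchors_cpp(query, target, as.integer(k))
}

# internal constructor for a syntenic block
new_block <- function(query_id, target_id, qlen, tlen, qstart, qend, tstart,
                      tend, strand, score = NA_real_, anchors = NULL) {
  structure(list(query_id = query_id, target_id = target_id,
                 qlen = qlen, tlen = tlen,
                 qstart = qstart, qend = qend, tstart = tstart, tend = tend,
                 strand = strand, score = score,
                 matches = NA_integer_, mismatches = NA_integer_,
                 insertions = NA_integer_, deletions = NA_integer_,
                 columns = NA_integer_, identity = NA_real_,
                 cigar = NA_character_, anchors = anchors),
            class = "synteny_block")
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf("<synteny_block> %s:%d-%d %s %s:%d-%d  identity=%s matches=%s columns=%s\n",
              x$query_id, x$qstart, x$qend, x$strand, x$target_id, x$tstart,
              x$tend,
              ifelse(is.na(x$identity), "?", sprintf("%.2f", x$identity)),
              x$matches, x$columns))
  invisible(x)
}

#' Chain colinear anchors into syntenic blocks
#'
#' Sparse dynamic programming over anchors sorted by query position: a chain
#' score is the number of anchored bases minus a linear gap penalty
#' (0.01/base on the larger of the query and target gaps). Chains mix no
#' orientations; chains whose query span is below `min_chain` are dropped;
#' the returned blocks are non-overlapping on the query, overlaps resolved by
#' score and ties by the leftmost block.
#'
#' @param anchors data.frame from [find_anchors()]
#' @param qlen,tlen sequence lengths (needed to orient minus-strand chains)
#' @param max_gap maximum gap (bp, query or target) bridged within one chain
#' @param min_chain minimum query span (bp) of a reported block
#' @param query_id,target_id labels carried into the blocks
#' @return list of `synteny_block` objects (identity not yet computed; see
#'   [block_identity()])
#' @export
chain_anchors <- function(anchors, qlen, tlen, max_gap = 10000,
                          min_chain = 1000, query_id = "query",
                          target_id = "target") {
  if (nrow(anchors) == 0) return(list())
  chains <- list()
  for (str in unique(anchors$strand)) {
    a <- anchors[anchors$strand == str, , drop = FALSE]
    if (str == "-") {
      # transform to a space where colinear means increasing on both axes
      ts <- tlen - a$tend; te <- tlen - a$tstart
      a$tstart <- ts; a$tend <- te
    }
    a <- a[order(a$qstart, a$tstart), , drop = FALSE]
    n <- nrow(a)
    score <- as.numeric(a$len)
    back <- rep(NA_integer_, n)
    max_overlap <- 50L
    for (i in seq_len(n)) {
      # candidate predecessors: earlier anchors, colinear, gaps within bounds
      for (j in seq_len(i - 1L)) {
        gq <- a$qstart[i] - a$qend[j]
        gt <- a$tstart[i] - a$tend[j]
        if (gq < -max_overlap || gt < -max_overlap) next
        if (gq > max_gap || gt > max_gap) next
        if (a$qstart[i] <= a$qstart[j] || a$tstart[i] <= a$tstart[j]) next
        pen <- 0.01 * max(gq, gt, 0)
        s <- score[j] + a$len[i] - pen
        if (s > score[i]) { score[i] <- s; back[i] <- j }
      }
    }
    used <- rep(FALSE, n)
    for (i in order(-score)) {
      if (used[i]) next
      idx <- integer()
      j <- i
      while (!is.na(j) && !used[j]) { idx <- c(j, idx); used[j] <- TRUE; j <- back[j] }
      aa <- a[idx, , drop = FALSE]
      chains[[length(chains) + 1L]] <- list(anchors = aa, strand = str,
                                            score = score[i],
                                            qstart = aa$qstart[1],
                                            qend = aa$qend[nrow(aa)])
    }
  }
  # select non-overlapping chains on the query, by score then leftmost
  ord <- order(-vapply(chains, `[[`, numeric(1), "score"),
               vapply(chains, `[[`, numeric(1), "qstart"))
  taken <- list()
  occ <- matrix(numeric(0), ncol = 2)
  for (ci in ord) {
    ch <- chains[[ci]]
    if (ch$qend - ch$qstart < min_chain) next
    if (nrow(occ) > 0 && any(ch$qstart < occ[, 2] & ch$qend > occ[, 1])) next
    occ <- rbind(occ, c(ch$qstart, ch$qend))
    taken[[length(taken) + 1L]] <- ch
  }
  lapply(taken, function(ch) {
    aa <- ch$anchors
    if (ch$strand == "-") {
      tstart_fwd <- tlen - aa$tend[nrow(aa)]
      tend_fwd <- tlen - aa$tstart[1]
    } else {
      tstart_fwd <- aa$tstart[1]
      tend_fwd <- aa$tend[nrow(aa)]
    }
    new_block(query_id, target_id, qlen, tlen, qstart = aa$qstart[1],
              qend = aa$qend[nrow(aa)], tstart = tstart_fwd, tend = tend_fwd,
              strand = ch$strand, score = ch$score, anchors = aa)
  })
}

# split a chain at gaps exceeding dp_limit; returns list of anchor frames
split_chain_at_big_gaps <- function(aa, dp_limit) {
  if (nrow(aa) == 1) return(list(aa))
  gq <- aa$qstart[-1] - aa$qend[-nrow(aa)]
  gt <- aa$tstart[-1] - aa$tend[-nrow(aa)]
  cut <- which(pmax(gq, gt) > dp_limit)
  if (length(cut) == 0) return(list(aa))
  bounds <- c(0, cut, nrow(aa))
  lapply(seq_len(length(bounds) - 1L),
         function(i) aa[(bounds[i] + 1L):bounds[i + 1L], , drop = FALSE])
}

#' Compute the identity of a syntenic block
#'
#' Anchors contribute exact matches; the gaps between consecutive anchors are
#' aligned by global dynamic programming with unit mismatch/gap costs
#' ([nw_align()]). Identity is `100 * matches / aligned_columns`, each indel
#' base counting as one column; `gap_compressed = TRUE` counts each indel run
#' once instead.
#'
#' @param block a `synteny_block` from [chain_anchors()] (anchors attached)
#' @param query,target the sequences the anchors were computed on
#' @param dp_limit largest inter-anchor gap (bp) aligned by DP; the caller
#'   ([synteny_blocks()]) splits chains at larger gaps
#' @param gap_compressed alternative identity denominator (indel runs, not
#'   indel bases)
#' @return the block with `matches`, `mismatches`, `insertions`, `deletions`,
#'   `columns`, `identity` and the `cigar` path filled in
#' @export
block_identity <- function(block, query, target, dp_limit = 5000,
                           gap_compressed = FALSE) {
  aa <- block$anchors
  stopifnot(!is.null(aa))
  tseq <- if (block$strand == "-") revcomp(target) else target
  qpos <- aa$qstart[1]; tpos <- aa$tstart[1]
  ops <- character(); lens <- integer()
  matches <- 0L; mismatches <- 0L; ins <- 0L; del <- 0L
  for (i in seq_len(nrow(aa))) {
    a_qs <- aa$qstart[i]; a_ts <- aa$tstart[i]
    a_len <- aa$qend[i] - aa$qstart[i]
    # trim anchors that overlap the already-emitted path
    o <- max(qpos - a_qs, tpos - a_ts, 0L)
    a_qs <- a_qs + o; a_ts <- a_ts + o; a_len <- a_len - o
    if (a_len <= 0) next
    gq <- a_qs - qpos; gt <- a_ts - tpos
    if (gq > dp_limit || gt > dp_limit) {
      stop("inter-anchor gap exceeds dp_limit; split the chain first")
    }
    if (gq > 0 || gt > 0) {
      if (gq == 0) {
        ops <- c(ops, "D"); lens <- c(lens, gt); del <- del + gt
      } else if (gt == 0) {
        ops <- c(ops, "I"); lens <- c(lens, gq); ins <- ins + gq
      } else {
        al <- nw_align(substr(query, qpos + 1, qpos + gq),
                       substr(tseq, tpos + 1, tpos + gt))
        gp <- parse_cigar(al$cigar)
        ops <- c(ops, gp$op); lens <- c(lens, gp$len)
        matches <- matches + al$matches
        mismatches <- mismatches + al$mismatches
        ins <- ins + al$insertions; del <- del + al$deletions
      }
    }
    ops <- c(ops, "="); lens <- c(lens, a_len)
    matches <- matches + a_len
    qpos <- a_qs + a_len; tpos <- a_ts + a_len
  }
  block$matches <- matches; block$mismatches <- mismatches
  block$insertions <- ins; block$deletions <- del
  block$columns <- matches + mismatches + ins + del
  block$cigar <- cigar_string(ops, lens)
  block$identity <- alignment_identity(matches, mismatches, block$cigar,
                                       gap_compressed = gap_compressed)
  block
}

#' Pairwise syntenic blocks between two sequences
#'
#' Convenience driver: [find_anchors()], [chain_anchors()], chain splitting at
#' gaps beyond the DP limit, then [block_identity()] per block.
#'
#' @inheritParams find_anchors
#' @inheritParams chain_anchors
#' @inheritParams block_identity
#' @return list of fully computed `synteny_block` objects
#' @export
synteny_blocks <- function(query, target, k = 21, max_gap = 10000,
                           min_chain = 1000, dp_limit = 5000,
                           gap_compressed = FALSE, query_id = "query",
                           target_id = "target") {
  anchors <- find_anchors(query, target, k)
  blocks <- chain_anchors(anchors, nchar(query), nchar(target), max_gap,
                          min_chain, query_id, target_id)
  out <- list()
  for (b in blocks) {
    pieces <- split_chain_at_big_gaps(b$anchors, dp_limit)
    if (length(pieces) > 1) {
      message(sprintf("block %s:%d-%d split at %d gap(s) exceeding dp_limit",
                      query_id, b$qstart, b$qend, length(pieces) - 1L))
    }
    for (aa in pieces) {
      if (aa$qend[nrow(aa)] - aa$qstart[1] < min_chain) next
      nb <- new_block(query_id, target_id, b$qlen, b$tlen,
                      qstart = aa$qstart[1], qend = aa$qend[nrow(aa)],
                      tstart = if (b$strand == "-") b$tlen - aa$tend[nrow(aa)] else aa$tstart[1],
                      tend = if (b$strand == "-") b$tlen - aa$tstart[1] else aa$tend[nrow(aa)],
                      strand = b$strand, score = b$score, anchors = aa)
      out[[length(out) + 1L]] <- block_identity(nb, query, target, dp_limit,
                                                gap_compressed)
    }
  }
  out
}

#' Longest non-overlapping syntenic block between two regions
#'
#' Reports the query span and identity of the single longest block among the
#' non-overlapping chains.
#'
#' @inheritParams synteny_blocks
#' @return list with `length` (bp of query span; 0 if no block passes
#'   `min_chain`), `identity` (percent; `NA` when length is 0) and `block`
#' @export
longest_syntenic_block <- function(query, target, k = 21, max_gap = 10000,
                                   min_chain = 1000, dp_limit = 5000,
                                   query_id = "query", target_id = "target") {
  blocks <- synteny_blocks(query, target, k, max_gap, min_chain, dp_limit,
                           query_id = query_id, target_id = target_id)
  if (length(blocks) == 0) {
    return(list(length = 0L, identity = NA_real_, block = NULL))
  }
  spans <- vapply(blocks, function(b) b$qend - b$qstart, numeric(1))
  b <- blocks[[which.max(spans)]]
  list(length = b$qend - b$qstart, identity = b$identity, block = b)
}

#' Pairwise homology matrix over a set of regions
#'
#' For every unordered pair of regions, the longest non-overlapping syntenic
#' block is computed once and mirrored, so lengths and identities are exactly
#' symmetric. The diagonal is the region length at 100 percent identity.
#'
#' @param regions named character vector of region sequences (>= 2, unique
#'   names)
#' @param ... passed to [longest_syntenic_block()]
#' @return an `identity_matrix` object: list with `labels`, `length` and
#'   `identity` matrices
#' @seealso [identity_matrix_stats()], [read_identity_matrix()]
#' @export
identity_matrix <- function(regions, ...) {
  stopifnot(length(regions) >= 2)
  labels <- names(regions)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("regions must carry unique names")
  }
  n <- length(regions)
  len <- matrix(0, n, n, dimnames = list(labels, labels))
  idy <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    len[i, i] <- nchar(regions[[i]])
    idy[i, i] <- 100
    for (j in seq_len(n)) {
      if (j <= i) next
      r <- longest_syntenic_block(regions[[i]], regions[[j]],
                                  query_id = labels[i], target_id = labels[j],
                                  ...)
      len[i, j] <- len[j, i] <- r$length
      idy[i, j] <- idy[j, i] <- r$identity
    }
  }
  structure(list(labels = labels, length = len, identity = idy),
            class = "identity_matrix")
}

#' Summary statistics of a pairwise homology matrix
#'
#' @param im an `identity_matrix`
#' @return list with `mean_length` and `mean_identity` over the off-diagonal
#'   unordered pairs, `max_identity` with the pair attaining it, and `n_pairs`
#' @export
identity_matrix_stats <- function(im) {
  stopifnot(inherits(im, "identity_matrix"))
  ut <- upper.tri(im$length)
  lens <- im$length[ut]
  ids <- im$identity[ut]
  mx <- which(im$identity == max(ids, na.rm = TRUE) & ut, arr.ind = TRUE)[1, ]
  list(mean_length = mean(lens), mean_identity = mean(ids, na.rm = TRUE),
       max_identity = max(ids, na.rm = TRUE),
       max_pair = c(im$labels[mx[1]], im$labels[mx[2]]),
       n_pairs = sum(ut))
}

# distribute a query span [start, start+len) over fixed-size windows
split_span <- function(start, len, window, nwin) {
  if (len <= 0) return(NULL)
  end <- start + len
  w0 <- start %/% window
  w1 <- (end - 1) %/% window
  wins <- w0:w1
  s <- pmax(start, wins * window)
  e <- pmin(end, (wins + 1) * window)
  wins <- pmin(wins + 1L, nwin) # clamp trailing positions into last window
  list(win = wins, n = e - s)
}

#' Windowed identity profile of an acceptor against candidate donors
#'
#' The acceptor is tiled with non-overlapping windows; for each window and
#' candidate, identity is computed over the syntenic projection (columns of
#' the block alignment paths attributed to the acceptor coordinate). A window
#' is assigned to the arg-max candidate iff its identity reaches `threshold`;
#' ties leave the window unassigned. Windows with no aligned columns to a
#' candidate have identity `NA` for it.
#'
#' @param acceptor character scalar, the sequence being profiled
#' @param candidates named character vector of candidate donor sequences
#' @param window_size window size in bp (windows larger than the acceptor
#'   collapse to a single window)
#' @param threshold assignment threshold in percent (99.9 by default, the
#'   near-perfect-identity signature of recent gene conversion)
#' @param ... passed to [synteny_blocks()]
#' @return a `window_profile`: data.frame with `window_start`, `window_end`,
#'   one identity column per candidate, and `assigned`; per-candidate match
#'   and column count matrices are kept in attributes for exact aggregation
#' @export
window_identity <- function(acceptor, candidates, window_size = 1000,
                            threshold = 99.9, ...) {
  stopifnot(length(candidates) >= 1, !is.null(names(candidates)))
  L <- nchar(acceptor)
  nwin <- max(1L, as.integer(ceiling(L / window_size)))
  starts <- (seq_len(nwin) - 1L) * window_size
  ends <- pmin(starts + window_size, L)
  cand <- names(candidates)
  m_mat <- matrix(0, nwin, length(cand), dimnames = list(NULL, cand))
  c_mat <- matrix(0, nwin, length(cand), dimnames = list(NULL, cand))
  for (cn in cand) {
    blocks <- synteny_blocks(acceptor, candidates[[cn]], query_id = "acceptor",
                             target_id = cn, ...)
    for (b in blocks) {
      path <- parse_cigar(b$cigar)
      qpos <- b$qstart
      for (r in seq_len(nrow(path))) {
        op <- path$op[r]; ln <- path$len[r]
        if (op %in% c("=", "X", "I")) {
          sp <- split_span(qpos, ln, window_size, nwin)
          c_mat[sp$win, cn] <- c_mat[sp$win, cn] + sp$n
          if (op == "=") m_mat[sp$win, cn] <- m_mat[sp$win, cn] + sp$n
          qpos <- qpos + ln
        } else { # D: columns with no acceptor base, attribute to current window
          w <- min(qpos %/% window_size + 1L, nwin)
          c_mat[w, cn] <- c_mat[w, cn] + ln
        }
      }
    }
  }
  idy <- 100 * m_mat / c_mat
  idy[c_mat == 0] <- NA_real_
  assigned <- rep(NA_character_, nwin)
  for (w in seq_len(nwin)) {
    v <- idy[w, ]
    if (all(is.na(v))) next
    mx <- max(v, na.rm = TRUE)
    if (mx < threshold) next
    top <- cand[!is.na(v) & v == mx]
    if (length(top) == 1) assigned[w] <- top
  }
  out <- data.frame(window_start = starts, window_end = ends,
                    check.names = FALSE)
  for (cn in cand) out[[cn]] <- idy[, cn]
  out$assigned <- assigned
  structure(out, class = c("window_profile", "data.frame"),
            window_size = window_size, threshold = threshold,
            matches = m_mat, columns = c_mat, candidates = cand)
}

#' Extract indel structural variants from a block alignment path
#'
#' @param block a computed `synteny_block` (cigar present)
#' @param min_len minimum indel length reported (50 bp by default, the usual
#'   structural-variant cutoff)
#' @return data.frame with `type` (`INS`/`DEL`), `position` (acceptor/query
#'   coordinate, 0-based) and `length`
#' @export
extract_indels <- function(block, min_len = 50) {
  stopifnot(inherits(block, "synteny_block"), !is.na(block$cigar))
  path <- parse_cigar(block$cigar)
  qpos <- block$qstart
  out <- list()
  for (r in seq_len(nrow(path))) {
    op <- path$op[r]; ln <- path$len[r]
    if (op == "I") {
      if (ln >= min_len) out[[length(out) + 1L]] <- data.frame(
        type = "INS", position = qpos, length = ln)
      qpos <- qpos + ln
    } else if (op == "D") {
      if (ln >= min_len) out[[length(out) + 1L]] <- data.frame(
        type = "DEL", position = qpos, length = ln)
    } else {
      qpos <- qpos + ln
    }
  }
  if (length(out) == 0) {
    return(data.frame(type = character(), position = integer(),
                      length = integer()))
  }
  do.call(rbind, out)
}
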