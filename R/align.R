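#' Global pairwise alignment with unit costs
#'
#' Needleman-Wunsch alignment under the Levenshtein objective: a mismatch
#' costs 1 and every gap base costs 1 (no affine opening cost). This is the
#' alignment model behind all identity percentages in the package: identity is
#' `100 * matches / aligned_columns`, with each indel base contributing one
#' column ("blast identity"). The traceback is deterministic (diagonal
#' preferred over query-consuming over target-consuming moves), so repeated
#' calls return the same optimal path.
#'
#' `N` and other ambiguity symbols never match anything, including themselves;
#' case is ignored.
#'
#' @param query,target character scalars (DNA)
#' @param max_cells guard on the DP matrix size; larger problems error
#' @return a list with `cost` (edit distance), `matches`, `mismatches`,
#'   `insertions` (bases present only in the query), `deletions` (bases present
#'   only in the target), `columns` and the `cigar` path (ops `=`, `X`, `I`,
#'   `D`; `I` consumes query, `D` consumes target)
#' @examples
#' nw_align("ACGTACGT", "ACGTTACGT")$cigar
#' @export
nw_align <- function(query, target, max_cells = 2e8) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(target), length(target) == 1L)
  .nw_align_cpp(query, target, max_cells)
}

# parse a cigar string into a data.frame(op, len)
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) {
    return(data.frame(op = character(), len = integer()))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XID]", cigar))[[1]]
  stopifnot(length(lens) == length(ops))
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

cigar_string <- function(ops, lens) {
  keep <- lens > 0
  ops <- ops[keep]; lens <- lens[keep]
  if (length(ops) == 0) return("")
  # merge adjacent identical ops
  r <- rle(ops)
  merged_len <- integer(length(r$values))
  idx <- 1L
  for (i in seq_along(r$values)) {
    merged_len[i] <- sum(lens[idx:(idx + r$lengths[i] - 1L)])
    idx <- idx + r$lengths[i]
  }
  paste0(merged_len, r$values, collapse = "")
}

# identity from alignment counts; gap_compressed counts each indel run once
alignment_identity <- function(matches, mismatches, cigar, gap_compressed = FALSE) {
  path <- parse_cigar(cigar)
  if (gap_compressed) {
    gap_runs <- sum(path$op %in% c("I", "D"))
    denom <- matches + mismatches + gap_runs
  } else {
    denom <- matches + mismatches + sum(path$len[path$op %in% c("I", "D")])
  }
  if (denom == 0) return(NA_real_)
  100 * matches / denom
}
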