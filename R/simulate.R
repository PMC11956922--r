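#' Simulation configuration for a synthetic SD gene-family cohort
#'
#' Bundles every knob of the generator: the locus/flank geometry, the exon
#' layout (five exons by default, mirroring the gene family's structure), the
#' duplicon token library used to tile the flanks, the paralog divergence
#' ladder anchored at an outgroup split, the clock rate, gene-conversion tract
#' behaviour and the haplotype-configuration frequencies.
#'
#' The default ladder places the family origin at 4.5 MYA, the NOTCH2NLC
#' split at 2.8 MYA and the NOTCH2NLA/NOTCH2NLB split at 1.6 MYA, with the
#' outgroup (orangutan-scale) split at 15.2 MYA; NOTCH2NLR, which is not
#' dated independently, sits at 3.5 MYA between the origin and the NLC split.
#' `mu` is substitutions/site/Myr per lineage, so two lineages split T Myr ago
#' are expected to differ at `2 * mu * T` of sites.
#'
#' Default configuration frequencies encode a 69-haplotype cohort whose
#' summary reproduces the headline cohort fractions (43% canonical H1, 30/69
#' lacking NOTCH2NLR, 21/69 deletion-class, 14/69 B-to-A conversions, 7/69
#' NOTCH2tv, 2/69 with both conversions).
#'
#' @param seed integer seed; all generator entry points restore the RNG state
#' @param n_haplotypes cohort size
#' @param locus_length,flank_length bp of the gene-bearing locus and of each
#'   flank (flanks carry the duplicon barcode)
#' @param exon_layout data.frame(start, end), 0-based half-open offsets within
#'   the locus; must be sorted, non-overlapping and inside the locus
#' @param duplicon_library data.frame(token_id, length)
#' @param paralog_tree data.frame(label, time) in decreasing time order; label
#'   i diverges from the remaining crown at its time; the last two labels
#'   share the final split time
#' @param outgroup_time,outgroup_label calibration split (MYA) and label
#' @param mu substitutions/site/Myr per lineage
#' @param polymorphism per-site private variant probability per haplotype locus
#' @param igc_tract_mean mean of the geometric margin added around gene spans
#'   when placing conversion tracts (bp)
#' @param barcode_fixed_edits distinctive token substitutions per paralog, at
#'   disjoint token positions (guarantees reference barcode separation)
#' @param barcode_random_edits add Poisson(1) random token insertions per
#'   paralog flank on top of the fixed edits
#' @param barcode_query_noise Poisson mean of per-haplotype barcode token
#'   edits (clamped at 2)
#' @param config_frequencies named probabilities over configuration labels
#' @return a validated `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_haplotypes = 69L,
                       locus_length = 20000L,
                       flank_length = 5000L,
                       exon_layout = data.frame(
                         start = c(2000L, 5000L, 8000L, 11000L, 15000L),
                         end = c(2400L, 5400L, 8400L, 11400L, 15400L)),
                       duplicon_library = data.frame(
                         token_id = sprintf("dup%02d", 1:12), length = 300L),
                       paralog_tree = data.frame(
                         label = c("NOTCH2", "NOTCH2NLR", "NOTCH2NLC",
                                   "NOTCH2NLA", "NOTCH2NLB"),
                         time = c(4.5, 3.5, 2.8, 1.6, 1.6)),
                       outgroup_time = 15.2,
                       outgroup_label = "outgroup",
                       mu = 1e-3,
                       polymorphism = 5e-4,
                       igc_tract_mean = 1000,
                       barcode_fixed_edits = 5L,
                       barcode_random_edits = TRUE,
                       barcode_query_noise = 0.5,
                       config_frequencies = c(H1 = 30, H2 = 13, H3 = 5,
                                              H4 = 2, H5 = 8, H6 = 2, H7 = 1,
                                              H8 = 4, H9 = 2, H10 = 2) / 69) {
  cfg <- list(seed = as.integer(seed), n_haplotypes = as.integer(n_haplotypes),
              locus_length = as.integer(locus_length),
              flank_length = as.integer(flank_length),
              exon_layout = exon_layout, duplicon_library = duplicon_library,
              paralog_tree = paralog_tree, outgroup_time = outgroup_time,
              outgroup_label = outgroup_label, mu = mu,
              polymorphism = polymorphism, igc_tract_mean = igc_tract_mean,
              barcode_fixed_edits = as.integer(barcode_fixed_edits),
              barcode_random_edits = isTRUE(barcode_random_edits),
              barcode_query_noise = barcode_query_noise,
              config_frequencies = config_frequencies)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$config_frequencies) - 1) > 1e-9) {
    stop("config_frequencies must sum to 1")
  }
  if (any(cfg$config_frequencies < 0)) stop("config_frequencies must be >= 0")
  if (cfg$mu < 0) stop("mu must be >= 0")
  tt <- cfg$paralog_tree$time
  if (any(tt <= 0) || any(tt > cfg$outgroup_time)) {
    stop("divergence times must be in (0, outgroup_time]")
  }
  if (is.unsorted(rev(tt))) stop("paralog_tree times must be non-increasing")
  n <- nrow(cfg$paralog_tree)
  if (n >= 2 && tt[n] != tt[n - 1]) {
    stop("the last two paralogs must share the final split time")
  }
  ex <- cfg$exon_layout
  if (nrow(ex) > 0) {
    if (any(ex$start < 0) || any(ex$end > cfg$locus_length)) {
      stop("exon outside locus bounds")
    }
    if (any(ex$end <= ex$start)) stop("exons must have positive length")
    if (is.unsorted(ex$start, strictly = TRUE) ||
        any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("exons must be sorted and non-overlapping")
    }
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields override [sim_config()] defaults; `exon_layout`,
#' `duplicon_library` and `paralog_tree` may be given as lists of rows.
#'
#' @param file path to a YAML file
#' @return a `sim_config`
#' @export
sim_config_from_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  for (f in c("exon_layout", "duplicon_library", "paralog_tree")) {
    if (!is.null(y[[f]])) y[[f]] <- do.call(rbind, lapply(y[[f]], as.data.frame))
  }
  if (!is.null(y$config_frequencies)) {
    y$config_frequencies <- unlist(y$config_frequencies)
  }
  do.call(sim_config, y)
}

# --- internal builders (consume the current RNG stream) ---------------------

# tile one flank with duplicon tokens separated by short random spacers;
# returns list(elements = data.frame(type, token_id, strand, seq), seq)
build_flank <- function(flank_length, library_seqs, spacer = 20L) {
  els <- list()
  used <- 0L
  ids <- names(library_seqs)
  lens <- nchar(library_seqs)
  min_tok <- min(lens)
  while (flank_length - used >= min_tok + spacer) {
    ok <- ids[lens + spacer <= flank_length - used]
    id <- if (length(ok) == 1) ok else sample(ok, 1)
    strand <- if (runif(1) < 0.5) "+" else "-"
    seq <- if (strand == "+") library_seqs[[id]] else revcomp(library_seqs[[id]])
    els[[length(els) + 1L]] <- list(type = "token", token_id = id,
                                    strand = strand, seq = seq)
    used <- used + nchar(seq)
    sp <- min(spacer, flank_length - used)
    if (sp > 0) {
      els[[length(els) + 1L]] <- list(type = "spacer", token_id = NA_character_,
                                      strand = "+", seq = random_dna(sp))
      used <- used + sp
    }
  }
  if (flank_length - used > 0) {
    els[[length(els) + 1L]] <- list(type = "spacer", token_id = NA_character_,
                                    strand = "+",
                                    seq = random_dna(flank_length - used))
  }
  els
}

flank_seq <- function(els) paste(vapply(els, `[[`, character(1), "seq"),
                                 collapse = "")

# token coordinate table of one flank, offset into record coordinates
flank_tokens <- function(els, offset) {
  pos <- offset
  rows <- list()
  for (e in els) {
    len <- nchar(e$seq)
    if (e$type == "token") {
      rows[[length(rows) + 1L]] <- data.frame(start = pos, end = pos + len,
                                              token_id = e$token_id,
                                              strand = e$strand,
                                              stringsAsFactors = FALSE)
    }
    pos <- pos + len
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      token_id = character(), strand = character()))
  }
  do.call(rbind, rows)
}

# locus record constructor: flanks as element lists, locus as sequence
new_locus_record <- function(label, locus_seq, left, right, exon_layout,
                             position = label, haplotype = NA_character_) {
  lf <- flank_seq(left); rf <- flank_seq(right)
  locus_start <- nchar(lf)
  exons <- data.frame(start = exon_layout$start + locus_start,
                      end = exon_layout$end + locus_start)
  tokens <- rbind(flank_tokens(left, 0L),
                  flank_tokens(right, locus_start + nchar(locus_seq)))
  structure(list(label = label, position = position, haplotype = haplotype,
                 seq = paste0(lf, locus_seq, rf),
                 locus_start = locus_start, locus_length = nchar(locus_seq),
                 exons = exons, strand = "+", tokens = tokens,
                 left = left, right = right),
            class = "locus_record")
}

#' @export
print.locus_record <- function(x, ...) {
  cat(sprintf("<locus_record> %s (position %s, haplotype %s): %d bp record, locus %d bp at offset %d, %d exons, %d duplicon tokens\n",
              x$label, x$position, x$haplotype, nchar(x$seq), x$locus_length,
              x$locus_start, nrow(x$exons), nrow(x$tokens)))
  invisible(x)
}

locus_seq <- function(record) {
  substr(record$seq, record$locus_start + 1,
         record$locus_start + record$locus_length)
}

#' Locus portion of a record (without flanks)
#'
#' @param record a `locus_record`
#' @return character scalar of length `locus_length`
#' @export
locus_sequence <- function(record) {
  stopifnot(inherits(record, "locus_record"))
  locus_seq(record)
}

set_locus_seq <- function(record, locus) {
  stopifnot(nchar(locus) == record$locus_length)
  lf <- substr(record$seq, 1, record$locus_start)
  rf <- substr(record$seq, record$locus_start + record$locus_length + 1,
               nchar(record$seq))
  record$seq <- paste0(lf, locus, rf)
  record
}

# Poisson substitutions along a branch of length t (Myr) at rate mu
mutate_seq <- function(seq, mu, t) {
  L <- nchar(seq)
  n <- rpois(1, mu * t * L)
  if (n == 0 || L == 0) return(seq)
  n <- min(n, L)
  pos <- sample.int(L, n)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    s[p] <- sample(setdiff(bases, toupper(s[p])), 1)
  }
  paste(s, collapse = "")
}

.sim_ancestor <- function(config) {
  lib <- config$duplicon_library
  library_seqs <- setNames(
    vapply(lib$length, random_dna, character(1)), lib$token_id)
  locus <- random_dna(config$locus_length)
  left <- build_flank(config$flank_length, library_seqs)
  right <- build_flank(config$flank_length, library_seqs)
  rec <- new_locus_record("ancestor", locus, left, right, config$exon_layout)
  attr(rec, "library_seqs") <- library_seqs
  rec
}

#' Simulate the ancestral locus record
#'
#' Uniform-random A/C/G/T locus of `locus_length`, exon intervals placed per
#' `exon_layout`, and both flanks tiled with duplicon tokens drawn from the
#' library (random order and orientation, recorded in the token table).
#'
#' @param config a [sim_config()]
#' @return a `locus_record`
#' @export
simulate_ancestor <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, .sim_ancestor(config))
}

# apply one token edit (substitution / insertion / deletion / flip) to an
# element list; kind chosen by caller
edit_flank_tokens <- function(els, library_seqs, kind, slot = NULL,
                              new_id = NULL) {
  tok_idx <- which(vapply(els, `[[`, character(1), "type") == "token")
  if (length(tok_idx) == 0) return(els)
  if (is.null(slot)) slot <- sample(seq_along(tok_idx), 1)
  i <- tok_idx[min(slot, length(tok_idx))]
  if (kind == "substitute") {
    cur <- els[[i]]$token_id
    if (is.null(new_id)) new_id <- sample(setdiff(names(library_seqs), cur), 1)
    els[[i]]$token_id <- new_id
    els[[i]]$seq <- if (els[[i]]$strand == "+") library_seqs[[new_id]] else
      revcomp(library_seqs[[new_id]])
  } else if (kind == "flip") {
    els[[i]]$strand <- if (els[[i]]$strand == "+") "-" else "+"
    els[[i]]$seq <- revcomp(els[[i]]$seq)
  } else if (kind == "delete") {
    els[[i]] <- NULL
  } else if (kind == "insert") {
    if (is.null(new_id)) new_id <- sample(names(library_seqs), 1)
    strand <- if (runif(1) < 0.5) "+" else "-"
    seq <- if (strand == "+") library_seqs[[new_id]] else
      revcomp(library_seqs[[new_id]])
    els <- append(els, list(list(type = "token", token_id = new_id,
                                 strand = strand, seq = seq)), after = i)
  }
  els
}

# per-paralog flank perturbation: `fixed` distinctive substitutions at token
# slots disjoint across paralogs, plus optional Poisson(1) random insertions
perturb_flanks <- function(rec, paralog_index, config, library_seqs) {
  fixed <- config$barcode_fixed_edits
  n_left <- sum(vapply(rec$left, `[[`, character(1), "type") == "token")
  n_right <- sum(vapply(rec$right, `[[`, character(1), "type") == "token")
  total <- n_left + n_right
  slots <- ((paralog_index - 1L) * fixed + seq_len(fixed) - 1L) %% max(total, 1L) + 1L
  for (s in slots) {
    if (s <= n_left) {
      rec$left <- edit_flank_tokens(rec$left, library_seqs, "substitute",
                                    slot = s)
    } else {
      rec$right <- edit_flank_tokens(rec$right, library_seqs, "substitute",
                                     slot = s - n_left)
    }
  }
  if (config$barcode_random_edits) {
    for (k in seq_len(rpois(1, 1))) {
      side <- if (runif(1) < 0.5) "left" else "right"
      rec[[side]] <- edit_flank_tokens(rec[[side]], library_seqs, "insert")
    }
  }
  rec
}

rebuild_record <- function(rec) {
  lseq <- locus_seq(rec)
  new_locus_record(rec$label, lseq, rec$left, rec$right,
                   data.frame(start = rec$exons$start - rec$locus_start,
                              end = rec$exons$end - rec$locus_start),
                   position = rec$position, haplotype = rec$haplotype)
}

.sim_family <- function(config) {
  if (config$mu * config$outgroup_time >= 0.75) {
    stop("mu * T >= 0.75: substitution saturation, reduce mu or the tree depth")
  }
  tree <- config$paralog_tree
  if (nrow(tree) < 2) stop("paralog_tree must have >= 2 labels")
  anc <- .sim_ancestor(config)
  library_seqs <- attr(anc, "library_seqs")
  root <- locus_seq(anc) # sequence at the outgroup split
  out_seq <- mutate_seq(root, config$mu, config$outgroup_time)
  outgroup <- new_locus_record(config$outgroup_label, out_seq, anc$left,
                               anc$right,
                               config$exon_layout)
  times <- tree$time
  crown <- mutate_seq(root, config$mu, config$outgroup_time - times[1])
  records <- list()
  n <- nrow(tree)
  for (i in seq_len(n)) {
    lab <- tree$label[i]
    seq_i <- mutate_seq(crown, config$mu, times[i])
    rec <- new_locus_record(lab, seq_i, anc$left, anc$right, config$exon_layout)
    rec <- perturb_flanks(rec, i, config, library_seqs)
    rec$label <- lab; rec$position <- lab
    records[[lab]] <- rebuild_record(rec)
    if (i < n - 1) {
      crown <- mutate_seq(crown, config$mu, times[i] - times[i + 1])
    }
    # between the last two labels the crown does not evolve further: they
    # share the final split time
  }
  structure(list(records = records, outgroup = outgroup, ancestor = anc,
                 library_seqs = library_seqs, config = config),
            class = "paralog_family")
}

#' Simulate a paralog family along a divergence ladder
#'
#' Each paralog derives from the ancestor by Poisson(`mu` x branch length x L)
#' substitutions per branch (Jukes-Cantor: uniform rates, no indels on gene
#' bodies), so two paralogs split T MYA are expected to differ at `2 mu T` of
#' sites. Flank duplicon content is perturbed per paralog so barcodes are
#' distinguishable. An outgroup record split at `outgroup_time` is included
#' for clock calibration.
#'
#' @param config a [sim_config()]
#' @return a `paralog_family`: named `records` (one `locus_record` per
#'   paralog), `outgroup`, `ancestor`, `library_seqs`, `config`
#' @export
simulate_family <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, .sim_family(config))
}

#' @export
print.paralog_family <- function(x, ...) {
  cat(sprintf("<paralog_family> %d paralogs (%s) + outgroup %s; mu=%g, locus %d bp\n",
              length(x$records), paste(names(x$records), collapse = ", "),
              x$outgroup$label, x$config$mu, x$config$locus_length))
  invisible(x)
}

#' Apply an interlocus gene-conversion tract
#'
#' Overwrites the acceptor locus with the donor locus inside the tract
#' (0-based half-open, locus coordinates, which are homologous across
#' paralogs by construction); the sequence is unchanged outside.
#'
#' @param acceptor,donor `locus_record`s with equal locus length
#' @param tract integer vector `c(start, end)` in locus coordinates
#' @return the modified acceptor record; the event (donor label, tract) is
#'   appended to its `igc_events` attribute
#' @export
apply_igc <- function(acceptor, donor, tract) {
  stopifnot(inherits(acceptor, "locus_record"), inherits(donor, "locus_record"))
  stopifnot(length(tract) == 2)
  if (tract[1] < 0 || tract[2] > acceptor$locus_length ||
      tract[2] > donor$locus_length || tract[1] > tract[2]) {
    stop("tract outside locus bounds")
  }
  if (tract[2] > tract[1]) {
    a <- locus_seq(acceptor)
    d <- locus_seq(donor)
    substr(a, tract[1] + 1, tract[2]) <- substr(d, tract[1] + 1, tract[2])
    acceptor <- set_locus_seq(acceptor, a)
  }
  ev <- attr(acceptor, "igc_events")
  attr(acceptor, "igc_events") <- rbind(ev, data.frame(
    donor = donor$label, acceptor = acceptor$position,
    start = tract[1], end = tract[2]))
  acceptor
}

# geometric margin with configured mean, at least 1
geom_margin <- function(mean) 1L + rgeom(1, 1 / max(mean, 1))

# gene span in locus coordinates
gene_span <- function(config) {
  c(min(config$exon_layout$start), max(config$exon_layout$end))
}

# private polymorphism on the locus portion only
apply_polymorphism <- function(rec, rate) {
  if (rate <= 0) return(rec)
  set_locus_seq(rec, mutate_seq(locus_seq(rec), rate, 1))
}

# B-to-A style conversion: tract covers the full gene span plus geometric
# margins, clamped to the locus
conversion_tract_gene <- function(config) {
  gs <- gene_span(config)
  c(max(0L, gs[1] - geom_margin(config$igc_tract_mean)),
    min(config$locus_length, gs[2] + geom_margin(config$igc_tract_mean)))
}

# NOTCH2tv-style conversion: promoter through intron 4 (never exon 5)
conversion_tract_tv <- function(config) {
  ex <- config$exon_layout
  stopifnot(nrow(ex) >= 5)
  gap <- ex$start[5] - ex$end[4]
  margin <- min(geom_margin(config$igc_tract_mean), gap - 1L)
  c(0L, ex$start[5] - max(margin, 1L))
}

# A/B hybrid at the NLC position: copy donor A over [gene_start, breakpoint)
# and donor B over [breakpoint, gene_end), the breakpoint chosen so the
# exonic mismatch counts to the two donors are equal (a tied best transcript
# match). When the count of exonic A/B differences is odd, the A-side site
# adjacent to the breakpoint is set to a base matching neither donor, which
# adds one mismatch to each and restores the tie.
make_hybrid <- function(acceptor, donorA, donorB, config) {
  gs <- gene_span(config)
  a <- strsplit(locus_seq(donorA), "")[[1]]
  b <- strsplit(locus_seq(donorB), "")[[1]]
  ex <- config$exon_layout
  exonic <- unlist(lapply(seq_len(nrow(ex)),
                          function(i) (ex$start[i] + 1):ex$end[i]))
  diffs <- sort(exonic[a[exonic] != b[exonic]]) # 1-based locus positions
  len <- length(diffs)
  fl <- len %/% 2
  # B segment carries the last fl diff sites; 0-based breakpoint
  bp <- if (fl > 0) diffs[len - fl + 1] - 1L else gs[2]
  acceptor <- apply_igc(acceptor, donorA, c(gs[1], bp))
  acceptor <- apply_igc(acceptor, donorB, c(bp, gs[2]))
  if (len %% 2 == 1) {
    p <- diffs[len - fl] # last A-side diff site
    s <- strsplit(locus_seq(acceptor), "")[[1]]
    s[p] <- setdiff(c("A", "C", "G", "T"), c(a[p], b[p]))[1]
    acceptor <- set_locus_seq(acceptor, paste(s, collapse = ""))
  }
  acceptor
}

# apply query-level barcode noise (Poisson(mean) edits clamped at 2)
barcode_noise <- function(rec, config, library_seqs) {
  n <- min(rpois(1, config$barcode_query_noise), 2L)
  if (n == 0) return(rec)
  ev <- attr(rec, "igc_events")
  for (k in seq_len(n)) {
    side <- if (runif(1) < 0.5) "left" else "right"
    kind <- sample(c("substitute", "flip", "insert"), 1)
    rec[[side]] <- edit_flank_tokens(rec[[side]], library_seqs, kind)
  }
  rec <- rebuild_record(rec)
  attr(rec, "igc_events") <- ev
  rec
}

.sim_cohort <- function(config, catalog, exact_counts) {
  fam <- .sim_family(config)
  labels <- names(config$config_frequencies)
  unknown <- setdiff(labels, catalog$config_label)
  if (length(unknown) > 0) {
    stop("unknown configuration label(s): ", paste(unknown, collapse = ", "))
  }
  n <- config$n_haplotypes
  if (exact_counts) {
    counts <- largest_remainder(config$config_frequencies * n)
    draw <- rep(labels, counts)
  } else {
    draw <- sample(labels, n, replace = TRUE,
                   prob = config$config_frequencies)
  }
  positions <- setdiff(catalog_positions(catalog), character(0))
  haplotypes <- list()
  hap_truth <- list()
  loci_truth <- list()
  igc_truth <- list()
  for (h in seq_len(n)) {
    hap_id <- sprintf("hap%03d", h)
    cfg_label <- draw[h]
    states <- catalog_states(catalog, cfg_label)
    loci <- list()
    for (pos in positions) {
      st <- states[[pos]]
      if (st == "absent") {
        loci_truth[[length(loci_truth) + 1L]] <- data.frame(
          haplotype = hap_id, position = pos, label = NA_character_,
          deleted = TRUE)
        next
      }
      rec <- fam$records[[pos]]
      rec$haplotype <- hap_id; rec$position <- pos
      rec <- apply_polymorphism(rec, config$polymorphism)
      true_label <- pos
      if (st == "NOTCH2NLA" && pos == "NOTCH2NLB") {
        rec <- apply_igc(rec, fam$records$NOTCH2NLA,
                         conversion_tract_gene(config))
        true_label <- "NOTCH2NLA"
      } else if (st == "NOTCH2tv") {
        rec <- apply_igc(rec, fam$records$NOTCH2,
                         conversion_tract_tv(config))
        true_label <- "NOTCH2tv"
      } else if (st == "hybrid") {
        rec <- make_hybrid(rec, fam$records$NOTCH2NLA, fam$records$NOTCH2NLB,
                           config)
        true_label <- "hybrid"
      } else if (st != pos) {
        stop("unsupported state '", st, "' at position ", pos)
      }
      rec <- barcode_noise(rec, config, fam$library_seqs)
      ev <- attr(rec, "igc_events")
      if (!is.null(ev) && nrow(ev) > 0) {
        ev$haplotype <- hap_id
        igc_truth[[length(igc_truth) + 1L]] <- ev
      }
      loci_truth[[length(loci_truth) + 1L]] <- data.frame(
        haplotype = hap_id, position = pos, label = true_label,
        deleted = FALSE)
      loci[[pos]] <- rec
    }
    haplotypes[[hap_id]] <- loci
    hap_truth[[length(hap_truth) + 1L]] <- data.frame(
      haplotype = hap_id, config_label = cfg_label)
  }
  bind0 <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  truth <- structure(list(
    haplotypes = bind0(hap_truth, data.frame(haplotype = character(),
                                             config_label = character())),
    loci = bind0(loci_truth, data.frame(haplotype = character(),
                                        position = character(),
                                        label = character(),
                                        deleted = logical())),
    igc_events = if (length(igc_truth) > 0) {
      ev <- do.call(rbind, igc_truth)
      ev[, c("haplotype", "acceptor", "donor", "start", "end")]
    } else {
      data.frame(haplotype = character(), acceptor = character(),
                 donor = character(), start = integer(), end = integer())
    }), class = "sim_truth")
  structure(list(haplotypes = haplotypes, truth = truth, family = fam,
                 config = config), class = "sim_cohort")
}

# integer apportionment by largest remainder, deterministic tie-break by order
largest_remainder <- function(x) {
  f <- floor(x)
  rem <- sum(round(sum(x))) - sum(f)
  if (rem > 0) {
    extra <- order(-(x - f), seq_along(x))[seq_len(rem)]
    f[extra] <- f[extra] + 1
  }
  as.integer(f)
}

#' Simulate a haplotype cohort with known truth
#'
#' Draws one configuration per haplotype from `config_frequencies` (or
#' apportions them exactly with `exact_counts = TRUE`), instantiates each
#' canonical position from the simulated paralog family, applies private
#' polymorphism, the configuration's deletions and gene-conversion events,
#' and per-haplotype barcode noise. Everything applied is recorded in the
#' returned truth tables.
#'
#' @param config a [sim_config()]
#' @param catalog a configuration catalog (default [config_catalog()])
#' @param exact_counts apportion configuration counts deterministically
#'   (largest remainder) instead of multinomial sampling
#' @return a `sim_cohort`: `haplotypes` (list of named `locus_record` lists),
#'   `truth` (`haplotypes`, `loci`, `igc_events` tables), `family`, `config`
#' @export
simulate_cohort <- function(config, catalog = config_catalog(),
                            exact_counts = FALSE) {
  validate_sim_config(config)
  withr::with_seed(config$seed, .sim_cohort(config, catalog, exact_counts))
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d haplotypes, %d loci, %d gene-conversion events\n",
              length(x$haplotypes), nrow(x$truth$loci),
              nrow(x$truth$igc_events)))
  invisible(x)
}
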