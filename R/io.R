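# Shared I/O: FASTA via Biostrings, GFF3/BED via rtracklayer, Newick via ape,
# PAF-like synteny TSV and Table-style identity matrices as plain TSV.
# Internal coordinates are 0-based half-open everywhere; GFF3 is 1-based
# closed on disk and converted exactly at the boundary.

#' Convert between GFF3 (1-based closed) and internal (0-based half-open)
#' coordinates
#'
#' @param start,end interval bounds in the source convention
#' @return `c(start, end)` in the other convention
#' @export
gff_to_internal <- function(start, end) c(start - 1L, end)

#' @rdname gff_to_internal
#' @export
internal_to_gff <- function(start, end) c(start + 1L, end)

#' Read / write FASTA
#'
#' @param file path
#' @return named character vector of sequences (`read_fasta`)
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector
#' @export
write_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, file, width = 60)
  invisible(file)
}

# GRanges helpers for on-disk BED/GFF3 (internal 0-based half-open)
intervals_to_granges <- function(df, seqname_col = "seqid") {
  GenomicRanges::GRanges(
    seqnames = df[[seqname_col]],
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
}

#' Write duplicon tokens as BED6
#'
#' @param df data.frame(seqid, start, end, token_id, strand) and optionally
#'   `identity` (stored in the score column)
#' @param file path
#' @export
write_duplicon_bed <- function(df, file) {
  if (nrow(df) == 0) {
    writeLines(character(), file)
    return(invisible(file))
  }
  gr <- intervals_to_granges(df)
  gr$name <- df$token_id
  gr$score <- if ("identity" %in% names(df)) df$identity else 0
  rtracklayer::export(gr, file, format = "bed")
  invisible(file)
}

#' @rdname write_duplicon_bed
#' @return data.frame(seqid, start, end, token_id, strand, identity)
#' @export
read_duplicon_bed <- function(file) {
  if (length(readLines(file, n = 1)) == 0) {
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), token_id = character(),
                      strand = character(), identity = numeric()))
  }
  gr <- rtracklayer::import(file, format = "bed")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             token_id = gr$name,
             strand = as.character(GenomicRanges::strand(gr)),
             identity = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' One `gene` feature plus `exon` children per locus.
#'
#' @param genes data.frame(seqid, gene_id, start, end, strand) for genes
#' @param exons data.frame(seqid, gene_id, start, end, strand) for exons
#' @param file path
#' @export
write_genes_gff3 <- function(genes, exons, file) {
  rows <- character()
  fmt <- function(seqid, type, start, end, strand, attrs) {
    g <- internal_to_gff(start, end)
    sprintf("%s\tsdparalog\t%s\t%d\t%d\t.\t%s\t.\t%s", seqid, type, g[1],
            g[2], strand, attrs)
  }
  for (i in seq_len(nrow(genes))) {
    rows <- c(rows, fmt(genes$seqid[i], "gene", genes$start[i], genes$end[i],
                        genes$strand[i],
                        sprintf("ID=%s", genes$gene_id[i])))
  }
  for (i in seq_len(nrow(exons))) {
    rows <- c(rows, fmt(exons$seqid[i], "exon", exons$start[i], exons$end[i],
                        exons$strand[i],
                        sprintf("Parent=%s", exons$gene_id[i])))
  }
  writeLines(c("##gff-version 3", rows), file)
  invisible(file)
}

#' Read gene models from GFF3
#'
#' @param file path
#' @return list with `genes` and `exons` data.frames in internal coordinates
#' @export
read_genes_gff3 <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  df <- data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
                   type = as.character(gr$type),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = rep(NA_character_, length(gr)),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$ID)) df$gene_id[df$type == "gene"] <- gr$ID[df$type == "gene"]
  if (!is.null(gr$Parent)) {
    par <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                  character(1))
    df$gene_id[df$type == "exon"] <- par[df$type == "exon"]
  }
  list(genes = df[df$type == "gene", c("seqid", "gene_id", "start", "end",
                                       "strand")],
       exons = df[df$type == "exon", c("seqid", "gene_id", "start", "end",
                                       "strand")])
}

#' Write syntenic blocks as a PAF-like TSV
#'
#' Columns: query, qlen, qstart, qend, strand, target, tlen, tstart, tend,
#' matches, columns, identity, cigar.
#'
#' @param blocks list of computed `synteny_block`s
#' @param file path
#' @export
write_synteny_tsv <- function(blocks, file) {
  df <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(query = b$query_id, qlen = b$qlen, qstart = b$qstart,
               qend = b$qend, strand = b$strand, target = b$target_id,
               tlen = b$tlen, tstart = b$tstart, tend = b$tend,
               matches = b$matches, columns = b$columns,
               identity = b$identity, cigar = b$cigar,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(query = character(), qlen = integer(),
                     qstart = integer(), qend = integer(),
                     strand = character(), target = character(),
                     tlen = integer(), tstart = integer(), tend = integer(),
                     matches = integer(), columns = integer(),
                     identity = numeric(), cigar = character())
  }
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_synteny_tsv
#' @return list of `synteny_block`s (`read_synteny_tsv`)
#' @export
read_synteny_tsv <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    b <- new_block(df$query[i], df$target[i], df$qlen[i], df$tlen[i],
                   df$qstart[i], df$qend[i], df$tstart[i], df$tend[i],
                   df$strand[i])
    b$matches <- df$matches[i]; b$columns <- df$columns[i]
    b$identity <- df$identity[i]; b$cigar <- df$cigar[i]
    b
  })
}

#' Read / write a pairwise homology matrix in printed-table layout
#'
#' Upper triangle: longest-synteny lengths (bp); lower triangle: percent
#' identities; diagonal `x`. This is the layout of published region homology
#' tables, and the reader accepts thousands separators.
#'
#' @param file path to a TSV
#' @return an `identity_matrix`
#' @export
read_identity_matrix <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                   row.names = 1)
  labels <- rownames(df)
  stopifnot(identical(labels, colnames(df)))
  n <- length(labels)
  len <- matrix(0, n, n, dimnames = list(labels, labels))
  idy <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  num <- function(x) as.numeric(gsub(",", "", x))
  for (i in seq_len(n)) {
    idy[i, i] <- 100
    for (j in seq_len(n)) {
      if (i < j) {
        len[i, j] <- len[j, i] <- num(df[i, j])
      } else if (i > j) {
        idy[i, j] <- idy[j, i] <- num(df[i, j])
      }
    }
  }
  structure(list(labels = labels, length = len, identity = idy),
            class = "identity_matrix")
}

#' @rdname read_identity_matrix
#' @param im an `identity_matrix`
#' @export
write_identity_matrix <- function(im, file) {
  n <- length(im$labels)
  m <- matrix("x", n, n, dimnames = list(im$labels, im$labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) m[i, j] <- format(im$length[i, j], scientific = FALSE)
      if (i > j) m[i, j] <- format(im$identity[i, j])
    }
  }
  write.table(m, file, sep = "\t", quote = FALSE, col.names = NA)
  invisible(file)
}

#' Write a simulated cohort to disk
#'
#' One FASTA per haplotype (record per locus, named `haplotype|position`),
#' one GFF3 of gene models, one BED of duplicon tokens, and the truth tables
#' (configurations, loci, gene-conversion events) as TSV. [read_cohort()]
#' recovers the sequences, gene models, token tables and truth losslessly
#' (the simulator-internal flank element structure is not serialized).
#'
#' @param cohort a `sim_cohort`
#' @param dir output directory (created if needed)
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- list(); exons <- list(); beds <- list()
  for (hap_id in names(cohort$haplotypes)) {
    loci <- cohort$haplotypes[[hap_id]]
    seqs <- setNames(
      vapply(loci, `[[`, character(1), "seq"),
      paste0(hap_id, "|", vapply(loci, `[[`, character(1), "position")))
    write_fasta(seqs, file.path(dir, paste0(hap_id, ".fa")))
    for (rec in loci) {
      sid <- paste0(hap_id, "|", rec$position)
      gid <- paste0(sid, "|gene")
      genes[[length(genes) + 1L]] <- data.frame(
        seqid = sid, gene_id = gid, start = min(rec$exons$start),
        end = max(rec$exons$end), strand = rec$strand)
      exons[[length(exons) + 1L]] <- data.frame(
        seqid = sid, gene_id = gid, start = rec$exons$start,
        end = rec$exons$end, strand = rec$strand)
      if (nrow(rec$tokens) > 0) {
        beds[[length(beds) + 1L]] <- data.frame(
          seqid = sid, rec$tokens, stringsAsFactors = FALSE)
      }
    }
  }
  bind0 <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  write_genes_gff3(
    bind0(genes, data.frame(seqid = character(), gene_id = character(),
                            start = integer(), end = integer(),
                            strand = character())),
    bind0(exons, data.frame(seqid = character(), gene_id = character(),
                            start = integer(), end = integer(),
                            strand = character())),
    file.path(dir, "genes.gff3"))
  write_duplicon_bed(
    bind0(beds, data.frame(seqid = character(), start = integer(),
                           end = integer(), token_id = character(),
                           strand = character())),
    file.path(dir, "duplicons.bed"))
  tr <- cohort$truth
  write.table(tr$haplotypes, file.path(dir, "truth_haplotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  loci <- tr$loci
  if (nrow(loci) > 0) {
    meta <- lapply(seq_len(nrow(loci)), function(i) {
      rec <- cohort$haplotypes[[loci$haplotype[i]]][[loci$position[i]]]
      if (is.null(rec)) {
        data.frame(locus_start = NA_integer_, locus_length = NA_integer_)
      } else {
        data.frame(locus_start = rec$locus_start,
                   locus_length = rec$locus_length)
      }
    })
    loci <- cbind(loci, do.call(rbind, meta))
  } else {
    loci$locus_start <- integer(); loci$locus_length <- integer()
  }
  write.table(loci, file.path(dir, "truth_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tr$igc_events, file.path(dir, "truth_igc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @return a `sim_cohort` (without the simulator-internal family object)
#' @export
read_cohort <- function(dir) {
  haps <- read.delim(file.path(dir, "truth_haplotypes.tsv"),
                     stringsAsFactors = FALSE)
  loci <- read.delim(file.path(dir, "truth_loci.tsv"),
                     stringsAsFactors = FALSE)
  igc <- read.delim(file.path(dir, "truth_igc.tsv"), stringsAsFactors = FALSE)
  gff <- read_genes_gff3(file.path(dir, "genes.gff3"))
  bed <- read_duplicon_bed(file.path(dir, "duplicons.bed"))
  haplotypes <- list()
  for (hap_id in haps$haplotype) {
    seqs <- read_fasta(file.path(dir, paste0(hap_id, ".fa")))
    recs <- list()
    for (nm in names(seqs)) {
      pos <- sub("^[^|]*\\|", "", nm)
      ex <- gff$exons[gff$exons$seqid == nm, c("start", "end"), drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      rownames(ex) <- NULL
      tk <- bed[bed$seqid == nm, c("start", "end", "token_id", "strand"),
                drop = FALSE]
      tk <- tk[order(tk$start), , drop = FALSE]
      rownames(tk) <- NULL
      meta <- loci[loci$haplotype == hap_id & loci$position == pos, ,
                   drop = FALSE]
      recs[[pos]] <- structure(list(
        label = if (nrow(meta)) meta$label[1] else pos, position = pos,
        haplotype = hap_id, seq = unname(seqs[[nm]]),
        locus_start = if (nrow(meta)) meta$locus_start[1] else 0L,
        locus_length = if (nrow(meta)) meta$locus_length[1] else nchar(seqs[[nm]]),
        exons = ex, strand = "+", tokens = tk, left = NULL, right = NULL),
        class = "locus_record")
    }
    haplotypes[[hap_id]] <- recs
  }
  truth <- structure(list(haplotypes = haps,
                          loci = loci[, c("haplotype", "position", "label",
                                          "deleted")],
                          igc_events = igc), class = "sim_truth")
  structure(list(haplotypes = haplotypes, truth = truth, family = NULL,
                 config = NULL), class = "sim_cohort")
}
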