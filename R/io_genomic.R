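## Import/export of gene models and event catalogues in the standard
## formats: GFF3 (1-based) + FASTA for structures and sequence, BED
## (0-based half-open, handled by rtracklayer) for quick browser tracks,
## CSV for event lists and consequence tables.

## Feature table for one gene model: gene, mRNA, exon, CDS and UTR rows on
## a per-gene seqname (the fixture genes are unplaced toy contigs).
gene_model_features <- function(gm) {
  exons <- gm$exons
  cds_lo <- min(gm$cds_start, gm$cds_end)
  cds_hi <- max(gm$cds_start, gm$cds_end)
  span <- c(min(exons[, "start"]), max(exons[, "end"]))
  feats <- data.frame(start = span[1L], end = span[2L], type = "gene",
                      ID = gm$gene_id, Parent = NA_character_)
  feats <- rbind(feats,
                 data.frame(start = span[1L], end = span[2L], type = "mRNA",
                            ID = paste0(gm$gene_id, ".t1"),
                            Parent = gm$gene_id))
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, "start"]; e <- exons[i, "end"]
    feats <- rbind(feats,
                   data.frame(start = s, end = e, type = "exon",
                              ID = sprintf("%s.exon%d", gm$gene_id, i),
                              Parent = paste0(gm$gene_id, ".t1")))
    cs <- max(s, cds_lo); ce <- min(e, cds_hi)
    if (cs <= ce)
      feats <- rbind(feats,
                     data.frame(start = cs, end = ce, type = "CDS",
                                ID = sprintf("%s.cds%d", gm$gene_id, i),
                                Parent = paste0(gm$gene_id, ".t1")))
    utr5_type <- if (gm$strand == "+") "five_prime_UTR" else "three_prime_UTR"
    utr3_type <- if (gm$strand == "+") "three_prime_UTR" else "five_prime_UTR"
    if (s < cds_lo)
      feats <- rbind(feats,
                     data.frame(start = s, end = min(e, cds_lo - 1L),
                                type = utr5_type,
                                ID = sprintf("%s.utr.l%d", gm$gene_id, i),
                                Parent = paste0(gm$gene_id, ".t1")))
    if (e > cds_hi)
      feats <- rbind(feats,
                     data.frame(start = max(s, cds_hi + 1L), end = e,
                                type = utr3_type,
                                ID = sprintf("%s.utr.r%d", gm$gene_id, i),
                                Parent = paste0(gm$gene_id, ".t1")))
  }
  feats$seqname <- gm$gene_id
  feats$strand <- gm$strand
  ## GFF3 CDS phase: nt to skip before the first complete codon, assigned
  ## in transcript (coding-strand) order
  feats$phase <- NA_integer_
  cds_rows <- which(feats$type == "CDS")
  ord <- if (gm$strand == "+") order(feats$start[cds_rows])
         else order(-feats$start[cds_rows])
  cum <- 0L
  for (r in cds_rows[ord]) {
    feats$phase[r] <- (3L - cum %% 3L) %% 3L
    cum <- cum + feats$end[r] - feats$start[r] + 1L
  }
  feats
}

#' Write gene models to GFF3 (+ companion FASTA)
#'
#' GFF3 keeps 1-based inclusive coordinates; each gene sits on its own
#' seqname. The genomic sequences go to a separate FASTA via
#' [write_genomic_fasta()].
#'
#' @param genes named list of [gene_model()] objects.
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  feats <- do.call(rbind, lapply(genes, gene_model_features))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(feats$seqname, levels = unique(feats$seqname)),
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = feats$strand)
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$ID <- feats$ID
  S4Vectors::mcols(gr)$Parent <- feats$Parent
  S4Vectors::mcols(gr)$phase <- feats$phase
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read gene models from GFF3 + FASTA
#'
#' Reconstructs [gene_model()] objects from a GFF3 written by
#' [write_gene_models_gff3()] (or any GFF3 with gene/exon/CDS features and
#' one gene per seqname) plus the companion genomic FASTA.
#'
#' @param gff3_path GFF3 file.
#' @param fasta_path FASTA of genomic sequences named by gene id.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models_gff3 <- function(gff3_path, fasta_path) {
  gr <- rtracklayer::import(gff3_path, format = "GFF3")
  seqs <- read_genomic_fasta(fasta_path)
  ids <- unique(as.character(S4Vectors::mcols(
    gr[S4Vectors::mcols(gr)$type == "gene"])$ID))
  out <- lapply(ids, function(id) {
    sub <- gr[GenomicRanges::seqnames(gr) == id]
    strand <- as.character(GenomicRanges::strand(
      sub[S4Vectors::mcols(sub)$type == "gene"][1L]))
    ex <- sub[S4Vectors::mcols(sub)$type == "exon"]
    cds <- sub[S4Vectors::mcols(sub)$type == "CDS"]
    cds_lo <- min(GenomicRanges::start(cds))
    cds_hi <- max(GenomicRanges::end(cds))
    gene_model(
      id, seqs[[id]],
      cbind(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex)),
      cds_start = if (strand == "+") cds_lo else cds_hi,
      cds_end = if (strand == "+") cds_hi else cds_lo,
      strand = strand)
  })
  names(out) <- ids
  out
}

#' Write / read genomic sequences as FASTA
#'
#' @param genes named list of [gene_model()] objects.
#' @param path FASTA file.
#' @return `path` invisibly / named character vector of sequences.
#' @export
write_genomic_fasta <- function(genes, path) {
  ss <- Biostrings::DNAStringSet(
    vapply(genes, `[[`, "", "genomic_seq"))
  names(ss) <- vapply(genes, `[[`, "", "gene_id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_genomic_fasta
#' @export
read_genomic_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Export gene-model exons as BED
#'
#' rtracklayer handles the 1-based-inclusive to 0-based-half-open
#' conversion on export.
#'
#' @param genes named list of [gene_model()] objects.
#' @param path BED file.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(genes, path) {
  rows <- do.call(rbind, lapply(genes, function(gm)
    data.frame(seqname = gm$gene_id, start = gm$exons[, "start"],
               end = gm$exons[, "end"], strand = gm$strand,
               name = sprintf("%s.exon%d", gm$gene_id,
                              seq_len(nrow(gm$exons))))))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(rows$seqname, levels = unique(rows$seqname)),
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr)$name <- rows$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write / read an AS-event catalogue as CSV
#'
#' One row per primitive edit: `gene_id`, `event_id`, `kind`, `part_type`,
#' `index`, `delta`, `start`, `end`.
#'
#' @param events list of [as_event()] objects.
#' @param path CSV file.
#' @return `path` invisibly / list of [as_event()] objects.
#' @export
write_events_csv <- function(events, path) {
  rows <- lapply(events, function(ev) {
    do.call(rbind, lapply(ev$parts, function(p)
      data.frame(gene_id = ev$gene_id, event_id = ev$event_id,
                 kind = ev$kind, part_type = p$type,
                 index = if (is.null(p$index)) NA_integer_ else p$index,
                 delta = if (is.null(p$delta)) NA_integer_ else p$delta,
                 start = if (is.null(p$start)) NA_integer_ else p$start,
                 end = if (is.null(p$end)) NA_integer_ else p$end,
                 stringsAsFactors = FALSE)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(df[, c("gene_id", "event_id", "kind")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$gene_id == keys$gene_id[i] &
                df$event_id == keys$event_id[i], , drop = FALSE]
    parts <- lapply(seq_len(nrow(sub)), function(j) {
      p <- sub[j, ]
      switch(p$part_type,
             retain_intron = retain_intron(p$index),
             skip_exon = skip_exon(p$index),
             alt5ss = alt5ss(p$index, p$delta),
             alt3ss = alt3ss(p$index, p$delta),
             alt_exon = alt_exon(p$start, p$end),
             stop("unknown part type: ", p$part_type))
    })
    as_event(keys$event_id[i], keys$gene_id[i], keys$kind[i], parts)
  })
}
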