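#' Construct a gene model
#'
#' A gene model is an exon/intron structure laid out on a genomic sequence,
#' with an annotated coding region. Coordinates are 1-based inclusive on the
#' genomic sequence as stored, regardless of strand; for minus-strand genes
#' all transcript-level operations work internally on the reverse complement.
#'
#' @param gene_id character scalar, gene label.
#' @param genomic_seq character scalar, the genomic sequence (A/C/G/T).
#' @param exons two-column matrix or data.frame of exon `start`, `end`
#'   coordinates (1-based inclusive), non-overlapping. They may be given in
#'   any order; they are stored sorted by genomic start.
#' @param cds_start,cds_end genomic coordinates of the first nucleotide of
#'   the start codon and the last nucleotide of the stop codon. On the minus
#'   strand `cds_start > cds_end` in genomic coordinates is expected and
#'   handled.
#' @param strand `"+"` or `"-"`.
#' @param validate check structural invariants (exon order, CDS frame,
#'   terminal stop codon, canonical GT..AG introns). Default `TRUE`.
#'
#' @return An object of class `gene_model`: a list with elements `gene_id`,
#'   `genomic_seq`, `strand`, `exons` (matrix, genomic coordinates sorted by
#'   start), `cds_start`, `cds_end`, and derived `utr5`/`utr3` intervals in
#'   transcript coordinates.
#' @export
gene_model <- function(gene_id, genomic_seq, exons, cds_start, cds_end,
                       strand = "+", validate = TRUE) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(genomic_seq), length(genomic_seq) == 1L,
            strand %in% c("+", "-"))
  genomic_seq <- toupper(genomic_seq)
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  if (ncol(exons) != 2L) stop("`exons` must have two columns (start, end)")
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  gm <- structure(
    list(gene_id = gene_id, genomic_seq = genomic_seq, strand = strand,
         exons = exons, cds_start = as.integer(cds_start),
         cds_end = as.integer(cds_end)),
    class = "gene_model")
  layout <- coding_layout(gm)
  gm$utr5 <- c(1L, layout$cds_lo_tx - 1L)
  gm$utr3 <- c(layout$cds_hi_tx + 1L, nchar(layout$transcript))
  if (validate) {
    if (any(exons[, "end"] < exons[, "start"]))
      stop("exon end before start in gene ", gene_id)
    if (nrow(exons) > 1L &&
        any(exons[-1L, "start"] <= exons[-nrow(exons), "end"]))
      stop("overlapping exons in gene ", gene_id)
    if (max(exons) > nchar(genomic_seq))
      stop("exons extend beyond genomic sequence in gene ", gene_id)
    cds <- substr(layout$transcript, layout$cds_lo_tx, layout$cds_hi_tx)
    if (nchar(cds) %% 3L != 0L)
      stop("spliced CDS length not divisible by 3 in gene ", gene_id)
    if (substr(cds, 1L, 3L) != "ATG")
      stop("CDS does not begin with ATG in gene ", gene_id)
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (!last %in% c("TAA", "TAG", "TGA"))
      stop("CDS does not end in a stop codon in gene ", gene_id)
    viol <- validate_splice_sites(gm)
    if (nrow(viol) > 0L)
      stop("non-canonical splice sites in gene ", gene_id, ": ",
           paste(viol$intron, collapse = ", "))
  }
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  n_ex <- nrow(x$exons)
  cat(sprintf("<gene_model> %s (%s strand): %d exons, %d introns, %d bp genomic\n",
              x$gene_id, x$strand, n_ex, n_ex - 1L, nchar(x$genomic_seq)))
  invisible(x)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Canonical coding-strand view of a gene model. For plus-strand genes this
## is the stored layout; for minus-strand genes the sequence is
## reverse-complemented and all coordinates are flipped so downstream code
## only ever reasons 5'->3' on the coding strand.
coding_layout <- function(gm) {
  seq <- gm$genomic_seq
  exons <- gm$exons
  cds_lo <- min(gm$cds_start, gm$cds_end)
  cds_hi <- max(gm$cds_start, gm$cds_end)
  if (gm$strand == "-") {
    L <- nchar(seq)
    seq <- reverse_complement(seq)
    exons <- cbind(start = L - exons[, "end"] + 1L,
                   end   = L - exons[, "start"] + 1L)
    exons <- exons[order(exons[, "start"]), , drop = FALSE]
    tmp <- cds_lo
    cds_lo <- L - cds_hi + 1L
    cds_hi <- L - tmp + 1L
  }
  n <- nrow(exons)
  introns <- if (n > 1L) {
    cbind(start = exons[-n, "end"] + 1L, end = exons[-1L, "start"] - 1L)
  } else {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  exon_seqs <- substring(seq, exons[, "start"], exons[, "end"])
  transcript <- paste(exon_seqs, collapse = "")
  list(seq = seq, exons = exons, introns = introns,
       transcript = transcript,
       cds_lo_tx = genomic_to_transcript(exons, cds_lo),
       cds_hi_tx = genomic_to_transcript(exons, cds_hi))
}

## Map a coding-strand genomic position to its offset in the spliced
## transcript defined by `segments` (ordered, non-overlapping intervals).
## Returns NA if the position falls outside every segment.
genomic_to_transcript <- function(segments, pos) {
  off <- 0L
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, 1L]; e <- segments[i, 2L]
    if (pos >= s && pos <= e) return(off + (pos - s) + 1L)
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

#' Check introns for canonical GT..AG splice sites
#'
#' Every intron of a valid gene model is expected to begin with the GT donor
#' and end with the AG acceptor dinucleotide on the coding strand.
#'
#' @param gm a [gene_model()].
#' @return A data.frame with one row per violation: `intron` (index on the
#'   coding strand), `site` (`"donor"` or `"acceptor"`) and `observed`
#'   dinucleotide. Zero rows when all sites are canonical.
#' @export
validate_splice_sites <- function(gm) {
  lay <- coding_layout(gm)
  out <- data.frame(intron = integer(0), site = character(0),
                    observed = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lay$introns))) {
    s <- lay$introns[i, "start"]; e <- lay$introns[i, "end"]
    donor <- substr(lay$seq, s, s + 1L)
    acceptor <- substr(lay$seq, e - 1L, e)
    if (donor != "GT")
      out <- rbind(out, data.frame(intron = i, site = "donor",
                                   observed = donor))
    if (acceptor != "AG")
      out <- rbind(out, data.frame(intron = i, site = "acceptor",
                                   observed = acceptor))
  }
  out
}

#' Describe an alternative-splicing event
#'
#' An AS event is a set of primitive edits applied to a gene model's fully
#' spliced transcript. Supported primitives:
#' \describe{
#'   \item{`retain_intron(k)`}{intron `k` (coding-strand order) is kept.}
#'   \item{`skip_exon(k)`}{exon `k` is removed.}
#'   \item{`alt5ss(k, delta)`}{the donor at the 3' end of exon `k` moves by
#'     `delta` nt: negative trims the exon end, positive extends it into the
#'     intron.}
#'   \item{`alt3ss(k, delta)`}{the acceptor at the 5' start of exon `k`
#'     moves by `delta` nt: negative trims the exon start, positive extends
#'     it upstream into the intron.}
#'   \item{`alt_exon(start, end)`}{an unannotated (alternative) exon at the
#'     given coding-strand genomic interval is included.}
#' }
#' Composite events list two or more primitives; they are applied 5' to 3'
#' and must not overlap.
#'
#' @param event_id character label, e.g. `"I1R"`, `"E3S"`, `"Alt3ssE4"`.
#' @param gene_id gene the event belongs to.
#' @param kind one of `"intron_retention"`, `"exon_skipping"`, `"alt5ss"`,
#'   `"alt3ss"`, `"alt_exon"`, `"composite"`.
#' @param parts list of primitive edits, each a list with a `type` field
#'   (`"retain_intron"`, `"skip_exon"`, `"alt5ss"`, `"alt3ss"`,
#'   `"alt_exon"`) and its arguments (`index`, `delta`, `start`, `end`).
#' @return An object of class `as_event`.
#' @export
as_event <- function(event_id, gene_id, kind, parts) {
  kinds <- c("intron_retention", "exon_skipping", "alt5ss", "alt3ss",
             "alt_exon", "composite")
  if (!kind %in% kinds)
    stop("unknown event kind: ", kind)
  if (kind == "composite" && length(parts) < 2L)
    stop("composite events must list at least 2 parts")
  structure(list(event_id = event_id, gene_id = gene_id, kind = kind,
                 parts = parts), class = "as_event")
}

#' @export
print.as_event <- function(x, ...) {
  cat(sprintf("<as_event> %s [%s] on %s: %d part(s)\n",
              x$event_id, x$kind, x$gene_id, length(x$parts)))
  invisible(x)
}

## Primitive-edit constructors (convenience for fixture/event definitions).
#' @rdname as_event
#' @param index exon or intron index (coding-strand order).
#' @export
retain_intron <- function(index) list(type = "retain_intron", index = index)
#' @rdname as_event
#' @export
skip_exon <- function(index) list(type = "skip_exon", index = index)
#' @rdname as_event
#' @param delta signed shift of the splice site in nucleotides.
#' @export
alt5ss <- function(index, delta) list(type = "alt5ss", index = index,
                                      delta = delta)
#' @rdname as_event
#' @export
alt3ss <- function(index, delta) list(type = "alt3ss", index = index,
                                      delta = delta)
#' @rdname as_event
#' @param start,end coding-strand genomic interval of an alternative exon.
#' @export
alt_exon <- function(start, end) list(type = "alt_exon", start = start,
                                      end = end)
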