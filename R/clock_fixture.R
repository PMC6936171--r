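## Packaged fixture: five circadian-clock gene models (ScLHY, ScPRR37,
## ScPRR73, ScPRR95, ScTOC1) with the published AS-event catalogue.
##
## Real sugarcane sequences are not publicly deposited for these loci, so the
## fixture carries synthetic toy sequences engineered to reproduce the
## documented consequence of every event exactly: all intron-retention events
## insert premature termination codons; the ScPRR73 combined alternative
## splice-site event removes 246 nt (82 aa) in frame; the ScPRR37
## alternative 3' splice-site event in exon 4 removes 30 nt (10 aa) in
## frame. Exon/intron counts are inferred from the gene-structure diagrams
## (not enumerated in print) and are marked as such; they are always at
## least the largest exon/intron index any event references.

## T-free filler: no stop codon can form in any reading frame across filler,
## so frame bookkeeping stays fully deterministic.
filler_acg <- function(n) {
  paste(rep(c("G", "C", "A", "A", "C", "G", "C", "A", "G"),
            length.out = n), collapse = "")
}

## 12-mer reading ATA-ACA-AAT-AAC in the annotated frame (no stop) but
## containing a stop codon in both shifted frames; placed codon-aligned it
## converts any upstream frameshift into a PTC at a known exon.
frameshift_trap <- function() "ATAACAAATAAC"

## Intron starting GT and ending AG, built from T-free filler with the third
## base fixed to C (so the donor's T can never seed a stop codon). `phase`
## is the CDS length mod 3 at the donor; when `with_stop`, a TAA is written
## in the reading frame a retained intron would be translated in.
make_intron <- function(len, phase, with_stop = FALSE) {
  stopifnot(len >= 12L)
  chars <- strsplit(filler_acg(len), "")[[1]]
  chars[1:2] <- c("G", "T")
  chars[3] <- "C"
  if (with_stop) {
    q <- 6L + ((3L - phase) %% 3L)  # 0-based, congruent to (3-phase) mod 3
    chars[(q + 1L):(q + 3L)] <- c("T", "A", "A")
  }
  chars[(len - 1L):len] <- c("A", "G")
  paste(chars, collapse = "")
}

## Assemble a gene model from per-exon CDS bodies and intron sequences.
## Body 1 excludes the ATG; the last body excludes the terminal TAA. The
## plus-strand layout is built first; minus-strand genes are stored as its
## reverse complement with flipped coordinates.
assemble_fixture_gene <- function(gene_id, bodies, introns, strand = "+") {
  utr5 <- filler_acg(21L)
  utr3 <- filler_acg(15L)
  n <- length(bodies)
  stopifnot(length(introns) == n - 1L)
  exon_seqs <- bodies
  exon_seqs[1L] <- paste0(utr5, "ATG", bodies[1L])
  exon_seqs[n] <- paste0(bodies[n], "TAA", utr3)
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- exon_seqs
  pieces[seq(2L, 2L * n - 2L, by = 2L)] <- introns
  genomic <- paste(pieces, collapse = "")
  widths <- nchar(pieces)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  exon_idx <- seq(1L, 2L * n - 1L, by = 2L)
  exons <- cbind(start = starts[exon_idx], end = ends[exon_idx])
  cds_lo <- nchar(utr5) + 1L
  cds_hi <- ends[2L * n - 1L] - nchar(utr3)
  if (strand == "-") {
    L <- nchar(genomic)
    genomic <- reverse_complement(genomic)
    exons <- cbind(start = L - exons[, "end"] + 1L,
                   end = L - exons[, "start"] + 1L)
    tmp <- cds_lo
    cds_lo <- L - cds_hi + 1L   # genomic coord of stop's last nt, now start
    cds_hi <- L - tmp + 1L
    gene_model(gene_id, genomic, exons, cds_start = cds_hi,
               cds_end = cds_lo, strand = "-")
  } else {
    gene_model(gene_id, genomic, exons, cds_start = cds_lo,
               cds_end = cds_hi, strand = "+")
  }
}

#' Fixture gene models for the five clock genes
#'
#' Synthetic gene models for ScLHY, ScPRR37, ScPRR73, ScPRR95 and ScTOC1
#' whose AS-event catalogue ([clock_as_events()]) reproduces the documented
#' transcript consequences. Sequences are toy constructs (see file notes);
#' exon/intron counts are inferred. ScTOC1 is stored on the minus strand to
#' exercise the reverse-complement path.
#'
#' @return Named list of [gene_model()] objects.
#' @export
clock_gene_models <- function() {
  trap <- frameshift_trap()

  ## ScLHY: 8 exons; I1R carries an in-frame stop inside intron 1; intron 5
  ## is stop-free with length !== 0 mod 3, so its retention frameshifts into
  ## the trap at the start of exon 6 ("creates a PTC on exon 6").
  lhy <- assemble_fixture_gene(
    "ScLHY",
    bodies = c(filler_acg(60), filler_acg(90), filler_acg(81),
               filler_acg(72), filler_acg(96),
               paste0(trap, filler_acg(75)),
               filler_acg(60), filler_acg(45)),
    introns = c(make_intron(81L, phase = 0L, with_stop = TRUE),
                make_intron(80L, 0L), make_intron(84L, 0L),
                make_intron(77L, 0L),
                make_intron(88L, 0L),             # 88 %% 3 == 1, no stop
                make_intron(80L, 0L), make_intron(75L, 0L)))

  ## ScPRR37: 8 exons. Exon 3 length 82 (frameshift on skipping); exon 4
  ## opens with the 30 nt the alternative 3' splice site removes, then a
  ## codon-aligned trap; introns 3, 6 and 7 carry in-frame stops (a late
  ## stop-free retained intron would yield a PTC yet a longer raw protein,
  ## so I7R keeps its stop inside the intron). Intron 2 hosts the
  ## alternative exon Ex2a.
  p37_e4 <- paste0(filler_acg(30), filler_acg(2), trap, filler_acg(60))
  p37_e8 <- paste0(trap, filler_acg(48))
  alt_ex <- {
    chars <- strsplit(filler_acg(85L), "")[[1]]
    chars[7:9] <- c("T", "A", "A")   # in frame: entry phase is 0
    paste(chars, collapse = "")
  }
  p37_i2 <- paste0(make_intron(44L, 0L), alt_ex, make_intron(45L, 0L))
  prr37 <- assemble_fixture_gene(
    "ScPRR37",
    bodies = c(filler_acg(60), filler_acg(90), filler_acg(82),
               p37_e4, filler_acg(90), filler_acg(84), filler_acg(96),
               p37_e8),
    introns = c(make_intron(80L, 0L),
                p37_i2,
                make_intron(83L, phase = 1L, with_stop = TRUE),
                make_intron(78L, 1L), make_intron(80L, 0L),
                make_intron(90L, phase = 0L, with_stop = TRUE),
                make_intron(85L, phase = 0L, with_stop = TRUE)))

  ## ScPRR73: 8 exons; the combined Alt5ss E4 (-104) + Alt3ss E5 (-142)
  ## event removes 246 nt in frame (82 aa).
  prr73 <- assemble_fixture_gene(
    "ScPRR73",
    bodies = c(filler_acg(60), filler_acg(90), filler_acg(90),
               filler_acg(150), filler_acg(180), filler_acg(90),
               filler_acg(90), filler_acg(57)),
    introns = c(make_intron(78L, 0L),
                make_intron(84L, phase = 0L, with_stop = TRUE),
                make_intron(80L, 0L), make_intron(77L, 0L),
                make_intron(79L, 0L),
                make_intron(90L, phase = 0L, with_stop = TRUE),
                make_intron(76L, 0L)))

  ## ScPRR95: 8 exons; Alt3ss E5 includes 7 intron nucleotides, shifting
  ## frame into the trap at the start of exon 5 ("inserts a PTC on exon 5").
  prr95 <- assemble_fixture_gene(
    "ScPRR95",
    bodies = c(filler_acg(60), filler_acg(90), filler_acg(90),
               filler_acg(90), paste0(trap, filler_acg(78)),
               filler_acg(90), filler_acg(90), filler_acg(60)),
    introns = c(make_intron(77L, 0L), make_intron(80L, 0L),
                make_intron(84L, phase = 0L, with_stop = TRUE),
                make_intron(82L, 0L), make_intron(78L, 0L),
                make_intron(80L, 0L),
                make_intron(90L, phase = 0L, with_stop = TRUE)))

  ## ScTOC1: 6 exons, minus strand. Exon 3 length 88 (frameshift on
  ## skipping) with a trap in exon 4; introns 1 and 3 carry in-frame stops.
  toc1 <- assemble_fixture_gene(
    "ScTOC1",
    bodies = c(filler_acg(60), filler_acg(90), filler_acg(88),
               paste0(filler_acg(2), frameshift_trap(), filler_acg(57)),
               filler_acg(90), filler_acg(63)),
    introns = c(make_intron(84L, phase = 0L, with_stop = TRUE),
                make_intron(80L, 0L),
                make_intron(85L, phase = 1L, with_stop = TRUE),
                make_intron(80L, 0L), make_intron(77L, 0L)),
    strand = "-")

  list(ScLHY = lhy, ScPRR37 = prr37, ScPRR73 = prr73, ScPRR95 = prr95,
       ScTOC1 = toc1)
}

#' Fixture AS-event catalogue for the clock genes
#'
#' The published event list for the five genes: two or more intron
#' retentions per gene, exon skipping, alternative splice sites, one
#' alternative exon, and two composite events. The ScPRR95 I3R and ScTOC1
#' I3R retentions come from the gene-structure survey rather than the
#' printed event table (the survey states every gene carries at least two
#' retained introns); they are marked `inferred`.
#'
#' @return List of [as_event()] objects. The attribute `"effects"` is a
#'   data.frame with the documented effect per event
#'   (`"ptc"` or `"in_frame"`) and whether the event is inferred.
#' @export
clock_as_events <- function() {
  genes <- clock_gene_models()
  ## coding-strand genomic interval of the ScPRR37 alternative exon: it sits
  ## inside annotated intron 2, 44 nt after the donor, and is 85 nt long.
  lay37 <- coding_layout(genes$ScPRR37)
  ex2a_start <- lay37$introns[2L, "start"] + 44L
  ex2a_end <- ex2a_start + 84L

  ev <- list(
    as_event("I1R", "ScLHY", "intron_retention", list(retain_intron(1))),
    as_event("I5R", "ScLHY", "intron_retention", list(retain_intron(5))),
    as_event("Ex2a", "ScPRR37", "alt_exon",
             list(alt_exon(ex2a_start, ex2a_end))),
    as_event("E3S", "ScPRR37", "exon_skipping", list(skip_exon(3))),
    as_event("I3R", "ScPRR37", "intron_retention", list(retain_intron(3))),
    as_event("I6R", "ScPRR37", "intron_retention", list(retain_intron(6))),
    as_event("I7R", "ScPRR37", "intron_retention", list(retain_intron(7))),
    as_event("Alt3ssE4", "ScPRR37", "alt3ss", list(alt3ss(4, -30))),
    as_event("I2R", "ScPRR73", "intron_retention", list(retain_intron(2))),
    as_event("Alt5ssE4.Alt3ssE5", "ScPRR73", "composite",
             list(alt5ss(4, -104), alt3ss(5, -142))),
    as_event("I6R", "ScPRR73", "intron_retention", list(retain_intron(6))),
    as_event("I3R", "ScPRR95", "intron_retention", list(retain_intron(3))),
    as_event("Alt3ssE5", "ScPRR95", "alt3ss", list(alt3ss(5, 7))),
    as_event("I7R", "ScPRR95", "intron_retention", list(retain_intron(7))),
    as_event("I1R.E23S", "ScTOC1", "composite",
             list(retain_intron(1), skip_exon(2), skip_exon(3))),
    as_event("E3S", "ScTOC1", "exon_skipping", list(skip_exon(3))),
    as_event("I3R", "ScTOC1", "intron_retention", list(retain_intron(3))))

  effects <- data.frame(
    gene_id = vapply(ev, `[[`, "", "gene_id"),
    event_id = vapply(ev, `[[`, "", "event_id"),
    kind = vapply(ev, `[[`, "", "kind"),
    effect = c("ptc", "ptc", "ptc", "ptc", "ptc", "ptc", "ptc",
               "in_frame", "ptc", "in_frame", "ptc", "ptc", "ptc", "ptc",
               "ptc", "ptc", "ptc"),
    inferred = FALSE, stringsAsFactors = FALSE)
  effects$inferred[effects$gene_id == "ScPRR95" &
                     effects$event_id == "I3R"] <- TRUE
  effects$inferred[effects$gene_id == "ScTOC1" &
                     effects$event_id == "I3R"] <- TRUE
  attr(ev, "effects") <- effects
  ev
}
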