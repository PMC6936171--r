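## Transcript construction and consequence classification.

## Resolve an event into the ordered, non-overlapping coding-strand genomic
## segments whose concatenation is the transcript. event = NULL gives the
## fully spliced (FS) form.
transcript_segments <- function(gm, event = NULL) {
  lay <- coding_layout(gm)
  exons <- lay$exons
  n_ex <- nrow(exons)
  n_in <- nrow(lay$introns)
  skip <- rep(FALSE, n_ex)
  retain <- rep(FALSE, max(n_in, 1L))
  extra <- NULL
  if (!is.null(event)) {
    for (p in event$parts) {
      switch(p$type,
        retain_intron = {
          if (p$index < 1L || p$index > n_in)
            stop("annotation error: unknown intron index ", p$index,
                 " in gene ", gm$gene_id)
          retain[p$index] <- TRUE
        },
        skip_exon = {
          if (p$index < 1L || p$index > n_ex)
            stop("annotation error: unknown exon index ", p$index,
                 " in gene ", gm$gene_id)
          skip[p$index] <- TRUE
        },
        alt5ss = {
          if (p$index < 1L || p$index > n_ex)
            stop("annotation error: unknown exon index ", p$index)
          exons[p$index, "end"] <- exons[p$index, "end"] + as.integer(p$delta)
        },
        alt3ss = {
          if (p$index < 1L || p$index > n_ex)
            stop("annotation error: unknown exon index ", p$index)
          exons[p$index, "start"] <- exons[p$index, "start"] -
            as.integer(p$delta)
        },
        alt_exon = {
          extra <- rbind(extra, cbind(start = as.integer(p$start),
                                      end = as.integer(p$end)))
        },
        stop("annotation error: unknown edit type ", p$type))
    }
  }
  segs <- exons[!skip, , drop = FALSE]
  if (any(retain))
    segs <- rbind(segs, lay$introns[which(retain), , drop = FALSE])
  if (!is.null(extra)) segs <- rbind(segs, extra)
  segs <- segs[order(segs[, "start"]), , drop = FALSE]
  if (any(segs[, "end"] < segs[, "start"]))
    stop("invalid event: inverted segment produced by ",
         if (is.null(event)) "FS" else event$event_id)
  if (nrow(segs) > 1L &&
      any(segs[-1L, "start"] <= segs[-nrow(segs), "end"]))
    stop("invalid event: overlapping segments produced by ",
         if (is.null(event)) "FS" else event$event_id)
  ## merge segments that abut so retained introns fuse with their exons
  merged <- segs[1L, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1L]) {
    if (segs[i, "start"] == merged[nrow(merged), "end"] + 1L) {
      merged[nrow(merged), "end"] <- segs[i, "end"]
    } else {
      merged <- rbind(merged, segs[i, , drop = FALSE])
    }
  }
  list(segments = merged, layout = lay)
}

#' Build a transcript from a gene model and an optional AS event
#'
#' With `event = NULL` the fully spliced (FS) transcript is returned: all
#' introns removed, exons concatenated 5' to 3' on the coding strand. With
#' an event, each primitive edit is applied and the transcript is the exact
#' concatenation of the retained genomic segments.
#'
#' @param gm a [gene_model()].
#' @param event an [as_event()] or `NULL` for the FS form.
#' @return Character scalar, the transcript sequence (coding strand).
#' @export
build_transcript <- function(gm, event = NULL) {
  ts <- transcript_segments(gm, event)
  paste(substring(ts$layout$seq, ts$segments[, "start"],
                  ts$segments[, "end"]), collapse = "")
}

## Translate from the first position of `seq` until the first stop codon.
## Returns the amino-acid string (stop excluded) and whether a stop was hit.
translate_until_stop <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(list(protein = "", stopped = FALSE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, 3L * n)),
    no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(protein = substr(aa, 1L, stop_at - 1L), stopped = TRUE)
  } else {
    list(protein = aa, stopped = FALSE)
  }
}

#' Classify the transcript and protein consequence of an AS event
#'
#' Applies the event, translates the edited transcript from the annotated
#' start codon with the standard genetic code, and reports whether the event
#' inserts a premature termination codon (PTC) or preserves the reading
#' frame. A PTC is any stop codon at least one codon upstream of the
#' position homologous to the annotated stop; no NMD-rule prediction is
#' attempted.
#'
#' @param gm a [gene_model()].
#' @param event an [as_event()].
#' @return An object of class `event_consequence`: list with
#'   `transcript_seq`, `delta_nt` (signed length change vs the FS form),
#'   `frame_preserved`, `ptc`, `protein_seq` and `aa_delta` (amino acids
#'   lost vs wild type; `NA` unless the frame is preserved).
#' @export
classify_event <- function(gm, event) {
  fs <- transcript_segments(gm, NULL)
  as_ <- transcript_segments(gm, event)
  fs_tx <- paste(substring(fs$layout$seq, fs$segments[, "start"],
                           fs$segments[, "end"]), collapse = "")
  as_tx <- paste(substring(as_$layout$seq, as_$segments[, "start"],
                           as_$segments[, "end"]), collapse = "")
  delta_nt <- nchar(as_tx) - nchar(fs_tx)

  lay <- fs$layout
  ## coding-strand genomic coordinates of start codon / stop codon first nt
  cds_lo_gen <- transcript_to_genomic(fs$segments, lay$cds_lo_tx)
  stop_gen <- transcript_to_genomic(fs$segments, lay$cds_hi_tx - 2L)

  wt <- translate_until_stop(substr(fs_tx, lay$cds_lo_tx, nchar(fs_tx)))

  start_as <- genomic_to_transcript(as_$segments, cds_lo_gen)
  if (is.na(start_as))
    stop("classification error: CDS start removed by event ",
         event$event_id, " in gene ", gm$gene_id)
  tr <- translate_until_stop(substr(as_tx, start_as, nchar(as_tx)))
  first_stop_nt <- if (tr$stopped) start_as + 3L * nchar(tr$protein) else NA_integer_

  stop_as <- genomic_to_transcript(as_$segments, stop_gen)
  ptc <- if (!tr$stopped) {
    FALSE
  } else if (!is.na(stop_as)) {
    first_stop_nt < stop_as
  } else {
    nchar(tr$protein) < nchar(wt$protein)
  }
  frame_preserved <- (delta_nt %% 3L == 0L) && !ptc
  aa_delta <- if (frame_preserved) nchar(wt$protein) - nchar(tr$protein)
              else NA_integer_
  structure(
    list(event_id = event$event_id, gene_id = gm$gene_id,
         transcript_seq = as_tx, delta_nt = delta_nt,
         frame_preserved = frame_preserved, ptc = ptc,
         protein_seq = tr$protein, aa_delta = aa_delta),
    class = "event_consequence")
}

#' @export
print.event_consequence <- function(x, ...) {
  eff <- if (x$ptc) "inserts a PTC"
         else if (x$frame_preserved && x$aa_delta > 0)
           sprintf("in-frame, removes %d aa", x$aa_delta)
         else "in frame"
  cat(sprintf("<event_consequence> %s/%s: delta %+d nt, %s\n",
              x$gene_id, x$event_id, x$delta_nt, eff))
  invisible(x)
}

## Inverse of genomic_to_transcript: transcript offset -> coding-strand
## genomic position.
transcript_to_genomic <- function(segments, off) {
  rem <- off
  for (i in seq_len(nrow(segments))) {
    w <- segments[i, 2L] - segments[i, 1L] + 1L
    if (rem <= w) return(segments[i, 1L] + rem - 1L)
    rem <- rem - w
  }
  NA_integer_
}

#' Classify every event of a catalogue against its gene models
#'
#' Convenience wrapper producing the tidy consequence table used by the
#' analysis scripts.
#'
#' @param genes named list of [gene_model()] objects.
#' @param events list of [as_event()] objects.
#' @return data.frame with one row per event: `gene_id`, `event_id`,
#'   `kind`, `delta_nt`, `frame_preserved`, `ptc`, `aa_delta`.
#' @export
classify_events <- function(genes, events) {
  rows <- lapply(events, function(ev) {
    gm <- genes[[ev$gene_id]]
    if (is.null(gm))
      stop("annotation error: no gene model for ", ev$gene_id)
    cq <- classify_event(gm, ev)
    data.frame(gene_id = ev$gene_id, event_id = ev$event_id,
               kind = ev$kind, delta_nt = cq$delta_nt,
               frame_preserved = cq$frame_preserved, ptc = cq$ptc,
               aa_delta = if (is.na(cq$aa_delta)) NA_integer_ else cq$aa_delta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
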