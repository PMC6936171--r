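# Gene-model construction, transcript building and splice-site validation.

test_that("fully spliced transcript is the exon concatenation", {
  gm <- toy_two_exon_gene()
  expect_identical(build_transcript(gm), "ATGGCCGCAGGCGAAGATTAA")
})

test_that("intron retention keeps the full intron between its exons", {
  gm <- toy_two_exon_gene(intron_body = "AAATAAGCC")
  ev <- as_event("I1R", "toy", "intron_retention", list(retain_intron(1)))
  tx <- build_transcript(gm, ev)
  expect_identical(tx, gm$genomic_seq)  # single intron: retention = genomic
  expect_identical(nchar(tx) - nchar(build_transcript(gm)), 13L)
})

test_that("length conservation holds across the fixture catalogue", {
  genes <- clock_gene_models()
  for (gm in genes) {
    lay <- dielsplice:::coding_layout(gm)
    span <- max(lay$exons) - min(lay$exons) + 1L
    intron_total <- if (nrow(lay$introns) > 0L)
      sum(lay$introns[, "end"] - lay$introns[, "start"] + 1L) else 0L
    expect_identical(nchar(lay$transcript) + intron_total, span)
  }
})

test_that("every IR event grows the transcript by its intron's length", {
  genes <- clock_gene_models()
  events <- clock_as_events()
  ir <- Filter(function(e) e$kind == "intron_retention", events)
  for (ev in ir) {
    gm <- genes[[ev$gene_id]]
    lay <- dielsplice:::coding_layout(gm)
    k <- ev$parts[[1]]$index
    intron_len <- unname(lay$introns[k, "end"] - lay$introns[k, "start"] + 1L)
    delta <- nchar(build_transcript(gm, ev)) - nchar(build_transcript(gm))
    expect_identical(delta, intron_len)
  }
})

test_that("invalid feature indices and overlapping edits are rejected", {
  gm <- toy_two_exon_gene()
  expect_error(
    build_transcript(gm, as_event("bad", "toy", "intron_retention",
                                  list(retain_intron(7)))),
    "annotation error")
  expect_error(
    build_transcript(gm, as_event("bad", "toy", "exon_skipping",
                                  list(skip_exon(3)))),
    "annotation error")
  ## retained intron + donor extension into it overlap
  expect_error(
    build_transcript(gm, as_event("bad", "toy", "composite",
                                  list(retain_intron(1), alt5ss(1, 4)))),
    "invalid event")
})

test_that("splice-site validation flags non-canonical dinucleotides", {
  gm <- toy_two_exon_gene()
  expect_identical(nrow(validate_splice_sites(gm)), 0L)
  broken <- gm
  broken$genomic_seq <- sub("^ATGGCCGCAGT", "ATGGCCGCACT", gm$genomic_seq)
  viol <- validate_splice_sites(broken)
  expect_identical(viol$site, "donor")
  expect_identical(viol$observed, "CT")
  expect_identical(viol$intron, 1L)
})

test_that("fixture genes all carry canonical GT..AG introns", {
  for (gm in clock_gene_models())
    expect_identical(nrow(validate_splice_sites(gm)), 0L)
})

test_that("minus-strand genes behave exactly like their plus-strand twin", {
  plus <- toy_two_exon_gene()
  L <- nchar(plus$genomic_seq)
  minus <- gene_model("toy_minus", oracle_revcomp(plus$genomic_seq),
                      cbind(start = L - plus$exons[, "end"] + 1L,
                            end = L - plus$exons[, "start"] + 1L),
                      cds_start = L, cds_end = 1L, strand = "-")
  expect_identical(build_transcript(minus), build_transcript(plus))
  expect_identical(nrow(validate_splice_sites(minus)), 0L)
  ev <- as_event("I1R", "toy", "intron_retention", list(retain_intron(1)))
  expect_identical(build_transcript(minus, ev), build_transcript(plus, ev))
})

test_that("translation matches the hand-typed codon table on random CDSs", {
  withr::with_seed(42, {
    for (i in 1:100) {
      cds <- random_cds(sample(10:60, 1))
      expect_identical(dielsplice:::translate_until_stop(cds)$protein,
                       oracle_translate(cds))
    }
  })
})

test_that("gene-model invariants are enforced at construction", {
  # CDS not a multiple of 3
  expect_error(
    gene_model("bad", "ATGGCCGCTAA", cbind(1L, 11L), 1L, 11L),
    "divisible by 3")
  # missing terminal stop
  expect_error(
    gene_model("bad", "ATGGCCGCAAAA", cbind(1L, 12L), 1L, 12L),
    "stop codon")
  # non-canonical intron
  expect_error(
    gene_model("bad", "ATGGCCGCACTAAATAAGCCAGGGCTAA",
               rbind(c(1L, 9L), c(23L, 28L)), 1L, 28L),
    "non-canonical")
})
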