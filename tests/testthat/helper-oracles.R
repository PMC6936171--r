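# Independent oracles used across the suite. None of these call package
# internals: translation uses a hand-typed standard genetic code, OLS and
# the paired t use closed forms, and peak lookup is brute force.

oracle_codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# Translate until (and excluding) the first stop codon.
oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- unname(oracle_codon_table[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

# First in-frame stop position (1-based nt offset of the stop codon's first
# nt) scanning a given frame; NA if none.
oracle_first_stop <- function(seq, frame = 0L) {
  i <- 1L + frame
  while (i + 2L <= nchar(seq)) {
    if (substr(seq, i, i + 2L) %in% c("TAA", "TAG", "TGA")) return(i)
    i <- i + 3L
  }
  NA_integer_
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# Closed-form simple linear regression: slope, intercept, r^2, two-sided
# slope p-value.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  se_slope <- sqrt(sse / (n - 2) / sxx)
  tstat <- slope / se_slope
  list(slope = slope, intercept = intercept, r_squared = 1 - sse / sst,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = tstat,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 1))
}

# Random stop-free CDS of n_codons (plus ATG start and terminal stop).
random_cds <- function(n_codons) {
  all_codons <- names(oracle_codon_table)
  coding <- all_codons[oracle_codon_table != "*" & all_codons != "ATG"]
  paste0("ATG",
         paste(sample(coding, n_codons, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

# Two-exon toy gene with an arbitrary GT..AG intron between CDS halves.
toy_two_exon_gene <- function(intron_body = "AAATAAGCC", id = "toy") {
  exon1 <- "ATGGCCGCA"            # M A A
  exon2 <- "GGCGAAGATTAA"         # G E D *
  intron <- paste0("GT", intron_body, "AG")
  genomic <- paste0(exon1, intron, exon2)
  gene_model(id, genomic,
             rbind(c(1L, nchar(exon1)),
                   c(nchar(exon1) + nchar(intron) + 1L, nchar(genomic))),
             cds_start = 1L, cds_end = nchar(genomic), strand = "+")
}
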