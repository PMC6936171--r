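#!/usr/bin/env Rscript

# Stage 5 — splicing-ratio rhythms and temperature coupling.
#
# Computes log10(AS/FS) per event x organ x season, the linear-scale fold
# range of each (LOESS-smoothed) ratio rhythm, and the OLS regression of
# the ratio on ambient temperature with R^2 and p per group. Writes
# results under results/ratios/.

suppressMessages(library(dielsplice))

src <- "results/quantified"
out <- "results/ratios"
stopifnot(file.exists(file.path(src, "abundances.csv")))
dir.create(out, recursive = TRUE, showWarnings = FALSE)

quant <- read.csv(file.path(src, "abundances.csv"))
pseudo <- default_pseudocount(quant$norm_abundance)
groups <- unique(quant[quant$isoform_id != "FS",
                       c("gene_id", "isoform_id", "organ", "season_id")])

ratios <- list(); folds <- list(); regs <- list()
for (i in seq_len(nrow(groups))) {
  g <- groups[i, ]
  pick <- function(iso) {
    sel <- quant$gene_id == g$gene_id & quant$isoform_id == iso &
      quant$organ == g$organ & quant$season_id == g$season_id
    quant[sel, c("sample_id", "clock_time", "zt", "replicate",
                 "norm_abundance", "temp_c")]
  }
  as_s <- pick(g$isoform_id)
  rs <- ratio_series(as_s, pick("FS"), pseudo = pseudo)
  ratios[[i]] <- cbind(g[rep(1, nrow(rs)), ], rs, row.names = NULL)
  folds[[i]] <- cbind(g, fold = ratio_fold_range(rs, smooth = TRUE))
  reg <- temp_regression(rs, temp_c = as_s$temp_c)
  regs[[i]] <- cbind(g, slope = reg$slope, r_squared = reg$r_squared,
                     p_value = reg$p_value, n = reg$n,
                     significant_negative = reg$significant_negative)
}
write.csv(do.call(rbind, ratios), file.path(out, "ratio_series.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, folds), file.path(out, "fold_range.csv"),
          row.names = FALSE)
reg_tab <- do.call(rbind, regs)
write.csv(reg_tab, file.path(out, "temp_regressions.csv"),
          row.names = FALSE)

cat(sprintf("pseudo-count %.3g; %d ratio groups\n", pseudo, nrow(groups)))
neg <- reg_tab[reg_tab$significant_negative, ]
cat(sprintf("significant negative temperature coupling in %d/%d groups (genes: %s)\n",
            nrow(neg), nrow(reg_tab),
            paste(sort(unique(neg$gene_id)), collapse = ", ")))
cat("wrote", out, "\n")
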