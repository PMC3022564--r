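#!/usr/bin/env Rscript
# Step 3 — the ascertainment-bias signature.
#
# Summarises the between-population ratios (non-African-like over
# African-like) for per-genome burden and for minor-allele frequency at
# equal sample size (Monte-Carlo column). Under non-African-restricted
# pathogenic ascertainment the pathogenic category is expected to be the
# only one with ratios above 1. Writes a bar-chart figure when ggplot2 is
# available.

suppressMessages(library(mitosurvey))

if (!file.exists("results/tables/ratios.tsv"))
  stop("run analysis/02_survey.R first")

ratios <- read.delim("results/tables/ratios.tsv", check.names = FALSE)
keep <- c("Synonymous", "- Benign", "- Damaging", "Pathogenic total")
r <- ratios[ratios$category %in% keep, ]
cat("Between-population ratios (non-African-like / African-like):\n")
print(r, row.names = FALSE)

above <- r$category[r$burden_ratio > 1]
cat("\nCategories with burden ratio > 1:",
    if (length(above)) paste(above, collapse = ", ") else "none", "\n")
cat("Categories with Monte-Carlo frequency ratio > 1:",
    paste(r$category[!is.na(r$freq_ratio_mc) & r$freq_ratio_mc > 1],
          collapse = ", "), "\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  long <- rbind(
    data.frame(category = r$category, metric = "per-genome burden",
               ratio = r$burden_ratio, se = r$burden_ratio_se),
    data.frame(category = r$category, metric = "minor-allele frequency (MC)",
               ratio = r$freq_ratio_mc, se = r$freq_ratio_mc_se))
  long$category <- factor(long$category, levels = keep)
  p <- ggplot(long, aes(category, ratio)) +
    geom_col(fill = "grey35") +
    geom_errorbar(aes(ymin = ratio - se, ymax = ratio + se), width = 0.25) +
    geom_hline(yintercept = 1, linetype = 2) +
    facet_wrap(~metric) +
    labs(x = NULL, y = "non-African-like / African-like") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  ggsave("results/figures/ratio_signature.pdf", p, width = 7, height = 4)
  cat("Figure written to results/figures/ratio_signature.pdf\n")
}
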