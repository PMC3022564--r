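#' Published mtDNA survey reference values
#'
#' Headline numbers of the published genome-wide survey of human
#' mitochondrial polymorphism that this package's synthetic study design
#' emulates: 4458 complete genomes partitioned into an African population
#' (401 genomes, L haplogroups) and a non-African population (4057 genomes,
#' M/N haplogroups), with variable-site counts, printed percentages and
#' minor-allele totals per SNP category.
#'
#' `survey_reference_counts()` returns the variable-site table; percentages
#' are as printed (the survey reports them at one decimal; three printed
#' cells — African four-fold 53.0, total damaging 26.7 and non-African
#' damaging 26.3 — differ from their re-derived values at one-decimal
#' rounding, see [category_percentages()]). `survey_reference_sizes()`
#' returns the genome partition.
#'
#' @return A data.frame (counts) or named integer vector (sizes).
#' @export
survey_reference_counts <- function() {
  df <- data.frame(
    category = c("synonymous", "fourfold", "nonsynonymous", "unknown",
                 "benign", "damaging", "pathogenic", "pathogenic_coding",
                 "pathogenic_tRNA", "pathogenic_rRNA"),
    sites_total = c(2574L, 1177L, 1263L, 4L, 922L, 338L, 87L, 55L, 25L, 7L),
    pct_total = c(67.1, 45.7, 32.9, 0.3, 73.0, 26.7, NA, NA, NA, NA),
    sites_african = c(792L, 419L, 323L, 1L, 263L, 59L, 27L, 19L, 7L, 1L),
    pct_african = c(71.0, 53.0, 29.0, 0.3, 81.4, 18.3, NA, NA, NA, NA),
    sites_nonafrican = c(2422L, 1274L, 1178L, 4L, 865L, 309L, 85L, 53L,
                         25L, 7L),
    pct_nonafrican = c(67.3, 52.6, 32.7, 0.3, 73.4, 26.3, NA, NA, NA, NA),
    alleles_african = c(8614L, 4877L, 2942L, 5L, 2727L, 210L, 83L, 56L,
                        26L, 1L),
    alleles_nonafrican = c(39183L, 20284L, 15688L, 51L, 14611L, 1025L,
                           1259L, 956L, 177L, 126L),
    stringsAsFactors = FALSE)
  df
}

#' @rdname survey_reference_counts
#' @export
survey_reference_sizes <- function() {
  c(African = 401L, `non-African` = 4057L, total = 4458L)
}
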