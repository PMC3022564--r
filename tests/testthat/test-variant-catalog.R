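test_that("polymorphic site detection applies the missing-data rule", {
  ags <- aligned_genome_set(c("AAGA", "AAGA", "AAG-", "GAGG"),
                            paste0("g", 1:4))
  sites <- find_polymorphic_sites(ags)
  expect_equal(sites$pos0, c(0L, 3L))
  # column 1: (A,A,A,G) -> major A, minor G at 0.25
  minors <- call_minor_alleles(sites)
  m1 <- minors[minors$pos0 == 0L, ]
  expect_equal(m1$base, "G")
  expect_equal(m1$major, "A")
  expect_equal(m1$freq_pooled, 0.25)
  # column 4: (A,A,-,G) -> denominator 3
  m4 <- minors[minors$pos0 == 3L, ]
  expect_equal(m4$n_eff, 3L)
  expect_equal(m4$freq_pooled, 1 / 3)
  # monomorphic alignment: empty result, no error
  mono <- aligned_genome_set(c("AAAA", "AAAA"), c("a", "b"))
  expect_length(find_polymorphic_sites(mono)$pos0, 0L)
})

test_that("minor-allele calling breaks ties alphabetically and handles multi-allelic sites", {
  # tie: A and G both at 2 -> A is major
  ags <- aligned_genome_set(c("A", "A", "G", "G"), paste0("g", 1:4))
  minors <- call_minor_alleles(find_polymorphic_sites(ags))
  expect_equal(minors$major, "A")
  expect_equal(minors$base, "G")
  expect_equal(minors$freq_pooled, 0.5)
  # multi-allelic: counts A:5 C:2 T:1 -> minors C@0.25 and T@0.125
  ags2 <- aligned_genome_set(strsplit("AAAAACCT", "")[[1]], paste0("g", 1:8))
  minors2 <- call_minor_alleles(find_polymorphic_sites(ags2))
  expect_equal(nrow(minors2), 2L)
  expect_equal(minors2$freq_pooled[minors2$base == "C"], 0.25)
  expect_equal(minors2$freq_pooled[minors2$base == "T"], 0.125)
  # every minor allele is no more frequent than its major allele
  expect_true(all(minors2$freq_pooled <= 5 / 8))
})

test_that("effect classification is strand- and code-aware", {
  models <- tiny_models()
  ags <- tiny_genomes()
  bg <- major_background(ags)
  # P1 codon TTT (cols 4-6): T->C at codon position 3 is Phe->Phe
  cls <- classify_effect(5L, "C", models, bg)
  expect_equal(cls$category, "synonymous")
  expect_false(cls$fourfold)
  # P1 codon GGG (cols 10-12): G->A at position 1 makes AGG, a mito stop
  cls2 <- classify_effect(9L, "A", models, bg)
  expect_equal(cls2$category, "nonsynonymous")
  # P1 codon GGG position 3 is four-fold
  cls3 <- classify_effect(11L, "A", models, bg)
  expect_equal(cls3$category, "synonymous")
  expect_true(cls3$fourfold)
  # minus-strand gene: genomic CAT|CAT codes ATG|ATG; genomic G at the last
  # CAT column (pos0 20, codon 1 position 1 on the minus strand) gives
  # C on the coding strand -> CTG (Leu) vs ATG (Met): nonsynonymous
  cls4 <- classify_effect(20L, "G", models, bg)
  expect_equal(cls4$category, "nonsynonymous")
  expect_equal(cls4$compartment, "coding")
  # tRNA and rRNA compartments, and non-coding fallback
  expect_equal(classify_effect(22L, "A", models, bg)$category, "tRNA")
  expect_equal(classify_effect(26L, "A", models, bg)$category, "rRNA")
  expect_equal(classify_effect(0L, "T", models, bg)$category,
               "other-noncoding")
})

test_that("unresolved background codons are excluded, not guessed", {
  models <- tiny_models()
  ags <- tiny_genomes()
  bg <- major_background(ags)
  bg[4L] <- NA_integer_  # first base of P1 codon 1 unknown
  cls <- classify_effect(5L, "C", models, bg)
  expect_equal(cls$category, "unknown-codon")
})

test_that("overlapping protein genes classify nonsynonymous-if-any", {
  # two plus-strand genes sharing columns 4..9; a change synonymous in one
  # frame but nonsynonymous in the other must come out nonsynonymous
  models <- suppressMessages(
    gene_models(c("A", "B"), c(1L, 3L), c(9L, 11L), c("+", "+"),
                c("protein", "protein")))
  ags <- aligned_genome_set(rep("GGGGGGGGGGGG", 3L), paste0("g", 1:3))
  bg <- major_background(ags)
  # pos0 5 is codon-2 pos 3 of gene A (four-fold, synonymous) and codon-2
  # pos 1 of gene B (GGG -> AGG = stop, nonsynonymous)
  cls <- suppressMessages(classify_effect(5L, "A", models, bg))
  expect_equal(cls$category, "nonsynonymous")
})

test_that("annotations attach with unknown default and cross-cutting pathogenic flag", {
  models <- tiny_models()
  # variants: nonsyn at pos0 9 (G->A stop), syn at pos0 5 (T->C),
  # tRNA at pos0 22
  ags <- tiny_genomes(list(list(2L, 10L, "A"), list(4L, 6L, "C"),
                           list(6L, 23L, "A")), n = 8L)
  effect <- data.frame(pos0 = c(9L, 29L), base = c("A", "T"),
                       label = c("damaging", "benign"))
  class(effect) <- c("effect_annotation", "data.frame")
  catalogue <- data.frame(pos0 = c(22L, 5L), base = c("A", "C"),
                          status = c("Confirmed", "Reported"))
  class(catalogue) <- c("pathogenic_catalogue", "data.frame")
  cat_ <- suppressMessages(
    build_variant_catalog(ags, models, effect, catalogue))
  expect_equal(nrow(cat_), 3L)
  nonsyn <- cat_[cat_$pos0 == 9L, ]
  expect_equal(nonsyn$effect, "damaging")
  syn <- cat_[cat_$pos0 == 5L, ]
  expect_equal(syn$effect, "n/a")
  expect_true(syn$pathogenic)                 # flag independent of category
  expect_equal(syn$category, "synonymous")
  trna <- cat_[cat_$pos0 == 22L, ]
  expect_true(trna$pathogenic)
  expect_equal(trna$compartment, "tRNA")
  # the unmatched effect row (pos0 29) is reported
  expect_message(build_variant_catalog(ags, models, effect, catalogue),
                 "without a matching minor allele")
})

test_that("a nonsynonymous minor without an effect entry defaults to unknown", {
  models <- tiny_models()
  ags <- tiny_genomes(list(list(2L, 10L, "A")), n = 6L)
  cat_ <- build_variant_catalog(ags, models,
                                effect = structure(
                                  data.frame(pos0 = integer(0),
                                             base = character(0),
                                             label = character(0)),
                                  class = c("effect_annotation", "data.frame")))
  expect_equal(cat_$effect, "unknown")
})

test_that("per-population counts conserve pooled counts and ordering is irrelevant", {
  ags <- tiny_genomes(list(list(1L, 10L, "A"), list(2L, 10L, "A"),
                           list(3L, 6L, "C")), n = 10L)
  cat_ <- build_variant_catalog(ags, tiny_models())
  expect_equal(cat_$count_African + cat_$count_non_African, cat_$count_pooled)
  # reorder genomes
  perm <- c(7L, 2L, 9L, 1L, 4L, 10L, 3L, 5L, 8L, 6L)
  ags2 <- restrict_samples(ags, perm)
  cat2 <- build_variant_catalog(ags2, tiny_models())
  expect_equal(cat2[, names(cat2)], cat_[, names(cat_)])
})
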