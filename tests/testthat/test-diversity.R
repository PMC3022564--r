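test_that("ng_pair aggregates sites and differences with pairwise deletion", {
  p <- ng_pair("TTTAAAGGG", "TTCAAAGGG")
  expect_equal(p$S, 5 / 3)   # per-codon S: TTT 1/3, AAA 1/3, GGG 1
  expect_equal(p$sd, 1)
  expect_equal(p$nd, 0)
  expect_equal(p$pS, 0.6)
  expect_equal(p$pN, 0)
  # identical sequences
  p2 <- ng_pair("TTTAAAGGG", "TTTAAAGGG")
  expect_equal(p2$pS, 0)
  expect_equal(p2$pN, 0)
  # codon with a gap in either sequence is skipped entirely
  p3 <- ng_pair("TTTAAA", "TT-AAA")
  expect_equal(p3$n_codons, 1L)
  expect_equal(p3$pS, 0)
  # a stop codon in one sequence removes the codon from the comparison
  p4 <- ng_pair("AGATTT", "AGGTTT")  # both first codons are mito stops
  expect_equal(p4$n_codons, 1L)
  # nothing usable -> flagged undefined
  expect_warning(p5 <- ng_pair("AGA", "AGG"), "no usable codons")
  expect_true(p5$flagged)
  expect_true(is.na(p5$pS))
})

test_that("two-genome diversity equals the pairwise p-distance exactly", {
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 99), "G"), collapse = "")
  ags <- aligned_genome_set(c(s1, s2), c("a", "b"))
  est <- nucleotide_diversity(ags, class = "all", n_boot = 0L)
  expect_identical(est$pi, 0.01)
})

test_that("diversity of three genomes is the mean of the three pair distances", {
  base <- strsplit(paste(rep("A", 100), collapse = ""), "")[[1]]
  g1 <- base; g2 <- base; g3 <- base
  g2[1] <- "G"                       # d(g1,g2)=0.01
  g3[c(1, 50)] <- c("C", "T")        # d(g1,g3)=0.02, d(g2,g3)=0.02
  ags <- aligned_genome_set(vapply(list(g1, g2, g3), paste, "", collapse = ""),
                            c("a", "b", "c"))
  est <- nucleotide_diversity(ags, class = "all", n_boot = 0L)
  expect_equal(est$pi, mean(c(0.01, 0.02, 0.02)))
})

test_that("site-wise formula equals the brute-force double loop (no missing data)", {
  spec <- simulation_spec(populations = c(A = 5L, B = 7L),
                          genome_length = 1600L, variant_scale = 0.01,
                          missing_rate = 0)
  bundle <- plant_variants(spec, seed = 99L)
  est <- nucleotide_diversity(bundle$genomes, class = "all", n_boot = 0L)
  expect_equal(est$pi, oracle_pi_bruteforce(bundle$genomes$seq),
               tolerance = 1e-12)
})

test_that("duplicating a genome changes diversity predictably", {
  ags <- tiny_genomes(list(list(1L, 10L, "A"), list(2L, 6L, "C")), n = 5L)
  n <- 5L
  L <- alignment_length(ags)
  pi0 <- nucleotide_diversity(ags, class = "all", n_boot = 0L)$pi
  # closed form: the copy of genome i adds one zero pair plus i's distances
  d_i <- vapply(seq_len(n)[-5L], function(j)
    sum(ags$seq[5L, ] != ags$seq[j, ]) / L, 0)
  expected <- (pi0 * choose(n, 2) + sum(d_i)) / choose(n + 1L, 2)
  dup <- restrict_samples(ags, c(5L, 1:5))
  dup$sample_ids[1] <- "copy"
  pi1 <- nucleotide_diversity(dup, class = "all", n_boot = 0L)$pi
  expect_equal(pi1, expected, tolerance = 1e-12)
  expect_equal(pi1, oracle_pi_bruteforce(dup$seq), tolerance = 1e-12)
  # genome 5 is reference-identical (below-average distances), so its copy
  # lowers the average pairwise distance
  expect_lt(pi1, pi0)
})

test_that("NG86 diversity recovers planted synonymous excess", {
  spec <- simulation_spec(populations = c(A = 12L, B = 18L),
                          genome_length = 3000L, variant_scale = 0.05,
                          missing_rate = 0.001)
  bundle <- plant_variants(spec, seed = 5L)
  syn <- nucleotide_diversity(bundle$genomes, bundle$models, class = "syn",
                              population = "B", n_boot = 50L, seed = 2L)
  nonsyn <- nucleotide_diversity(bundle$genomes, bundle$models,
                                 class = "nonsyn", population = "B",
                                 n_boot = 50L, seed = 2L)
  expect_gt(syn$pi, nonsyn$pi)      # planted category diversities order
  expect_gte(syn$se, 0)
  expect_equal(syn$n_pairs, 18 * 17 / 2)
  # two-genome NG86 pair cross-check against ng_pair on extracted CDS
  two <- restrict_samples(bundle$genomes, c(1L, 2L), drop_population = TRUE)
  est2 <- nucleotide_diversity(two, bundle$models, class = "syn", n_boot = 0L)
  prot <- bundle$models[bundle$models$feature == "protein", ]
  cds <- vapply(as_sequences(two), function(s) {
    paste(vapply(seq_len(nrow(prot)), function(g) {
      piece <- substr(s, prot$start[g], prot$end[g])
      if (prot$strand[g] == "-")
        piece <- chartr("ACGT", "TGCA",
                        paste(rev(strsplit(piece, "")[[1]]), collapse = ""))
      piece
    }, ""), collapse = "")
  }, "")
  direct <- ng_pair(cds[[1]], cds[[2]])
  expect_equal(est2$pi, if (direct$S > 0) direct$sd / direct$S else NA_real_)
})

test_that("four-fold columns are detected on both strands", {
  models <- tiny_models()
  ags <- tiny_genomes()
  bg <- major_background(ags)
  cols <- fourfold_columns(models, bg)
  # GGG codon of P1 occupies cols 10..12 (pos0 9..11): position 3 (pos0 11)
  # is four-fold; TTT/AAA/CTA third positions are two-fold; the minus-strand
  # ATG codons have no four-fold position
  expect_true(11L %in% cols)
  expect_false(any(c(5L, 8L) %in% cols))
  expect_equal(length(cols), 2L)  # GGG pos3 and CTA pos3 (Leu CTN)
  expect_true(14L %in% cols)
})

test_that("population restriction and minimum size are enforced", {
  ags <- tiny_genomes(n = 6L)
  expect_error(nucleotide_diversity(ags, population = "nope", n_boot = 0L),
               "unknown or empty population")
  one <- restrict_samples(ags, 1L, drop_population = TRUE)
  expect_error(nucleotide_diversity(one, n_boot = 0L), "at least 2")
})
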