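make_catalog <- function(freqs_a, counts_a, freqs_b = freqs_a,
                         counts_b = counts_a, category = "synonymous",
                         effect = "n/a", pathogenic = FALSE) {
  n <- length(freqs_a)
  data.frame(pos0 = seq_len(n) - 1L, base = rep("G", n), major = rep("A", n),
             category = category, fourfold = FALSE, effect = effect,
             pathogenic = pathogenic,
             compartment = ifelse(category == "nonsynonymous", "coding",
                                  "noncoding"),
             count_pooled = counts_a + counts_b,
             n_eff = 100L, freq_pooled = (counts_a + counts_b) / 100,
             count_African = counts_a, n_eff_African = 40L,
             freq_African = freqs_a,
             count_non_African = counts_b, n_eff_non_African = 60L,
             freq_non_African = freqs_b)
}

test_that("mean minor-allele frequency averages segregating alleles only", {
  cat_ <- make_catalog(freqs_a = c(0.1, 0.3), counts_a = c(4L, 12L))
  m <- mean_minor_allele_frequency(cat_, "synonymous", "African")
  expect_equal(m[["mean"]], 0.2)
  expect_equal(m[["se"]], 0.1)
  expect_equal(m[["k"]], 2)
  # single allele: SE reported as 0
  one <- make_catalog(0.25, 10L)
  m1 <- mean_minor_allele_frequency(one, "synonymous", "African")
  expect_equal(m1[["mean"]], 0.25)
  expect_equal(m1[["se"]], 0)
  # absent in the population (count 0): flagged absent, not zero
  absent <- make_catalog(0, 0L)
  m0 <- mean_minor_allele_frequency(absent, "synonymous", "African")
  expect_true(is.na(m0[["mean"]]))
  expect_equal(m0[["k"]], 0)
  # empty category
  m2 <- mean_minor_allele_frequency(cat_, "damaging", "African")
  expect_true(is.na(m2[["mean"]]))
})

test_that("per-genome burden counts carriers and conserves allele counts", {
  # one minor allele (A at 2/6) carried by genomes 1 and 3 (both African)
  ags <- tiny_genomes(list(list(1L, 10L, "A"), list(3L, 10L, "A")), n = 6L)
  cat_ <- build_variant_catalog(ags, tiny_models())
  b <- per_genome_burden(cat_, ags, "nonsynonymous", "African")
  expect_equal(unname(b$counts), c(1L, 1L, 0L))
  expect_equal(b$mean, 2 / 3)
  bn <- per_genome_burden(cat_, ags, "nonsynonymous", "non-African")
  expect_equal(unname(bn$counts), c(0L, 0L, 0L))
  # a genome with missing data at the site is not a carrier
  ags2 <- tiny_genomes(list(list(1L, 10L, "A"), list(3L, 10L, "A"),
                            list(3L, 10L, "N")), n = 4L)
  cat2 <- build_variant_catalog(ags2, tiny_models())
  b2 <- per_genome_burden(cat2, ags2, "nonsynonymous", "African")
  expect_equal(sum(b2$counts), 1L)
  # conservation: sum over genomes equals the allele's population count
  expect_equal(sum(b2$counts), sum(cat2$count_African))
})

test_that("Monte-Carlo subsampling is deterministic and exact at full size", {
  ags <- tiny_genomes(list(list(2L, 10L, "A"), list(4L, 10L, "A"),
                           list(6L, 6L, "C")), n = 12L)
  stat <- function(sub) {
    sites <- find_polymorphic_sites(sub)
    c(n_sites = length(sites$pos0))
  }
  pop_n <- sum(unname(ags$population) == "non-African")
  full <- monte_carlo_subsample(ags, "non-African", pop_n, n_reps = 5L,
                                seed = 11L, statistic = stat)
  direct <- stat(restrict_samples(
    ags, which(unname(ags$population) == "non-African"),
    drop_population = TRUE))
  expect_true(all(full$replicates[, "n_sites"] == direct[["n_sites"]]))
  # determinism
  r1 <- monte_carlo_subsample(ags, "non-African", 3L, n_reps = 20L,
                              seed = 4L, statistic = stat)
  r2 <- monte_carlo_subsample(ags, "non-African", 3L, n_reps = 20L,
                              seed = 4L, statistic = stat)
  expect_identical(r1$replicates, r2$replicates)
  expect_false(identical(
    r1$replicates,
    monte_carlo_subsample(ags, "non-African", 3L, n_reps = 20L, seed = 5L,
                          statistic = stat)$replicates))
  # oversized subsample is an error
  expect_error(monte_carlo_subsample(ags, "non-African", pop_n + 1L,
                                     n_reps = 2L, seed = 1L, statistic = stat),
               "exceeds population size")
})

test_that("the fast Monte-Carlo path equals the generic recomputation", {
  fix <- small_bundle(seed = 21L, variant_scale = 0.015,
                      populations = c("African" = 15L, "non-African" = 45L))
  genomes <- fix$bundle$genomes
  models <- fix$bundle$models
  catalog <- build_variant_catalog(genomes, models)
  expect_gt(nrow(catalog), 0L)
  site_pos0 <- sort(unique(catalog$pos0))
  bg <- major_background(genomes)
  masks <- site_category_masks(site_pos0, models, bg)
  fast <- mc_category_maf(genomes, "non-African", 20L, n_reps = 15L,
                          seed = 9L, site_pos0 = site_pos0,
                          site_categories = masks)
  # same semantics as the fast path: minors re-called in the subsample,
  # classification fixed at the pooled background
  generic_stat <- function(sub) {
    minors <- call_minor_alleles(find_polymorphic_sites(sub))
    cls <- classify_effect(minors$pos0, minors$base, models, bg)
    minors <- cbind(minors, cls)
    minors <- attach_annotations(minors)
    vapply(c("synonymous", "nonsynonymous", "tRNA", "rRNA"), function(cat) {
      sel <- category_rows(minors, cat)
      if (!any(sel)) NA_real_ else mean(minors$freq_pooled[sel])
    }, 0)
  }
  generic <- monte_carlo_subsample(genomes, "non-African", 20L, n_reps = 15L,
                                   seed = 9L, statistic = generic_stat)
  for (cat in c("synonymous", "nonsynonymous", "tRNA", "rRNA")) {
    expect_equal(unname(fast$replicates[, cat]),
                 unname(generic$replicates[, cat]),
                 tolerance = 1e-12, label = cat)
  }
})

test_that("U-test matches exact enumeration and handles ties", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, oracle_utest_exact(c(1, 2, 3), c(4, 5, 6)))
  # complete tie
  expect_equal(mann_whitney_u(1, 1)$p_value, 1)
  # exact branch equals the enumeration oracle on random tie-free samples
  set.seed(31)
  for (i in 1:10) {
    x <- sample(1:50, 5L); y <- sample(51:100, 6L) - 50.5
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_utest_exact(x, y))
  }
  # U is within its bounds and symmetric-complementary
  r <- mann_whitney_u(c(5, 1, 9), c(2, 7, 11, 3))
  expect_gte(r$U, 0)
  expect_lte(r$U, 3 * 4)
  r2 <- mann_whitney_u(c(2, 7, 11, 3), c(5, 1, 9))
  expect_equal(r$U + r2$U, 12)
  expect_equal(r$p_value, r2$p_value)
})

test_that("ratio summaries propagate errors to first order", {
  r <- category_ratio(c(mean = 0.31, se = 0.008), c(mean = 0.21, se = 0.02))
  expect_equal(unname(r[["ratio"]]), 0.31 / 0.21)
  expect_gt(r[["ratio"]], 1)
  expect_equal(unname(r[["se"]]),
               (0.31 / 0.21) * sqrt((0.008 / 0.31)^2 + (0.02 / 0.21)^2))
  # equal summaries -> 1; zero SEs -> zero SE
  expect_equal(unname(category_ratio(c(mean = 2, se = 0),
                                     c(mean = 1, se = 0))),
               c(2, 0))
  expect_warning(r0 <- category_ratio(c(mean = 1, se = 0.1),
                                      c(mean = 0, se = 0)),
                 "zero or missing denominator")
  expect_true(is.na(r0[["ratio"]]))
})
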