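test_that("reference generation is stop-free on both strands and seed-deterministic", {
  spec <- simulation_spec(populations = c(A = 5L, B = 10L),
                          genome_length = 3000L, variant_scale = 0.01)
  r1 <- generate_reference(spec, seed = 3L)
  r2 <- generate_reference(spec, seed = 3L)
  r3 <- generate_reference(spec, seed = 4L)
  expect_identical(r1$reference, r2$reference)
  expect_false(identical(r1$reference, r3$reference))
  code <- genetic_code()
  prot <- r1$models[r1$models$feature == "protein", ]
  expect_gt(nrow(prot), 0L)
  expect_true(any(prot$strand == "-"))
  comp <- c(4L, 3L, 2L, 1L)
  for (g in seq_len(nrow(prot))) {
    n_codon <- (prot$end0[g] - prot$start0[g]) %/% 3L
    bases <- if (prot$strand[g] == "+")
      r1$reference[(prot$start0[g] + 1L):(prot$start0[g] + 3L * n_codon)]
    else comp[r1$reference[prot$end0[g]:(prot$end0[g] - 3L * n_codon + 1L)]]
    codons <- apply(matrix(c("A", "C", "G", "T")[bases], nrow = 3L), 2L,
                    paste, collapse = "")
    expect_false(any(code[codons] == "*"),
                 label = paste("internal stop in", prot$name[g]))
  }
})

test_that("layout overflow and insufficient eligible sites are errors", {
  expect_error(
    generate_reference(simulation_spec(populations = c(A = 2L, B = 2L),
                                       genome_length = 1000L,
                                       variant_scale = 0)),
    "too small")
  spec <- simulation_spec(populations = c(A = 4L, B = 6L),
                          genome_length = 1600L, variant_scale = 3)
  expect_error(plant_variants(spec, seed = 1L), "insufficient eligible sites")
})

test_that("planted variants carry their intended category and annotations", {
  fix <- small_bundle(seed = 13L, variant_scale = 0.03)
  man <- fix$bundle$manifest
  expect_gt(nrow(man), 20L)
  # planting is verified against classify_effect at generation time
  want <- c(syn = "synonymous", nonsyn = "nonsynonymous", tRNA = "tRNA",
            rRNA = "rRNA", noncoding = "other-noncoding")
  expect_equal(man$category, unname(want[man$type]))
  # effect labels flow into the annotation table
  eff <- fix$bundle$effect
  lab <- man$effect_label[!is.na(man$effect_label)]
  expect_equal(nrow(eff), length(lab))
  # binomial realisation keeps counts near target (loose sanity, not a tuned
  # bound): pooled expectation over many variants
  exp_count <- man$target_freq_1 * 40 + man$target_freq_2 * 160
  got_count <- man$count_African + man$count_non_African
  expect_gt(cor(exp_count, got_count), 0.5)
})

test_that("manifest counts are consistent with the written alignment", {
  fix <- small_bundle(seed = 17L, variant_scale = 0.02)
  man <- fix$bundle$manifest
  back <- read_alignment(fix$paths[["alignment"]],
                         population = read_sample_metadata(fix$paths[["samples"]]))
  for (p in c("African", "non-African")) {
    rows <- which(unname(back$population) == p)
    sp <- gsub("[^A-Za-z0-9]+", "_", p)
    for (i in seq_len(nrow(man))) {
      col <- man$position[i]
      bi <- match(man$base[i], c("A", "C", "G", "T"))
      expect_equal(sum(back$seq[rows, col] == bi),
                   man[[paste0("count_", sp)]][i])
    }
  }
})

test_that("the ascertainment knob keeps African-private variants out of the catalogue", {
  fix <- small_bundle(seed = 29L, variant_scale = 0.2, genome_length = 8000L,
                      populations = c("African" = 60L, "non-African" = 200L))
  man <- fix$bundle$manifest
  cat_ <- fix$bundle$catalogue
  usable <- cat_[cat_$status %in% c("Reported", "Confirmed"), ]
  expect_gt(nrow(usable), 0L)
  key <- paste(usable$pos0 + 1L, usable$base)
  man_key <- paste(man$position, man$base)
  hit <- match(key, man_key)
  expect_false(anyNA(hit))
  expect_true(all(man$count_non_African[hit] >= 1L))
  # under ascertainment = "all" the restriction is lifted
  spec_all <- simulation_spec(populations = c("African" = 60L,
                                              "non-African" = 200L),
                              genome_length = 8000L,
                              variant_scale = 0.2, ascertainment = "all")
  b_all <- plant_variants(spec_all, seed = 29L)
  expect_gte(nrow(b_all$catalogue), nrow(cat_))
})

test_that("bundles round-trip through the io readers and an empty spec is monomorphic", {
  fix <- small_bundle(seed = 41L, variant_scale = 0.02)
  back <- read_alignment(fix$paths[["alignment"]])
  expect_identical(as_sequences(back), as_sequences(fix$bundle$genomes))
  models <- read_gene_models(fix$paths[["genes"]])
  expect_equal(models$start0, fix$bundle$models$start0)
  expect_equal(models$feature, fix$bundle$models$feature)
  eff <- read_effect_annotation(fix$paths[["effect"]])
  expect_equal(nrow(eff), nrow(fix$bundle$effect))
  # empty-variant spec -> monomorphic alignment
  spec0 <- simulation_spec(populations = c(A = 4L, B = 8L),
                           genome_length = 1600L, variant_scale = 0,
                           missing_rate = 0)
  b0 <- plant_variants(spec0, seed = 2L)
  expect_equal(nrow(b0$manifest), 0L)
  expect_length(find_polymorphic_sites(b0$genomes)$pos0, 0L)
})
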