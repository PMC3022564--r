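code <- genetic_code()

test_that("vertebrate mitochondrial code has its four signature reassignments", {
  expect_equal(translate_codon("ATA", code), "M")
  expect_equal(translate_codon("TGA", code), "W")
  expect_equal(translate_codon("AGA", code), "*")
  expect_equal(translate_codon("AGG", code), "*")
  expect_true(is.na(translate_codon("AT-", code)))
  expect_true(is.na(translate_codon("ANA", code)))
})

test_that("NG86 site counts match enumeration for hand-derived codons", {
  expect_equal(count_syn_sites("TTT", code)[["S"]], 1 / 3)
  expect_equal(count_syn_sites("CTA", code)[["S"]], 4 / 3)
  expect_equal(count_syn_sites("GGG", code)[["S"]], 1)   # AGG is a stop
  expect_error(count_syn_sites("AGA", code), "stop")
  expect_error(count_syn_sites("AN-", code), "unresolved")
})

test_that("S + N = 3 and oracle equivalence for every non-stop codon", {
  nonstop <- names(code)[code != "*"]
  for (codon in nonstop) {
    got <- count_syn_sites(codon, code)
    expect_equal(got[["S"]] + got[["N"]], 3)
    expect_equal(got, oracle_site_counts(codon, code))
  }
})

test_that("pathway-averaged differences match hand-derived cases", {
  expect_equal(pairwise_codon_diffs("TTT", "TTC", code),
               c(sd = 1, nd = 0))
  expect_equal(pairwise_codon_diffs("TTT", "GTA", code),
               c(sd = 0.5, nd = 1.5))
  expect_equal(pairwise_codon_diffs("AAA", "AAA", code),
               c(sd = 0, nd = 0))
  # one of the two AGT<->CGA pathways passes through the stop codon AGA and
  # is excluded; the surviving path AGT->CGT(Ser->Arg)->CGA(Arg->Arg) gives
  # exactly one nonsynonymous and one synonymous step
  expect_equal(pairwise_codon_diffs("AGT", "CGA", code), c(sd = 1, nd = 1))
  expect_equal(pairwise_codon_diffs("AGT", "CGA", code),
               oracle_pairwise_diffs("AGT", "CGA", code))
  # AAA<->TGA: both pathways pass through a stop (TAA / AGA); the fallback
  # counts both steps of both pathways as nonsynonymous
  expect_equal(pairwise_codon_diffs("AAA", "TGA", code),
               c(sd = 0, nd = 2))
  expect_true(is.na(pairwise_codon_diffs("AA-", "AAA", code)[["sd"]]))
})

test_that("pairwise differences are symmetric and sum to the Hamming distance", {
  set.seed(42)
  nonstop <- names(code)[code != "*"]
  for (i in 1:200) {
    c1 <- sample(nonstop, 1L)
    c2 <- sample(nonstop, 1L)
    d12 <- pairwise_codon_diffs(c1, c2, code)
    d21 <- pairwise_codon_diffs(c2, c1, code)
    expect_equal(d12, d21)
    hd <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    expect_equal(unname(d12[["sd"]] + d12[["nd"]]), hd)
  }
})

test_that("degeneracy classes match enumeration and the site-count link", {
  expect_equal(degeneracy_class("GGG", 3, code), 4L)
  expect_equal(degeneracy_class("ATA", 3, code), 2L)
  expect_equal(degeneracy_class("TTT", 1, code), 1L)
  expect_true(is.na(degeneracy_class("NTT", 1, code)))
  # a position is four-fold iff it contributes a full synonymous site
  nonstop <- names(code)[code != "*"]
  for (codon in sample(nonstop, 20L)) {
    for (p in 1:3) {
      deg <- degeneracy_class(codon, p, code)
      aa <- code[codon]
      contrib <- sum(vapply(setdiff(c("A", "C", "G", "T"),
                                    substr(codon, p, p)), function(b) {
        mut <- codon
        substr(mut, p, p) <- b
        code[mut] == aa
      }, TRUE)) / 3
      expect_equal(deg == 4L, contrib == 1)
    }
  }
})

test_that("alternative genetic codes are loadable by NCBI id", {
  standard <- genetic_code(1)
  expect_equal(unname(standard["TGA"]), "*")
  expect_equal(unname(standard["AGA"]), "R")
  # CGA: under the standard code CGA->AGA is synonymous (Arg) so S = 4/3;
  # under the mitochondrial code AGA is a stop and S = 1
  expect_equal(count_syn_sites("CGA", standard)[["S"]], 4 / 3)
  expect_equal(count_syn_sites("CGA", code)[["S"]], 1)
})
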