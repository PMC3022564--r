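# Small in-code fixtures shared across test files.

write_fasta <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# A 30-column toy genome: one plus-strand protein gene (codons 1..4 at
# columns 4..15), one minus-strand protein gene at columns 16..21, a tRNA at
# 22..25 and an rRNA at 26..29; columns 1..3 and 30 are non-coding.
tiny_models <- function() {
  gene_models(name = c("P1", "P2", "T1", "R1"),
              start = c(4L, 16L, 22L, 26L),
              end = c(15L, 21L, 25L, 29L),
              strand = c("+", "-", "+", "+"),
              feature = c("protein", "protein", "tRNA", "rRNA"))
}

# Reference consistent with tiny_models(): P1 = TTT AAA GGG CTA,
# P2 (minus strand, genomic CATCAT -> coding ATGATG = Met Met).
tiny_reference <- function() {
  paste0("ACG", "TTTAAAGGGCTA", "CATCAT", "ACGT", "ACGT", "A")
}

tiny_genomes <- function(variants = list(), n = 6L,
                         populations = c("African", "non-African")) {
  ref <- tiny_reference()
  seqs <- rep(ref, n)
  for (v in variants) {  # list(row, pos1, base)
    substr(seqs[v[[1]]], v[[2]], v[[2]]) <- v[[3]]
  }
  ids <- paste0("g", seq_len(n))
  pop <- setNames(rep(populations, length.out = n), ids)
  aligned_genome_set(seqs, ids, pop)
}

# A small but complete synthetic bundle written to a temp dir, plus a config.
small_bundle <- function(seed = 7L,
                         dir = withr::local_tempdir(.local_envir = parent.frame()),
                         variant_scale = 0.02, missing_rate = 0.002,
                         populations = c("African" = 40L, "non-African" = 160L),
                         genome_length = 3000L) {
  spec <- simulation_spec(populations = populations,
                          genome_length = genome_length,
                          variant_scale = variant_scale,
                          missing_rate = missing_rate)
  bundle <- plant_variants(spec, seed = seed)
  paths <- write_bundle(bundle, dir)
  list(spec = spec, bundle = bundle, paths = paths, dir = dir)
}

small_config <- function(paths, outdir, seed = 3L, mc_reps = 40L,
                         pi_boot = 40L, pi_max_genomes = 25L, ...) {
  c(list(alignment = paths[["alignment"]], samples = paths[["samples"]],
         genes = paths[["genes"]], effect = paths[["effect"]],
         pathogenic = paths[["pathogenic"]], outdir = outdir, seed = seed,
         mc_reps = mc_reps, pi_boot = pi_boot,
         pi_max_genomes = pi_max_genomes), list(...))
}
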