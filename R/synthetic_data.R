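#' Frequency distribution specifications for planted variants
#'
#' Parametric minor-allele frequency distributions used by the generator:
#' `freq_beta(mean, shape1)` (Beta with given mean, truncated at 0.5),
#' `freq_point(value)` (point mass), `freq_uniform(min, max)`, and
#' `freq_twopoint(p_low, low, high)` (rare/common mixture; used to model the
#' ascertainment structure of catalogued pathogenic variants, which are
#' mostly rare with a discovered-common minority).
#'
#' @param mean,shape1 Beta mean and first shape parameter
#'   (`shape2 = shape1 * (1 - mean) / mean`).
#' @return A frequency-distribution spec (list).
#' @export
freq_beta <- function(mean, shape1 = 0.5) {
  stopifnot(mean > 0, mean < 0.5, shape1 > 0)
  list(kind = "beta", mean = mean, shape1 = shape1)
}

#' @rdname freq_beta
#' @param value Point-mass frequency in (0, 0.5].
#' @export
freq_point <- function(value) {
  stopifnot(value > 0, value <= 0.5)
  list(kind = "point", value = value)
}

#' @rdname freq_beta
#' @param min,max Uniform bounds in (0, 0.5].
#' @export
freq_uniform <- function(min, max) {
  stopifnot(min > 0, max <= 0.5, min <= max)
  list(kind = "uniform", min = min, max = max)
}

#' @rdname freq_beta
#' @param p_low Probability of the rare component.
#' @param low,high The two frequencies.
#' @export
freq_twopoint <- function(p_low, low, high) {
  stopifnot(p_low >= 0, p_low <= 1, low > 0, high <= 0.5)
  list(kind = "twopoint", p_low = p_low, low = low, high = high)
}

draw_freq <- function(dist, k) {
  if (!k) return(numeric(0))
  out <- switch(dist$kind,
    beta = {
      a <- dist$shape1
      b <- a * (1 - dist$mean) / dist$mean
      rbeta(k, a, b)
    },
    point = rep(dist$value, k),
    uniform = stats::runif(k, dist$min, dist$max),
    twopoint = ifelse(stats::runif(k) < dist$p_low, dist$low, dist$high),
    stop("unknown frequency distribution kind: ", dist$kind))
  pmin(pmax(out, 1e-6), 0.5)
}

# One planted-variant stratum: where variants go, how many, their annotation
# state and their per-population presence/frequency structure.
stratum <- function(name, n, type, effect = NA_character_,
                    pathogenic = FALSE, presence, freq) {
  list(name = name, n = as.integer(n), type = type, effect = effect,
       pathogenic = pathogenic, presence = presence, freq = freq)
}

#' Simulation specification for a synthetic survey bundle
#'
#' Defines the study conditions emulated by the generator: two populations of
#' very unequal size (an African-like reference population of 401 genomes and
#' a non-African-like population of 4057), a stylised mitochondrial gene
#' layout, and per-stratum planted variant counts with per-population
#' presence probabilities and minor-allele frequency distributions.
#'
#' The default strata mirror a published genome-wide survey of human mtDNA
#' polymorphism: per-stratum variant counts and per-population presence
#' probabilities follow its variable-site table (e.g. 2574 synonymous sites
#' of which 792 segregate in the African-like population), and
#' given-presence mean frequencies follow its frequency table (African
#' synonymous 0.027 vs non-African 0.0040; damaging several-fold below
#' benign). Beta skew parameters are chosen so that 401-genome subsampling
#' of the non-African-like population reproduces the survey's Monte-Carlo
#' column magnitudes. Catalogued ("pathogenic") variants are planted with a
#' non-African-biased structure and, under the default
#' `ascertainment = "non-African-only"`, only variants segregating in the
#' non-African-like population enter the catalogue — the ascertainment-bias
#' knob.
#'
#' @param populations Named integer vector of the two population sizes
#'   (smaller population first by convention).
#' @param genome_length Alignment length in bp.
#' @param variant_scale Multiplier applied to all stratum counts (rounded;
#'   0 gives a monomorphic alignment).
#' @param missing_rate Per-base probability of an `N` (missing data).
#' @param ascertainment `"non-African-only"` (default) or `"all"`: whether
#'   the pathogenic catalogue is restricted to variants segregating in the
#'   larger (non-African-like) population.
#' @param strata Optional custom list of strata (see source for structure);
#'   overrides the defaults.
#' @return A list of class `SimulationSpec`.
#' @export
simulation_spec <- function(populations = c("African" = 401L,
                                            "non-African" = 4057L),
                            genome_length = 16569L,
                            variant_scale = 1,
                            missing_rate = 0.001,
                            ascertainment = c("non-African-only", "all"),
                            strata = NULL) {
  ascertainment <- match.arg(ascertainment)
  stopifnot(length(populations) == 2L, !is.null(names(populations)),
            all(populations >= 2L))
  if (is.null(strata)) {
    strata <- list(
      stratum("syn", 2574, "syn",
              presence = c(0.3077, 0.9410),
              freq = list(freq_beta(0.027, 0.6), freq_beta(0.0040, 0.18))),
      stratum("benign", 922, "nonsyn", effect = "benign",
              presence = c(0.2852, 0.9382),
              freq = list(freq_beta(0.026, 0.6), freq_beta(0.0042, 0.18))),
      stratum("damaging", 338, "nonsyn", effect = "damaging",
              presence = c(0.1746, 0.9142),
              freq = list(freq_beta(0.0089, 0.6), freq_beta(0.00082, 0.15))),
      stratum("unknown", 4, "nonsyn",
              presence = c(0.25, 1.0),
              freq = list(freq_beta(0.023, 0.6), freq_beta(0.0033, 0.18))),
      stratum("tRNA", 150, "tRNA",
              presence = c(0.31, 0.94),
              freq = list(freq_beta(0.027, 0.6), freq_beta(0.0040, 0.18))),
      stratum("rRNA", 220, "rRNA",
              presence = c(0.31, 0.94),
              freq = list(freq_beta(0.027, 0.6), freq_beta(0.0040, 0.18))),
      stratum("noncoding", 250, "noncoding",
              presence = c(0.31, 0.94),
              freq = list(freq_beta(0.027, 0.6), freq_beta(0.0040, 0.18))),
      stratum("pathogenic_coding", 55, "nonsyn", effect = "damaging",
              pathogenic = TRUE,
              presence = c(0.345, 1.0),
              freq = list(freq_beta(0.0074, 10),
                          freq_twopoint(0.75, 5e-4, 0.0161))),
      stratum("pathogenic_tRNA", 25, "tRNA", pathogenic = TRUE,
              presence = c(0.28, 1.0),
              freq = list(freq_beta(0.0093, 10),
                          freq_twopoint(0.75, 5e-4, 0.0055))),
      stratum("pathogenic_rRNA", 7, "rRNA", pathogenic = TRUE,
              presence = c(0.143, 1.0),
              freq = list(freq_beta(0.0025, 10),
                          freq_twopoint(0.75, 5e-4, 0.0161)))
    )
  }
  if (variant_scale != 1) {
    strata <- lapply(strata, function(s) {
      s$n <- as.integer(round(s$n * variant_scale))
      s
    })
  }
  strata <- Filter(function(s) s$n > 0L, strata)
  out <- list(populations = populations, genome_length = as.integer(genome_length),
              strata = strata, missing_rate = missing_rate,
              ascertainment = ascertainment)
  class(out) <- "SimulationSpec"
  out
}

#' @export
print.SimulationSpec <- function(x, ...) {
  cat(sprintf("SimulationSpec: %d bp, populations %s, %d strata (%d variants), ascertainment %s\n",
              x$genome_length,
              paste(sprintf("%s=%d", names(x$populations), x$populations),
                    collapse = "/"),
              length(x$strata), sum(vapply(x$strata, `[[`, 0L, "n")),
              x$ascertainment))
  invisible(x)
}

# Stylised mitochondrial gene layout scaled to the genome length: a control-
# region-like noncoding block, two rRNAs, interspersed tRNAs and a set of
# protein genes (one on the minus strand), everything separated by short
# noncoding spacers.
build_gene_layout <- function(genome_length) {
  L <- genome_length
  if (L < 1500L) stop("genome_length too small for a gene layout (< 1500)")
  f <- L / 16569
  prot_codons <- pmax(25L, round(c(318, 347, 513, 227, 68, 226, 261, 115,
                                   98, 459, 603, 174, 380) * f))
  n_prot <- max(3L, min(13L, round(13 * f)))
  prot_codons <- prot_codons[seq_len(n_prot)]
  n_trna <- max(2L, min(10L, round(10 * f)))
  trna_len <- 70L
  rrna_len <- pmax(150L, round(c(954, 1602) * f))
  cr_len <- max(100L, round(1100 * f))

  needed <- cr_len + sum(rrna_len) + n_trna * trna_len + sum(prot_codons) * 3L
  if (needed > L)
    stop("gene layout overflow: needs ", needed, " bp, genome is ", L)

  pieces <- c(list(c("noncoding", cr_len)),
              list(c("rRNA", rrna_len[1L])),
              list(c("tRNA", trna_len)),
              list(c("rRNA", rrna_len[2L])))
  minus_gene <- n_prot - 1L  # penultimate protein gene on the minus strand
  ti <- 1L
  for (g in seq_len(n_prot)) {
    pieces <- c(pieces, list(c("protein", prot_codons[g] * 3L)))
    if (ti < n_trna - 1L && g %% 2L == 0L) {
      pieces <- c(pieces, list(c("tRNA", trna_len)))
      ti <- ti + 1L
    }
  }
  while (ti < n_trna) {
    pieces <- c(pieces, list(c("tRNA", trna_len)))
    ti <- ti + 1L
  }
  name <- character(0); start <- integer(0); end <- integer(0)
  strand <- character(0); feature <- character(0)
  pos <- 1L
  counters <- c(protein = 0L, tRNA = 0L, rRNA = 0L)
  prot_seen <- 0L
  for (pc in pieces) {
    len <- as.integer(pc[2L])
    if (pc[1L] == "noncoding") { pos <- pos + len; next }
    counters[pc[1L]] <- counters[pc[1L]] + 1L
    if (pc[1L] == "protein") prot_seen <- prot_seen + 1L
    name <- c(name, paste0(substr(pc[1L], 1L, 1L), toupper(substr(pc[1L], 2L, 2L)),
                           substring(pc[1L], 3L), counters[pc[1L]]))
    start <- c(start, pos); end <- c(end, pos + len - 1L)
    strand <- c(strand, if (pc[1L] == "protein" && prot_seen == minus_gene) "-"
                        else "+")
    feature <- c(feature, pc[1L])
    pos <- pos + len
  }
  gene_models(name, start, end, strand, feature, code_id = 2L)
}

#' Generate a reference genome and gene models
#'
#' Builds the stylised gene layout for the requested genome length and a
#' random reference sequence whose protein genes contain no internal stop
#' codons on their own strand. Deterministic for a fixed seed.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @param code Genetic code.
#' @return A list with `reference` (integer base codes) and `models`
#'   (a `gene_models` table).
#' @export
generate_reference <- function(spec, seed = 1L, code = genetic_code()) {
  models <- build_gene_layout(spec$genome_length)
  comp <- c(4L, 3L, 2L, 1L)
  ref <- with_preserved_seed(seed, {
    r <- sample.int(4L, spec$genome_length, replace = TRUE)
    nonstop <- which(code != "*")
    split3 <- do.call(rbind, strsplit(CODONS, ""))
    prot <- models[models$feature == "protein", , drop = FALSE]
    for (g in seq_len(nrow(prot))) {
      n_codon <- (prot$end0[g] - prot$start0[g]) %/% 3L
      cods <- sample(nonstop, n_codon, replace = TRUE)
      bases <- base_to_int(as.vector(t(split3[cods, , drop = FALSE])))
      if (prot$strand[g] == "+") {
        r[(prot$start0[g] + 1L):(prot$start0[g] + 3L * n_codon)] <- bases
      } else {
        r[prot$end0[g]:(prot$end0[g] - 3L * n_codon + 1L)] <- comp[bases]
      }
    }
    r
  })
  list(reference = ref, models = models)
}

# Enumerate eligible (pos0, alt) pairs per planting type against the
# reference background. For coding types the NG86 tables decide synonymy.
eligible_pools <- function(reference, models, code) {
  tabs <- ng_site_table(code)
  comp <- c(4L, 3L, 2L, 1L)
  aa <- code
  syn_pos <- integer(0); syn_alt <- integer(0); syn_four <- logical(0)
  non_pos <- integer(0); non_alt <- integer(0)
  prot <- models[models$feature == "protein", , drop = FALSE]
  base_chars <- BASES[1:4]
  for (g in seq_len(nrow(prot))) {
    st <- prot$start0[g]; en <- prot$end0[g]
    n_codon <- (en - st) %/% 3L
    minus <- prot$strand[g] == "-"
    for (p in 1:3) {
      if (minus) {
        cols0 <- (en - 1L) - (3L * (seq_len(n_codon) - 1L) + (p - 1L))
        b_cod <- function(q) comp[reference[(en - 1L) - (3L * (seq_len(n_codon) - 1L) + (q - 1L)) + 1L]]
      } else {
        cols0 <- st + 3L * (seq_len(n_codon) - 1L) + (p - 1L)
        b_cod <- function(q) reference[st + 3L * (seq_len(n_codon) - 1L) + (q - 1L) + 1L]
      }
      b1 <- b_cod(1L); b2 <- b_cod(2L); b3 <- b_cod(3L)
      idx <- codon_index(b1, b2, b3)
      cur <- switch(p, b1, b2, b3)
      for (alt_coding in 1:4) {
        chg <- which(alt_coding != cur)
        if (!length(chg)) next
        bb1 <- b1[chg]; bb2 <- b2[chg]; bb3 <- b3[chg]
        if (p == 1L) bb1 <- rep(alt_coding, length(chg))
        if (p == 2L) bb2 <- rep(alt_coding, length(chg))
        if (p == 3L) bb3 <- rep(alt_coding, length(chg))
        mut_idx <- codon_index(bb1, bb2, bb3)
        same <- aa[mut_idx] == aa[idx[chg]]
        alt_genomic <- if (minus) comp[alt_coding] else alt_coding
        syn_sel <- chg[same]
        if (length(syn_sel)) {
          syn_pos <- c(syn_pos, cols0[syn_sel])
          syn_alt <- c(syn_alt, rep(alt_genomic, length(syn_sel)))
          syn_four <- c(syn_four, tabs$deg[cbind(idx[syn_sel], p)] == 4L)
        }
        non_sel <- chg[!same]
        if (length(non_sel)) {
          non_pos <- c(non_pos, cols0[non_sel])
          non_alt <- c(non_alt, rep(alt_genomic, length(non_sel)))
        }
      }
    }
  }
  feat_pool <- function(feat) {
    fm <- models[models$feature == feat, , drop = FALSE]
    unlist(lapply(seq_len(nrow(fm)), function(g)
      seq.int(fm$start0[g], fm$end0[g] - 1L)))
  }
  in_gene <- rep(FALSE, length(reference))
  for (g in seq_len(nrow(models)))
    in_gene[(models$start0[g] + 1L):models$end0[g]] <- TRUE
  list(syn = data.frame(pos0 = syn_pos, alt = syn_alt, fourfold = syn_four),
       nonsyn = data.frame(pos0 = non_pos, alt = non_alt),
       tRNA = feat_pool("tRNA"),
       rRNA = feat_pool("rRNA"),
       noncoding = which(!in_gene) - 1L)
}

#' Plant variants into a synthetic population alignment
#'
#' For each stratum of the spec, eligible positions are chosen (distinct
#' across all strata), per-population presence is drawn (Bernoulli), target
#' frequencies are drawn from the stratum's distributions, and carriers are
#' sampled binomially at the target frequency in each population. `N`s are
#' then sprinkled at the missing-data rate, and the truth manifest records
#' both targets and counts realised in the final alignment (read back from
#' it, so the manifest is consistent with the written data by construction).
#' Planted coding categories are verified post hoc with [classify_effect()]
#' against the reference background.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed (drives reference, planting and missingness).
#' @param code Genetic code.
#' @return A list of class `synthetic_bundle`: `genomes`
#'   (an `AlignedGenomeSet`), `models`, `effect` (`effect_annotation`),
#'   `catalogue` (`pathogenic_catalogue`, including a few non-usable decoy
#'   statuses), `manifest` (truth data.frame) and `spec`.
#' @export
plant_variants <- function(spec, seed = 1L, code = genetic_code()) {
  ref <- generate_reference(spec, seed = seed, code = code)
  reference <- ref$reference
  models <- ref$models
  pools <- eligible_pools(reference, models, code)
  pops <- names(spec$populations)
  n_pop <- as.integer(spec$populations)
  n_tot <- sum(n_pop)
  pop_of_row <- rep(pops, n_pop)
  L <- spec$genome_length

  planted <- with_preserved_seed(seed + 1L, {
    used <- logical(L)
    rows_list <- list()
    for (s in spec$strata) {
      if (s$type %in% c("syn", "nonsyn")) {
        pool <- pools[[s$type]]
        avail <- !used[pool$pos0 + 1L]
        pool <- pool[avail, , drop = FALSE]
        upos <- unique(pool$pos0)
        if (length(upos) < s$n)
          stop("insufficient eligible sites for stratum '", s$name, "': need ",
               s$n, ", have ", length(upos))
        sel_pos <- if (length(upos) == 1L) upos else sample(upos, s$n)
        # one eligible alternate per chosen position (random among options)
        pp <- pool[pool$pos0 %in% sel_pos, , drop = FALSE]
        pp <- pp[sample.int(nrow(pp)), , drop = FALSE]
        pp <- pp[!duplicated(pp$pos0), , drop = FALSE]
        df <- data.frame(pos0 = pp$pos0, alt = pp$alt,
                         fourfold = if (s$type == "syn") pp$fourfold else FALSE)
      } else {
        pool <- pools[[s$type]]
        pool <- pool[!used[pool + 1L]]
        if (length(pool) < s$n)
          stop("insufficient eligible sites for stratum '", s$name, "': need ",
               s$n, ", have ", length(pool))
        sel_pos <- if (length(pool) == 1L) pool else sample(pool, s$n)
        alt <- vapply(sel_pos, function(p) {
          sample(setdiff(1:4, reference[p + 1L]), 1L)
        }, 0L)
        df <- data.frame(pos0 = sel_pos, alt = alt, fourfold = FALSE)
      }
      used[df$pos0 + 1L] <- TRUE
      df$stratum <- s$name
      df$type <- s$type
      df$effect_label <- s$effect
      df$pathogenic <- s$pathogenic
      for (k in 1:2) {
        pres <- stats::runif(nrow(df)) < s$presence[k]
        f <- numeric(nrow(df))
        f[pres] <- draw_freq(s$freq[[k]], sum(pres))
        df[[paste0("presence_", k)]] <- pres
        df[[paste0("target_freq_", k)]] <- f
      }
      rows_list[[s$name]] <- df
    }
    do.call(rbind, rows_list)
  })
  if (is.null(planted)) {
    planted <- data.frame(pos0 = integer(0), alt = integer(0),
                          fourfold = logical(0), stratum = character(0),
                          type = character(0), effect_label = character(0),
                          pathogenic = logical(0),
                          presence_1 = logical(0), target_freq_1 = numeric(0),
                          presence_2 = logical(0), target_freq_2 = numeric(0),
                          stringsAsFactors = FALSE)
    planted$category <- character(0)
    planted$compartment <- character(0)
  }
  rownames(planted) <- NULL

  # verify planted coding categories against the reference background
  if (nrow(planted)) {
    cls <- classify_effect(planted$pos0, BASES[planted$alt], models,
                           reference, code)
    want <- c(syn = "synonymous", nonsyn = "nonsynonymous",
              tRNA = "tRNA", rRNA = "rRNA", noncoding = "other-noncoding")
    bad <- cls$category != unname(want[planted$type])
    if (any(bad))
      stop("internal planting error: ", sum(bad),
           " variant(s) with mismatched realised category")
    planted$category <- cls$category
    planted$compartment <- cls$compartment
    planted$fourfold <- cls$fourfold
  }

  # build the alignment
  m <- matrix(rep(reference, each = n_tot), nrow = n_tot)
  with_preserved_seed(seed + 2L, {
    offs <- c(0L, n_pop[1L])
    for (i in seq_len(nrow(planted))) {
      col <- planted$pos0[i] + 1L
      for (k in 1:2) {
        f <- planted[[paste0("target_freq_", k)]][i]
        if (f <= 0) next
        cnt <- rbinom(1L, n_pop[k], f)
        if (cnt > 0L)
          m[offs[k] + sample.int(n_pop[k], cnt), col] <- planted$alt[i]
      }
    }
    if (spec$missing_rate > 0) {
      n_cells <- as.numeric(n_tot) * L
      k_miss <- rbinom(1L, n_cells, spec$missing_rate)
      if (k_miss > 0L) {
        idx <- sample(n_cells, k_miss)
        m[idx] <- BASE_N
      }
    }
  })
  ids <- sprintf("g%05d", seq_len(n_tot))
  genomes <- new_aligned_genome_set(m, ids, setNames(pop_of_row, ids))

  # read realised counts back from the final alignment
  manifest <- planted
  if (nrow(manifest)) {
    cols <- manifest$pos0 + 1L
    pooled_counts <- matrix(0L, nrow = 4L, ncol = nrow(manifest))
    for (k in 1:2) {
      rows <- which(pop_of_row == pops[k])
      sub <- m[rows, cols, drop = FALSE]
      cnt <- sub == matrix(manifest$alt, nrow = length(rows),
                           ncol = nrow(manifest), byrow = TRUE)
      called <- sub <= 4L
      manifest[[paste0("count_", sanitize_label(pops[k]))]] <- colSums(cnt)
      manifest[[paste0("n_eff_", sanitize_label(pops[k]))]] <- colSums(called)
      for (b in 1:4)
        pooled_counts[b, ] <- pooled_counts[b, ] + colSums(sub == b)
    }
    for (k in 1:2) {
      cc <- manifest[[paste0("count_", sanitize_label(pops[k]))]]
      ne <- manifest[[paste0("n_eff_", sanitize_label(pops[k]))]]
      manifest[[paste0("freq_", sanitize_label(pops[k]))]] <-
        ifelse(ne > 0L, cc / ne, 0)
    }
    major <- major_alleles(pooled_counts)
    manifest$minor <- !is.na(major) & major != manifest$alt &
      (manifest[[paste0("count_", sanitize_label(pops[1L]))]] +
         manifest[[paste0("count_", sanitize_label(pops[2L]))]]) > 0L
    manifest$position <- manifest$pos0 + 1L
    manifest$base <- BASES[manifest$alt]
    manifest$effect <- ifelse(manifest$category == "nonsynonymous",
                              ifelse(is.na(manifest$effect_label), "unknown",
                                     manifest$effect_label),
                              "n/a")
  }

  # annotation files
  eff_rows <- which(!is.na(planted$effect_label))
  effect <- data.frame(pos0 = planted$pos0[eff_rows],
                       base = BASES[planted$alt[eff_rows]],
                       label = planted$effect_label[eff_rows],
                       stringsAsFactors = FALSE)
  class(effect) <- c("effect_annotation", "data.frame")

  path_rows <- which(planted$pathogenic)
  if (spec$ascertainment == "non-African-only" && length(path_rows)) {
    seg_big <- manifest[[paste0("count_", sanitize_label(pops[2L]))]] > 0L
    path_rows <- path_rows[seg_big[path_rows]]
  }
  catalogue <- data.frame(pos0 = planted$pos0[path_rows],
                          base = BASES[planted$alt[path_rows]],
                          status = with_preserved_seed(seed + 3L,
                            sample(c("Reported", "Confirmed"),
                                   length(path_rows), replace = TRUE,
                                   prob = c(0.8, 0.2))),
                          stringsAsFactors = FALSE)
  # a few decoy statuses that readers must discard
  if (nrow(catalogue) >= 3L) {
    decoys <- catalogue[1:3, , drop = FALSE]
    decoys$status <- c("Unclear", "Provisional", "PointMutationPolymorphism")
    catalogue <- rbind(catalogue, decoys)
  }
  class(catalogue) <- c("pathogenic_catalogue", "data.frame")

  manifest$alt <- NULL
  out <- list(genomes = genomes, models = models, effect = effect,
              catalogue = catalogue, manifest = manifest, spec = spec,
              reference = reference, seed = seed)
  class(out) <- "synthetic_bundle"
  out
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("synthetic_bundle: %d genomes x %d bp, %d planted variants, %d catalogue entries\n",
              n_genomes(x$genomes), alignment_length(x$genomes),
              nrow(x$manifest), nrow(x$catalogue)))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Emits exactly the file formats the survey readers consume: aligned
#' multi-FASTA, sample metadata TSV, GFF3 gene models, effect-annotation and
#' pathogenic-catalogue TSVs, plus the truth manifest.
#'
#' @param bundle A `synthetic_bundle` from [plant_variants()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             samples = file.path(dir, "samples.tsv"),
             genes = file.path(dir, "genes.gff3"),
             effect = file.path(dir, "effect.tsv"),
             pathogenic = file.path(dir, "pathogenic.tsv"),
             manifest = file.path(dir, "manifest.tsv"))
  write_alignment(bundle$genomes, paths[["alignment"]])
  write_sample_metadata(bundle$genomes$population, paths[["samples"]])
  write_gene_models(bundle$models, paths[["genes"]])
  write_annotation(bundle$effect, paths[["effect"]])
  write_annotation(bundle$catalogue, paths[["pathogenic"]])
  man <- bundle$manifest
  man$pos0 <- NULL
  write.table(man, paths[["manifest"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
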