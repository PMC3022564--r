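# Display rows of the report tables: label -> summary-category key.
TABLE_ROWS <- list(
  c("Synonymous", "synonymous"),
  c("- Four fold", "fourfold"),
  c("Nonsynonymous", "nonsynonymous"),
  c("- Unknown", "unknown"),
  c("- Benign", "benign"),
  c("- Damaging", "damaging"),
  c("tRNA", "tRNA"),
  c("rRNA", "rRNA"),
  c("Other noncoding", "other-noncoding"),
  c("Pathogenic total", "pathogenic"),
  c("- Coding regions", "pathogenic_coding"),
  c("- tRNAs", "pathogenic_tRNA"),
  c("- rRNAs", "pathogenic_rRNA"))

#' Read a survey configuration file
#'
#' YAML key-value configuration driving [run_survey()]. Keys: `alignment`,
#' `samples`, `genes` (paths, required); `effect`, `pathogenic` (paths,
#' optional); `outdir` (required); `seed` (default 1); `mc_reps` (default
#' 1000); `mc_size` (default: size of the smaller population); `pi_boot`
#' (bootstrap resamples for diversity SEs, default 1000); `pi_max_genomes`
#' (genome cap for the quadratic NG86 diversity computation, default 60);
#' `minor_definition` (`"pooled"` or `"population"`, default pooled: whether
#' per-population variable-site counts use the pooled minor-allele definition
#' or re-call minors within each population); `subsample_recall` (default
#' `TRUE`: re-call minor alleles within each Monte-Carlo subsample rather
#' than freezing the full-sample catalog). Relative paths are resolved
#' against the config file's directory.
#'
#' @param path Path to the YAML config.
#' @return Config list with defaults filled in.
#' @export
read_survey_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("alignment", "samples", "genes", "effect", "pathogenic", "outdir")) {
    if (!is.null(cfg[[k]]) && !grepl("^(/|[A-Za-z]:)", cfg[[k]]))
      cfg[[k]] <- file.path(base, cfg[[k]])
  }
  survey_config(cfg)
}

#' @rdname read_survey_config
#' @param cfg A named list of config values (paths already absolute or
#'   relative to the working directory).
#' @export
survey_config <- function(cfg) {
  defaults <- list(seed = 1L, mc_reps = 1000L, mc_size = NULL,
                   pi_boot = 1000L, pi_max_genomes = 60L,
                   minor_definition = "pooled", subsample_recall = TRUE,
                   effect = NULL, pathogenic = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("alignment", "samples", "genes", "outdir"))
    if (is.null(cfg[[k]])) stop("config key '", k, "' is required")
  if (!cfg$minor_definition %in% c("pooled", "population"))
    stop("minor_definition must be 'pooled' or 'population'")
  cfg
}

fmt_num <- function(x) formatC(x, digits = 10, format = "g")

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Category percentages with the survey's denominators
#'
#' Percentages follow the structure of the survey's variable-site table:
#' synonymous and nonsynonymous are percentages of their sum; four-fold of
#' synonymous; benign/damaging/unknown of nonsynonymous. Reported at one
#' decimal; a zero denominator gives `NA` with a warning.
#'
#' @param counts Named numeric vector of per-category site counts (names from
#'   `synonymous`, `fourfold`, `nonsynonymous`, `unknown`, `benign`,
#'   `damaging`; other names pass through as `NA`).
#' @return Named numeric vector of percentages (one decimal).
#' @export
category_percentages <- function(counts) {
  denom_of <- function(cat) {
    switch(cat,
      synonymous = , nonsynonymous =
        sum(counts[c("synonymous", "nonsynonymous")], na.rm = TRUE),
      fourfold = counts[["synonymous"]],
      unknown = , benign = , damaging = counts[["nonsynonymous"]],
      NA_real_)
  }
  out <- setNames(rep(NA_real_, length(counts)), names(counts))
  for (cat in names(counts)) {
    d <- denom_of(cat)
    if (is.na(d)) next
    if (d == 0) {
      warning("percentage undefined for '", cat, "': zero denominator")
      next
    }
    out[[cat]] <- round(100 * counts[[cat]] / d, 1L)
  }
  out
}

# Per-category distinct-site counts. Under the pooled definition a site is
# variable in a population when >=1 pooled minor allele of the category has
# count >=1 there; under the population definition minors are re-called
# within the population.
category_site_counts <- function(catalog, populations, genomes = NULL,
                                 models = NULL, effect = NULL,
                                 catalogue = NULL,
                                 minor_definition = "pooled",
                                 code = genetic_code()) {
  cats <- vapply(TABLE_ROWS, `[`, "", 2L)
  per_pop_catalogs <- NULL
  if (minor_definition == "population") {
    if (is.null(genomes) || is.null(models))
      stop("population minor definition needs genomes and gene models")
    per_pop_catalogs <- lapply(populations, function(p) {
      sub <- restrict_samples(genomes, population_rows(genomes, p),
                              drop_population = TRUE)
      build_variant_catalog(sub, models, effect, catalogue, code)
    })
    names(per_pop_catalogs) <- populations
  }
  res <- lapply(cats, function(cat) {
    rows <- category_rows(catalog, cat)
    total <- length(unique(catalog$pos0[rows]))
    per_pop <- vapply(populations, function(p) {
      if (minor_definition == "pooled") {
        seg <- rows & pop_col(catalog, "count", p) >= 1L
        length(unique(catalog$pos0[seg]))
      } else {
        pc <- per_pop_catalogs[[p]]
        length(unique(pc$pos0[category_rows(pc, cat)]))
      }
    }, 0L)
    allele_obs <- vapply(populations, function(p)
      sum(pop_col(catalog, "count", p)[rows]), 0)
    c(total = total, setNames(per_pop, paste0("sites_", sanitize_label(populations))),
      setNames(allele_obs, paste0("alleles_", sanitize_label(populations))))
  })
  mat <- do.call(rbind, res)
  rownames(mat) <- cats
  mat
}

build_table1 <- function(catalog, populations, ...) {
  mat <- category_site_counts(catalog, populations, ...)
  cats <- rownames(mat)
  sp <- sanitize_label(populations)
  # undefined percentages (empty denominator groups) are expected on sparse
  # inputs; surface them as log messages rather than warnings
  quiet_pct <- function(counts) withCallingHandlers(
    category_percentages(counts),
    warning = function(w) {
      message(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  pct_tot <- quiet_pct(setNames(mat[, "total"], cats))
  pct_p1 <- quiet_pct(setNames(mat[, paste0("sites_", sp[1L])], cats))
  pct_p2 <- quiet_pct(setNames(mat[, paste0("sites_", sp[2L])], cats))
  df <- data.frame(
    category = vapply(TABLE_ROWS, `[`, "", 1L),
    sites_total = mat[, "total"],
    pct_total = unname(pct_tot),
    stringsAsFactors = FALSE, check.names = FALSE)
  df[[paste0("sites_", sp[1L])]] <- mat[, paste0("sites_", sp[1L])]
  df[[paste0("pct_", sp[1L])]] <- unname(pct_p1)
  df[[paste0("sites_", sp[2L])]] <- mat[, paste0("sites_", sp[2L])]
  df[[paste0("pct_", sp[2L])]] <- unname(pct_p2)
  df[[paste0("minor_alleles_", sp[1L])]] <- mat[, paste0("alleles_", sp[1L])]
  df[[paste0("minor_alleles_", sp[2L])]] <- mat[, paste0("alleles_", sp[2L])]
  rownames(df) <- NULL
  df
}

build_table3 <- function(catalog, populations, mc) {
  sp <- sanitize_label(populations)
  rows <- lapply(TABLE_ROWS, function(tr) {
    cat <- tr[2L]
    m1 <- mean_minor_allele_frequency(catalog, cat, populations[1L])
    m2 <- mean_minor_allele_frequency(catalog, cat, populations[2L])
    mc_mean <- if (!is.null(mc)) unname(mc$mean[cat]) else NA_real_
    mc_se <- if (!is.null(mc)) unname(mc$se[cat]) else NA_real_
    # observational unit: per-allele frequencies in the reference population
    # against per-replicate subsample means
    p <- NA_real_
    if (!is.null(mc) && m1[["k"]] >= 1) {
      f1 <- pop_col(catalog, "freq", populations[1L])
      sel <- category_rows(catalog, cat) &
        pop_col(catalog, "count", populations[1L]) >= 1L
      reps <- mc$replicates[, cat]
      reps <- reps[!is.na(reps)]
      if (length(reps) > 1L)
        p <- mann_whitney_u(f1[sel], reps)$p_value
    }
    data.frame(category = tr[1L],
               mean_1 = m1[["mean"]], se_1 = m1[["se"]], k_1 = m1[["k"]],
               mean_2 = m2[["mean"]], se_2 = m2[["se"]], k_2 = m2[["k"]],
               mc_mean = mc_mean, mc_se_reps = mc_se, u_test_p = p)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("category",
                 paste0(c("maf_", "se_", "n_alleles_"), sp[1L]),
                 paste0(c("maf_", "se_", "n_alleles_"), sp[2L]),
                 paste0("maf_mc_", sp[2L]), "se_mc_reps", "u_test_p")
  df
}

build_table4 <- function(catalog, genomes, populations) {
  sp <- sanitize_label(populations)
  rows <- lapply(TABLE_ROWS, function(tr) {
    cat <- tr[2L]
    b1 <- per_genome_burden(catalog, genomes, cat, populations[1L])
    b2 <- per_genome_burden(catalog, genomes, cat, populations[2L])
    p <- if (length(b1$counts) && length(b2$counts))
      mann_whitney_u(b1$counts, b2$counts)$p_value else NA_real_
    data.frame(category = tr[1L],
               mean_1 = b1$mean, se_1 = b1$se,
               mean_2 = b2$mean, se_2 = b2$se, u_test_p = p)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("category", paste0(c("burden_", "se_"), sp[1L]),
                 paste0(c("burden_", "se_"), sp[2L]), "u_test_p")
  df
}

build_ratios <- function(table3, table4, populations) {
  sp <- sanitize_label(populations)
  n <- nrow(table4)
  safe_ratio <- function(m1, s1, m2, s2) {
    if (is.na(m2) || m2 == 0 || is.na(m1)) return(c(ratio = NA_real_, se = NA_real_))
    category_ratio(c(mean = m1, se = s1), c(mean = m2, se = s2))
  }
  burden <- t(vapply(seq_len(n), function(i)
    safe_ratio(table4[[paste0("burden_", sp[2L])]][i],
               table4[[paste0("se_", sp[2L])]][i],
               table4[[paste0("burden_", sp[1L])]][i],
               table4[[paste0("se_", sp[1L])]][i]),
    c(ratio = 0, se = 0)))
  freq <- t(vapply(seq_len(n), function(i)
    safe_ratio(table3[[paste0("maf_mc_", sp[2L])]][i],
               table3[["se_mc_reps"]][i],
               table3[[paste0("maf_", sp[1L])]][i],
               table3[[paste0("se_", sp[1L])]][i]),
    c(ratio = 0, se = 0)))
  data.frame(category = table4$category,
             burden_ratio = burden[, "ratio"], burden_ratio_se = burden[, "se"],
             freq_ratio_mc = freq[, "ratio"], freq_ratio_mc_se = freq[, "se"])
}

build_table2 <- function(genomes, models, populations, cfg, code) {
  classes <- c("all", "syn", "fourfold", "nonsyn")
  sp <- sanitize_label(populations)
  rows <- lapply(classes, function(cl) {
    ests <- lapply(seq_along(populations), function(k)
      nucleotide_diversity(genomes, models, class = cl,
                           population = populations[k],
                           n_boot = cfg$pi_boot,
                           seed = cfg$seed + 100L + k,
                           max_genomes = cfg$pi_max_genomes, code = code))
    data.frame(class = cl,
               pi_1 = ests[[1L]]$pi, se_1 = ests[[1L]]$se,
               n_1 = ests[[1L]]$n_genomes,
               pi_2 = ests[[2L]]$pi, se_2 = ests[[2L]]$se,
               n_2 = ests[[2L]]$n_genomes)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("class", paste0(c("pi_", "se_", "n_genomes_"), sp[1L]),
                 paste0(c("pi_", "se_", "n_genomes_"), sp[2L]))
  df
}

#' Run the full polymorphism survey
#'
#' End-to-end orchestration from a single configuration: read and
#' cross-validate all inputs, build the minor-allele catalog, and emit the
#' report tables — `table1_sites.tsv` (variable-site and minor-allele counts
#' with percentages), `table2_pi.tsv` (nucleotide diversity by site class),
#' `table3_maf.tsv` (mean minor-allele frequencies including the Monte-Carlo
#' equal-sample-size column), `table4_burden.tsv` (per-genome burdens),
#' `ratios.tsv` (between-population ratio summaries), the full
#' `variant_catalog.tsv` dump and a `run_log.txt` recording every switch and
#' data-quality message. Deterministic for a fixed config and seed.
#'
#' @param config A config list (see [survey_config()]) or path to a YAML
#'   file.
#' @param code Genetic code.
#' @return Invisibly, a list with all tables, the catalog, the
#'   `ResamplingResult` of the Monte-Carlo column, and output paths.
#' @export
run_survey <- function(config, code = genetic_code()) {
  cfg <- if (is.character(config)) read_survey_config(config)
         else survey_config(config)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  collect <- function(expr) withCallingHandlers(expr, message = function(m) {
    log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
    invokeRestart("muffleMessage")
  })

  stage <- "read sample metadata"
  result <- tryCatch({
    pop_map <- collect(read_sample_metadata(cfg$samples))
    stage <- "read alignment"
    genomes <- collect(read_alignment(cfg$alignment, population = pop_map))
    extra <- setdiff(names(pop_map), genomes$sample_ids)
    if (length(extra))
      stop("metadata samples absent from alignment: ",
           paste(extra, collapse = ", "))
    stage <- "read gene models"
    models <- collect(read_gene_models(cfg$genes))
    if (any(models$end > alignment_length(genomes)))
      stop("gene model extends beyond alignment")
    L <- alignment_length(genomes)
    stage <- "read effect annotation"
    effect <- if (!is.null(cfg$effect))
      collect(read_effect_annotation(cfg$effect, L)) else NULL
    stage <- "read pathogenic catalogue"
    catalogue <- if (!is.null(cfg$pathogenic))
      collect(read_pathogenic_catalogue(cfg$pathogenic, L)) else NULL
    stage <- "build variant catalog"
    catalog <- collect(build_variant_catalog(genomes, models, effect,
                                             catalogue, code))
    pops <- population_labels(genomes)     # smaller first
    n_small <- length(population_rows(genomes, pops[1L]))
    n_big <- length(population_rows(genomes, pops[2L]))
    note(sprintf("populations: %s (n=%d, reference) vs %s (n=%d)",
                 pops[1L], n_small, pops[2L], n_big))
    note(sprintf("polymorphic sites: %d; minor alleles: %d",
                 length(unique(catalog$pos0)), nrow(catalog)))
    note(sprintf("switches: minor_definition=%s subsample_recall=%s seed=%d",
                 cfg$minor_definition, cfg$subsample_recall, cfg$seed))
    n_unknown_codon <- sum(catalog$category == "unknown-codon")
    if (n_unknown_codon)
      note(sprintf("%d minor allele(s) with unresolved background codon excluded from syn/nonsyn tallies",
                   n_unknown_codon))

    mc_size <- cfg$mc_size %||% n_small
    if (mc_size > n_big)
      stop("mc_size exceeds the larger population")
    note(sprintf("Monte-Carlo: %d replicates of %d genomes from %s",
                 cfg$mc_reps, mc_size, pops[2L]))

    stage <- "Monte-Carlo subsampling"
    mc <- NULL
    if (nrow(catalog) && cfg$mc_reps > 0L) {
      site_pos0 <- sort(unique(catalog$pos0))
      bg <- major_background(genomes)
      masks <- site_category_masks(site_pos0, models, bg, effect, catalogue,
                                   code)
      if (cfg$subsample_recall) {
        mc <- mc_category_maf(genomes, pops[2L], mc_size,
                              n_reps = cfg$mc_reps, seed = cfg$seed + 20L,
                              site_pos0 = site_pos0,
                              site_categories = masks)
      } else {
        mc <- mc_frozen_maf(genomes, catalog, pops[2L], mc_size,
                            n_reps = cfg$mc_reps, seed = cfg$seed + 20L)
      }
    }

    stage <- "summaries"
    table1 <- collect(build_table1(catalog, pops, genomes = genomes,
                                   models = models, effect = effect,
                                   catalogue = catalogue,
                                   minor_definition = cfg$minor_definition,
                                   code = code))
    table3 <- build_table3(catalog, pops, mc)
    table4 <- build_table4(catalog, genomes, pops)
    ratios <- build_ratios(table3, table4, pops)
    stage <- "nucleotide diversity"
    table2 <- build_table2(genomes, models, pops, cfg, code)

    stage <- "write outputs"
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(table1 = file.path(cfg$outdir, "table1_sites.tsv"),
               table2 = file.path(cfg$outdir, "table2_pi.tsv"),
               table3 = file.path(cfg$outdir, "table3_maf.tsv"),
               table4 = file.path(cfg$outdir, "table4_burden.tsv"),
               ratios = file.path(cfg$outdir, "ratios.tsv"),
               catalog = file.path(cfg$outdir, "variant_catalog.tsv"),
               log = file.path(cfg$outdir, "run_log.txt"))
    write_tsv(table1, paths[["table1"]])
    write_tsv(table2, paths[["table2"]])
    write_tsv(table3, paths[["table3"]])
    write_tsv(table4, paths[["table4"]])
    write_tsv(ratios, paths[["ratios"]])
    write_variant_catalog(catalog, paths[["catalog"]])
    writeLines(log_lines, paths[["log"]])
    list(config = cfg, populations = pops, catalog = catalog, mc = mc,
         table1 = table1, table2 = table2, table3 = table3, table4 = table4,
         ratios = ratios, paths = paths, log = log_lines)
  }, error = function(e) {
    stop("survey failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# Frozen-catalog Monte-Carlo column: the minor-allele set is fixed at the
# pooled full-sample catalog; each replicate averages the within-subsample
# frequencies of the catalog alleles that segregate in the subsample.
mc_frozen_maf <- function(genomes, catalog, population, subsample_size,
                          n_reps = 1000L, seed = 1L) {
  rows <- population_rows(genomes, population)
  M <- genomes$seq[rows, catalog$pos0 + 1L, drop = FALSE]
  tgt <- matrix(base_to_int(catalog$base), nrow = length(rows),
                ncol = nrow(catalog), byrow = TRUE)
  hit <- M == tgt
  called <- M <= 4L
  cats <- SUMMARY_CATEGORIES
  sel_by_cat <- lapply(cats, function(cat) category_rows(catalog, cat))
  names(sel_by_cat) <- cats
  reps <- with_preserved_seed(seed, {
    out <- matrix(NA_real_, n_reps, length(cats), dimnames = list(NULL, cats))
    for (r in seq_len(n_reps)) {
      sub <- sample.int(length(rows), subsample_size)
      cnt <- colSums(hit[sub, , drop = FALSE])
      ne <- colSums(called[sub, , drop = FALSE])
      f <- ifelse(ne > 0L, cnt / ne, 0)
      seg <- cnt >= 1L
      for (ci in seq_along(cats)) {
        s <- seg & sel_by_cat[[ci]]
        if (any(s)) out[r, ci] <- mean(f[s])
      }
    }
    out
  })
  res <- list(statistic = "category mean minor-allele frequency (frozen catalog)",
              replicates = reps, subsample_size = subsample_size,
              n_reps = n_reps, seed = seed,
              mean = colMeans(reps, na.rm = TRUE),
              se = apply(reps, 2L, function(v) {
                v <- v[!is.na(v)]
                if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
              }),
              n_empty = colSums(is.na(reps)))
  class(res) <- "ResamplingResult"
  res
}

#' Regenerate report tables from a dumped variant catalog
#'
#' The reporting layer is a pure function of the catalog: the variable-site
#' table and the full-sample frequency columns of the frequency table can be
#' regenerated from `variant_catalog.tsv` alone and equal a direct run's
#' output (burden, diversity and Monte-Carlo columns additionally need the
#' alignment).
#'
#' @param catalog A variant catalog data.frame (e.g. from
#'   [read_variant_catalog()]).
#' @param populations The two population labels, smaller first. Sanitised
#'   labels (as in the dump's column names) are accepted.
#' @return A list with `table1` and `table3_full` (frequency table without
#'   Monte-Carlo and U-test columns).
#' @export
tables_from_catalog <- function(catalog, populations) {
  t1 <- build_table1(catalog, populations, minor_definition = "pooled")
  t3 <- build_table3(catalog, populations, mc = NULL)
  t3 <- t3[, setdiff(names(t3), c(paste0("maf_mc_", sanitize_label(populations)[2L]),
                                  "se_mc_reps", "u_test_p"))]
  list(table1 = t1, table3_full = t3)
}
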