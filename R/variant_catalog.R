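CATEGORY_LEVELS <- c("synonymous", "nonsynonymous", "tRNA", "rRNA",
                     "other-noncoding", "unknown-codon")

sanitize_label <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

# Pooled and per-population base counts for every alignment column.
# Returns 4 x L matrices (rows A,C,G,T) plus per-column missing counts.
column_base_counts <- function(x, rows = seq_len(n_genomes(x))) {
  m <- x$seq[rows, , drop = FALSE]
  counts <- matrix(0L, nrow = 4L, ncol = ncol(m),
                   dimnames = list(BASES[1:4], NULL))
  for (b in 1:4) counts[b, ] <- colSums(m == b)
  missing <- length(rows) - colSums(counts)
  list(counts = counts, missing = as.integer(missing))
}

# Pooled major allele for every column (ties broken alphabetically A<C<G<T);
# NA where a column has no called base.
major_alleles <- function(counts) {
  maj <- max.col(t(counts), ties.method = "first")
  maj[colSums(counts) == 0L] <- NA_integer_
  maj
}

#' Identify polymorphic sites in an alignment
#'
#' A polymorphic site is an alignment column at which more than one nucleotide
#' allele is found among the called (non-gap, non-`N`) bases; gaps and `N` are
#' excluded from allele sets and from frequency denominators. The major allele
#' is the most frequent pooled allele, ties broken alphabetically (`A<C<G<T`).
#'
#' @param genomes An `AlignedGenomeSet` (population labels required for the
#'   per-population counts; sets without labels yield pooled counts only).
#' @return An object of class `site_variants`: a list with `pos0` (0-based
#'   polymorphic columns), `counts` (4 x K pooled base counts), `missing`,
#'   `n_eff`, `major` (integer base codes), and, when populations are
#'   labelled, per-population `pop_counts` / `pop_missing`.
#' @export
find_polymorphic_sites <- function(genomes) {
  pooled <- column_base_counts(genomes)
  n_alleles <- colSums(pooled$counts > 0L)
  keep <- which(n_alleles >= 2L)
  counts <- pooled$counts[, keep, drop = FALSE]
  out <- list(pos0 = keep - 1L,
              counts = counts,
              missing = pooled$missing[keep],
              n_eff = colSums(counts),
              major = major_alleles(counts),
              n_genomes = n_genomes(genomes))
  if (!is.null(genomes$population)) {
    pops <- population_labels(genomes)
    out$populations <- pops
    out$pop_counts <- lapply(pops, function(p) {
      rows <- population_rows(genomes, p)
      cc <- matrix(0L, nrow = 4L, ncol = length(keep),
                   dimnames = list(BASES[1:4], NULL))
      sub <- genomes$seq[rows, keep, drop = FALSE]
      for (b in 1:4) cc[b, ] <- colSums(sub == b)
      cc
    })
    names(out$pop_counts) <- pops
    out$pop_n <- vapply(pops, function(p) length(population_rows(genomes, p)), 0L)
    out$pop_missing <- lapply(pops, function(p) {
      out$pop_n[[p]] - colSums(out$pop_counts[[p]])
    })
    names(out$pop_missing) <- pops
  }
  class(out) <- "site_variants"
  out
}

#' @export
print.site_variants <- function(x, ...) {
  cat(sprintf("site_variants: %d polymorphic columns (of %d genomes)\n",
              length(x$pos0), x$n_genomes))
  invisible(x)
}

#' Call minor alleles at polymorphic sites
#'
#' Every observed allele except the single (pooled) major allele is a minor
#' allele; multi-allelic sites yield several. Pooled frequency denominators
#' are the number of called genomes at the site.
#'
#' @param sites A `site_variants` object from [find_polymorphic_sites()].
#' @return A data.frame with one row per minor allele: `pos0`, `base`,
#'   `major`, `count_pooled`, `n_eff`, `freq_pooled`, `n_missing` and, when
#'   population labels are present, `count_<pop>`, `n_eff_<pop>` and
#'   `freq_<pop>` columns (labels sanitised to `[A-Za-z0-9_]`).
#' @export
call_minor_alleles <- function(sites) {
  stopifnot(inherits(sites, "site_variants"))
  K <- length(sites$pos0)
  present <- sites$counts > 0L
  if (K) present[cbind(sites$major, seq_len(K))] <- FALSE
  idx <- which(present, arr.ind = TRUE)      # rows: (base, site)
  site_i <- idx[, 2L]
  base_i <- idx[, 1L]
  out <- data.frame(
    pos0 = sites$pos0[site_i],
    base = BASES[base_i],
    major = BASES[sites$major[site_i]],
    count_pooled = sites$counts[idx],
    n_eff = sites$n_eff[site_i],
    n_missing = sites$missing[site_i],
    stringsAsFactors = FALSE)
  out$freq_pooled <- out$count_pooled / out$n_eff
  if (!is.null(sites$populations)) {
    for (p in sites$populations) {
      sp <- sanitize_label(p)
      cc <- sites$pop_counts[[p]][idx]
      ne <- (sites$pop_n[[p]] - sites$pop_missing[[p]])[site_i]
      out[[paste0("count_", sp)]] <- cc
      out[[paste0("n_eff_", sp)]] <- ne
      out[[paste0("freq_", sp)]] <- ifelse(ne > 0L, cc / ne, 0)
    }
    attr(out, "populations") <- sites$populations
  }
  o <- order(out$pos0, out$base)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_genomes") <- sites$n_genomes
  out
}

#' Pooled major-allele background of an alignment
#'
#' @param genomes An `AlignedGenomeSet`.
#' @return Integer vector of length `alignment_length(genomes)` with the
#'   pooled major base code at every column (ties alphabetical; `NA` where no
#'   genome has a called base). Used as the background for codon-level
#'   classification.
#' @export
major_background <- function(genomes) {
  pooled <- column_base_counts(genomes)
  major_alleles(pooled$counts)
}

#' Classify alleles by functional category
#'
#' For alleles inside a protein gene the alternate base is substituted into
#' the major-allele background codon (strand-aware: the base is complemented
#' for minus-strand genes) and the translations compared, giving
#' `synonymous` or `nonsynonymous`; synonymous alleles at four-fold degenerate
#' positions are additionally flagged. Alleles in tRNA/rRNA features take that
#' compartment; everything else is `other-noncoding`. Codons whose background
#' contains a gap/`N` (or a stop codon) give `unknown-codon`, which is
#' excluded from synonymous/nonsynonymous tallies. Positions inside two
#' overlapping protein genes are classified against each gene and counted
#' once with a nonsynonymous-if-any rule.
#'
#' @param pos0 Integer vector of 0-based alignment columns.
#' @param base Character vector of alternate bases (`A/C/G/T`), parallel to
#'   `pos0`.
#' @param models A `gene_models` table.
#' @param background Integer base-code vector from [major_background()].
#' @param code Genetic code (used for genes with `code_id` matching its id;
#'   all genes are translated with this code).
#' @return A data.frame with columns `category`, `fourfold` (logical) and
#'   `compartment` (`coding`/`tRNA`/`rRNA`/`noncoding`), one row per input
#'   allele.
#' @export
classify_effect <- function(pos0, base, models, background,
                            code = genetic_code()) {
  n <- length(pos0)
  stopifnot(length(base) == n)
  base_i <- base_to_int(toupper(base))
  if (any(base_i > 4L)) stop("alternate base must be one of A/C/G/T")
  category <- rep(NA_character_, n)
  fourfold <- rep(FALSE, n)
  compartment <- rep("noncoding", n)
  syn_seen <- rep(FALSE, n)
  nonsyn_seen <- rep(FALSE, n)
  unknown_seen <- rep(FALSE, n)
  comp_base <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G

  tabs <- ng_site_table(code)
  prot <- models[models$feature == "protein", , drop = FALSE]
  for (g in seq_len(nrow(prot))) {
    st <- prot$start0[g]; en <- prot$end0[g]
    n_codon <- (en - st) %/% 3L
    inside <- which(pos0 >= st & pos0 < en)
    if (!length(inside)) next
    if (prot$strand[g] == "+") {
      r <- pos0[inside] - st
    } else {
      r <- (en - 1L) - pos0[inside]
    }
    ci <- r %/% 3L
    within <- r %% 3L                       # 0-based position in codon
    full <- ci < n_codon                    # drop trailing partial codon
    inside <- inside[full]; ci <- ci[full]; within <- within[full]
    if (!length(inside)) next
    compartment[inside] <- "coding"
    # genomic columns of the codon in coding order
    if (prot$strand[g] == "+") {
      p1 <- st + ci * 3L
      cod_cols <- cbind(p1, p1 + 1L, p1 + 2L) + 1L
      b1 <- background[cod_cols[, 1L]]
      b2 <- background[cod_cols[, 2L]]
      b3 <- background[cod_cols[, 3L]]
      alt <- base_i[inside]
    } else {
      p1 <- (en - 1L) - ci * 3L
      cod_cols <- cbind(p1, p1 - 1L, p1 - 2L) + 1L
      b1 <- comp_base[background[cod_cols[, 1L]]]
      b2 <- comp_base[background[cod_cols[, 2L]]]
      b3 <- comp_base[background[cod_cols[, 3L]]]
      alt <- comp_base[base_i[inside]]
    }
    unresolved <- is.na(b1) | is.na(b2) | is.na(b3) |
      b1 > 4L | b2 > 4L | b3 > 4L
    bg_idx <- rep(NA_integer_, length(inside))
    bg_idx[!unresolved] <- codon_index(b1[!unresolved], b2[!unresolved],
                                       b3[!unresolved])
    bg_stop <- !is.na(bg_idx) & code[bg_idx] == "*"
    unknown_seen[inside[unresolved | bg_stop]] <- TRUE
    ok <- which(!unresolved & !bg_stop)
    if (length(ok)) {
      io <- inside[ok]
      bmat <- cbind(b1, b2, b3)[ok, , drop = FALSE]
      wo <- within[ok]
      alt_o <- alt[ok]
      mut <- bmat
      mut[cbind(seq_along(io), wo + 1L)] <- alt_o
      mut_idx <- codon_index(mut[, 1L], mut[, 2L], mut[, 3L])
      aa_bg <- code[bg_idx[ok]]
      aa_mut <- code[mut_idx]
      syn <- aa_bg == aa_mut
      syn_seen[io[syn]] <- TRUE
      nonsyn_seen[io[!syn]] <- TRUE
      is4 <- tabs$deg[cbind(bg_idx[ok], wo + 1L)] == 4L
      fourfold[io[syn & is4]] <- TRUE
    }
  }
  n_overlap_nonsyn <- sum(nonsyn_seen & syn_seen)
  if (n_overlap_nonsyn)
    message(n_overlap_nonsyn,
            " allele(s) in overlapping genes classified nonsynonymous-if-any")
  category[nonsyn_seen] <- "nonsynonymous"
  category[!nonsyn_seen & syn_seen] <- "synonymous"
  category[is.na(category) & unknown_seen] <- "unknown-codon"
  fourfold[category != "synonymous" | is.na(category)] <- FALSE

  for (feat in c("tRNA", "rRNA")) {
    fm <- models[models$feature == feat, , drop = FALSE]
    for (g in seq_len(nrow(fm))) {
      inside <- which(pos0 >= fm$start0[g] & pos0 < fm$end0[g])
      hit <- inside[compartment[inside] == "noncoding"]
      compartment[hit] <- feat
      category[hit[is.na(category[hit])]] <- feat
    }
  }
  category[is.na(category)] <- "other-noncoding"
  data.frame(category = category, fourfold = fourfold,
             compartment = compartment, stringsAsFactors = FALSE)
}

#' Attach effect and pathogenic annotations to minor alleles
#'
#' Nonsynonymous minor alleles receive their effect class from the annotation
#' table (`benign`/`damaging`; alleles absent from the annotation get
#' `unknown`); all other categories get `n/a`. Any minor allele matching a
#' Reported/Confirmed catalogue entry is flagged pathogenic — a cross-cutting
#' flag that does not change the allele's category — with its compartment
#' taken from the gene models. Annotation rows that do not correspond to a
#' detected minor allele are reported and ignored.
#'
#' @param minors A classified minor-allele data.frame (with `category`
#'   columns, see [build_variant_catalog()]).
#' @param effect An `effect_annotation` data.frame (or `NULL`).
#' @param catalogue A `pathogenic_catalogue` data.frame (or `NULL`).
#' @return `minors` with `effect` and `pathogenic` columns filled in.
#' @export
attach_annotations <- function(minors, effect = NULL, catalogue = NULL) {
  key <- paste(minors$pos0, minors$base)
  minors$effect <- ifelse(minors$category == "nonsynonymous", "unknown", "n/a")
  if (!is.null(effect) && nrow(effect)) {
    ekey <- paste(effect$pos0, effect$base)
    hit <- match(key, ekey)
    use <- !is.na(hit) & minors$category == "nonsynonymous"
    minors$effect[use] <- effect$label[hit[use]]
    unmatched <- sum(!(ekey %in% key))
    if (unmatched)
      message(unmatched, " effect annotation(s) without a matching minor allele ignored")
  }
  minors$pathogenic <- rep(FALSE, nrow(minors))
  if (!is.null(catalogue) && nrow(catalogue)) {
    ckey <- paste(catalogue$pos0, catalogue$base)
    minors$pathogenic <- key %in% ckey
    unmatched <- sum(!(ckey %in% key))
    if (unmatched)
      message(unmatched, " pathogenic catalogue entr",
              if (unmatched == 1L) "y" else "ies",
              " without a matching minor allele ignored")
  }
  minors
}

#' Build the full minor-allele catalog
#'
#' Runs polymorphic-site detection, minor-allele calling, functional
#' classification against the pooled major-allele background, and annotation
#' attachment in one step.
#'
#' @param genomes An `AlignedGenomeSet` with two labelled populations.
#' @param models A `gene_models` table.
#' @param effect Optional `effect_annotation`.
#' @param catalogue Optional `pathogenic_catalogue`.
#' @param code Genetic code.
#' @return A data.frame (the "variant catalog"): one row per minor allele with
#'   position, base, category, `fourfold`, `effect`, `pathogenic`,
#'   `compartment`, and pooled plus per-population counts and frequencies.
#' @export
build_variant_catalog <- function(genomes, models, effect = NULL,
                                  catalogue = NULL, code = genetic_code()) {
  sites <- find_polymorphic_sites(genomes)
  minors <- call_minor_alleles(sites)
  bg <- major_background(genomes)
  cls <- classify_effect(minors$pos0, minors$base, models, bg, code)
  minors <- cbind(minors, cls)
  minors <- attach_annotations(minors, effect, catalogue)
  attr(minors, "populations") <- sites$populations
  attr(minors, "n_genomes") <- sites$n_genomes
  minors
}

#' Write / read a variant catalog TSV
#'
#' The dump has one row per minor allele with 1-based positions; reading it
#' back restores the catalog (the reporting layer can be re-run from the
#' dump alone).
#'
#' @param catalog A variant catalog from [build_variant_catalog()].
#' @param path File path.
#' @return `path` (write) or the catalog data.frame (read).
#' @export
write_variant_catalog <- function(catalog, path) {
  out <- catalog
  out$position <- out$pos0 + 1L
  out$pos0 <- NULL
  out <- out[, c("position", setdiff(names(out), "position"))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_catalog
#' @param populations Optional character vector of the two population labels
#'   (in ascending size order); inferred from `freq_*` column names when
#'   omitted.
#' @export
read_variant_catalog <- function(path, populations = NULL) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c(base = "character", major = "character"))
  df$pos0 <- df$position - 1L
  df$position <- NULL
  if (is.null(populations)) {
    populations <- sub("^freq_", "", grep("^freq_", names(df), value = TRUE))
    populations <- setdiff(populations, "pooled")
  }
  attr(df, "populations") <- populations
  df
}
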