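# Summary categories reported by the survey. Each is a row selector over the
# variant catalog; "synonymous" includes its four-fold subset, effect classes
# are subsets of "nonsynonymous", and "pathogenic*" is the cross-cutting
# catalogue flag (subdivided by compartment).
SUMMARY_CATEGORIES <- c("synonymous", "fourfold", "nonsynonymous",
                        "unknown", "benign", "damaging",
                        "tRNA", "rRNA", "other-noncoding",
                        "pathogenic", "pathogenic_coding",
                        "pathogenic_tRNA", "pathogenic_rRNA")

#' Select catalog rows belonging to a summary category
#'
#' @param catalog A variant catalog (see [build_variant_catalog()]).
#' @param category One of `r paste(SUMMARY_CATEGORIES, collapse = ", ")`.
#' @return Logical vector over the catalog rows.
#' @export
category_rows <- function(catalog, category) {
  switch(category,
    synonymous = catalog$category == "synonymous",
    fourfold = catalog$category == "synonymous" & catalog$fourfold,
    nonsynonymous = catalog$category == "nonsynonymous",
    unknown = catalog$category == "nonsynonymous" & catalog$effect == "unknown",
    benign = catalog$category == "nonsynonymous" & catalog$effect == "benign",
    damaging = catalog$category == "nonsynonymous" & catalog$effect == "damaging",
    tRNA = catalog$category == "tRNA",
    rRNA = catalog$category == "rRNA",
    `other-noncoding` = catalog$category == "other-noncoding",
    pathogenic = catalog$pathogenic,
    pathogenic_coding = catalog$pathogenic & catalog$compartment == "coding",
    pathogenic_tRNA = catalog$pathogenic & catalog$compartment == "tRNA",
    pathogenic_rRNA = catalog$pathogenic & catalog$compartment == "rRNA",
    stop("unknown summary category: ", category))
}

pop_col <- function(catalog, what, population) {
  col <- paste0(what, "_", sanitize_label(population))
  if (!col %in% names(catalog))
    stop("catalog has no column for population '", population, "'")
  catalog[[col]]
}

#' Mean minor-allele frequency of a category in a population
#'
#' Unweighted mean, over the minor alleles of the category that segregate in
#' the population (within-population count >= 1), of their within-population
#' frequency; the standard error is the sample SD over those k alleles
#' divided by sqrt(k) (0 when k = 1). An empty category is flagged absent
#' (`NA`), not zero.
#'
#' @param catalog A variant catalog.
#' @param category Summary category (see [category_rows()]).
#' @param population Population label.
#' @return Named numeric vector `c(mean, se, k)`.
#' @export
mean_minor_allele_frequency <- function(catalog, category, population) {
  sel <- category_rows(catalog, category) &
    pop_col(catalog, "count", population) >= 1L
  f <- pop_col(catalog, "freq", population)[sel]
  k <- length(f)
  if (!k) return(c(mean = NA_real_, se = NA_real_, k = 0))
  se <- if (k > 1L) stats::sd(f) / sqrt(k) else 0
  c(mean = mean(f), se = se, k = k)
}

#' Per-genome minor-allele burden
#'
#' For each genome of a population, the number of catalogued minor alleles of
#' a category it carries (a genome with a gap/`N` at a site is not a carrier
#' there). The sum of the per-genome counts equals the sum of the alleles'
#' within-population counts (conservation).
#'
#' @param catalog A variant catalog.
#' @param genomes The `AlignedGenomeSet` the catalog was built from.
#' @param category Summary category.
#' @param population Population label.
#' @return A list with `counts` (named integer vector, one per genome),
#'   `mean` and `se` (SEM across genomes).
#' @export
per_genome_burden <- function(catalog, genomes, category, population) {
  rows <- population_rows(genomes, population)
  sel <- which(category_rows(catalog, category) &
                 pop_col(catalog, "count", population) >= 1L)
  counts <- integer(length(rows))
  if (length(sel)) {
    sub <- genomes$seq[rows, catalog$pos0[sel] + 1L, drop = FALSE]
    tgt <- matrix(base_to_int(catalog$base[sel]), nrow = length(rows),
                  ncol = length(sel), byrow = TRUE)
    counts <- as.integer(rowSums(sub == tgt))
  }
  names(counts) <- genomes$sample_ids[rows]
  list(counts = counts, mean = mean(counts),
       se = stats::sd(counts) / sqrt(length(counts)))
}

#' Monte-Carlo subsampling of a population statistic
#'
#' Draws `n_reps` subsamples of `subsample_size` genomes without replacement
#' from a population and recomputes an arbitrary statistic from scratch on
#' each restriction (sites monomorphic within a subsample drop out of any
#' minor-allele statistic). Deterministic for a fixed seed.
#'
#' @param genomes An `AlignedGenomeSet`.
#' @param population Population label to subsample.
#' @param subsample_size Genomes per replicate (must not exceed the
#'   population size; at equality every replicate equals the full-population
#'   statistic).
#' @param n_reps Number of replicates.
#' @param seed Seed; per-replicate draws come from one seeded stream.
#' @param statistic Function taking an `AlignedGenomeSet` restriction (the
#'   subsampled genomes, unlabelled) and returning a numeric scalar or a
#'   fixed-length named numeric vector.
#' @return A list of class `ResamplingResult`: `statistic` (name),
#'   `replicates` (n_reps x d matrix), `subsample_size`, `n_reps`, `seed`,
#'   `mean` and `se` (across replicates, per statistic component).
#' @export
monte_carlo_subsample <- function(genomes, population, subsample_size,
                                  n_reps = 1000L, seed = 1L, statistic) {
  rows <- population_rows(genomes, population)
  if (subsample_size > length(rows))
    stop("subsample_size (", subsample_size, ") exceeds population size (",
         length(rows), ")")
  reps <- with_preserved_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      sub <- restrict_samples(genomes, sort(sample(rows, subsample_size)),
                              drop_population = TRUE)
      statistic(sub)
    })
  })
  mat <- do.call(rbind, reps)
  if (is.null(colnames(mat)) && ncol(mat) == 1L) colnames(mat) <- "statistic"
  res <- list(statistic = deparse(substitute(statistic)),
              replicates = mat,
              subsample_size = subsample_size, n_reps = n_reps, seed = seed,
              mean = colMeans(mat),
              se = apply(mat, 2L, stats::sd) / sqrt(n_reps))
  class(res) <- "ResamplingResult"
  res
}

#' @export
print.ResamplingResult <- function(x, ...) {
  cat(sprintf("ResamplingResult: %d replicates of %d genomes (seed %d)\n",
              x$n_reps, x$subsample_size, x$seed))
  print(data.frame(mean = x$mean, se = x$se))
  invisible(x)
}

#' Monte-Carlo category mean minor-allele frequencies (fast path)
#'
#' The pipeline's Table-3 Monte-Carlo column: per replicate, minor alleles
#' are re-called within the subsample and the per-category mean within-
#' subsample frequency is computed; replicate means are then averaged. This
#' is the same computation as [monte_carlo_subsample()] with a
#' [mean_minor_allele_frequency()]-style statistic, specialised to operate
#' only on the columns that are polymorphic in the pooled data (columns
#' monomorphic overall cannot yield minor alleles in any subsample) with the
#' per-(column, base) category classification fixed at its pooled value.
#'
#' @param genomes An `AlignedGenomeSet`.
#' @param population Population to subsample (the larger one, in the survey).
#' @param subsample_size,n_reps,seed As in [monte_carlo_subsample()].
#' @param site_pos0 0-based columns of the pooled polymorphic sites.
#' @param site_categories A list mapping each summary category name to a
#'   4 x length(site_pos0) logical matrix: whether base b at column j belongs
#'   to the category (from the pooled catalog classification; see
#'   [site_category_masks()]).
#' @return A `ResamplingResult` whose statistic components are the per-
#'   category mean frequencies (NaN replicates, from categories empty in a
#'   subsample, are dropped from the mean with a count recorded).
#' @export
mc_category_maf <- function(genomes, population, subsample_size,
                            n_reps = 1000L, seed = 1L,
                            site_pos0, site_categories) {
  rows <- population_rows(genomes, population)
  if (subsample_size > length(rows))
    stop("subsample_size exceeds population size")
  M <- genomes$seq[rows, site_pos0 + 1L, drop = FALSE]
  K <- ncol(M)
  cats <- names(site_categories)
  reps <- with_preserved_seed(seed, {
    out <- matrix(NA_real_, nrow = n_reps, ncol = length(cats),
                  dimnames = list(NULL, cats))
    for (r in seq_len(n_reps)) {
      sub <- M[sample.int(length(rows), subsample_size), , drop = FALSE]
      counts <- matrix(0L, nrow = 4L, ncol = K)
      for (b in 1:4) counts[b, ] <- colSums(sub == b)
      n_eff <- colSums(counts)
      major <- max.col(t(counts), ties.method = "first")
      minor <- counts > 0L
      minor[cbind(major, seq_len(K))] <- FALSE
      minor[, n_eff == 0L] <- FALSE
      freq <- sweep(counts, 2L, pmax(n_eff, 1L), "/")
      for (ci in seq_along(cats)) {
        sel <- minor & site_categories[[ci]]
        k <- sum(sel)
        out[r, ci] <- if (k) sum(freq[sel]) / k else NA_real_
      }
    }
    out
  })
  res <- list(statistic = "category mean minor-allele frequency",
              replicates = reps,
              subsample_size = subsample_size, n_reps = n_reps, seed = seed,
              mean = colMeans(reps, na.rm = TRUE),
              se = apply(reps, 2L, function(v) {
                v <- v[!is.na(v)]
                if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
              }),
              n_empty = colSums(is.na(reps)))
  class(res) <- "ResamplingResult"
  res
}

#' Per-(column, base) category masks for the Monte-Carlo fast path
#'
#' Classifies all four bases at every pooled polymorphic column against the
#' pooled major-allele background and converts the catalog's annotation state
#' into 4 x K logical masks per summary category. A base equal to the pooled
#' major allele inherits the annotations of... nothing: it is classified
#' afresh (it may become a minor allele within a subsample), but effect and
#' pathogenic states exist only for alleles present in the annotation inputs.
#'
#' @param site_pos0 0-based polymorphic columns.
#' @param models Gene models.
#' @param background Pooled major background (see [major_background()]).
#' @param effect,catalogue Annotation inputs (as read by the io functions).
#' @param code Genetic code.
#' @return Named list of 4 x K logical matrices, one per summary category.
#' @export
site_category_masks <- function(site_pos0, models, background,
                                effect = NULL, catalogue = NULL,
                                code = genetic_code()) {
  K <- length(site_pos0)
  pos_rep <- rep(site_pos0, each = 4L)
  base_rep <- rep(BASES[1:4], K)
  cls <- classify_effect(pos_rep, base_rep, models, background, code)
  eff <- rep("n/a", length(pos_rep))
  eff[cls$category == "nonsynonymous"] <- "unknown"
  if (!is.null(effect) && nrow(effect)) {
    hit <- match(paste(pos_rep, base_rep), paste(effect$pos0, effect$base))
    use <- !is.na(hit) & cls$category == "nonsynonymous"
    eff[use] <- effect$label[hit[use]]
  }
  path <- rep(FALSE, length(pos_rep))
  if (!is.null(catalogue) && nrow(catalogue)) {
    path <- paste(pos_rep, base_rep) %in% paste(catalogue$pos0, catalogue$base)
  }
  fake <- data.frame(category = cls$category, fourfold = cls$fourfold,
                     compartment = cls$compartment, effect = eff,
                     pathogenic = path, stringsAsFactors = FALSE)
  masks <- lapply(SUMMARY_CATEGORIES, function(cat)
    matrix(category_rows(fake, cat), nrow = 4L, ncol = K))
  names(masks) <- SUMMARY_CATEGORIES
  masks
}

#' Mann-Whitney U-test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. With
#' `n1 + n2 <= 12` and no ties the p-value is exact (full enumeration of the
#' U distribution); otherwise the normal approximation with tie correction
#' and continuity correction is used. A comparison with zero rank variance
#' (all values identical) gives p = 1.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact `NULL` (the default policy above), or a logical forcing the
#'   exact / normal-approximation branch (exact with ties is refused by the
#'   underlying machinery and an error).
#' @return A list of class `UTestResult` with `U` (the statistic for `x`),
#'   `p_value`, `method` (`"exact"` or
#'   `"normal-approximation-with-tie-correction"`), and `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (n1 + n2) <= 12L && !ties
  if (exact && ties) stop("exact p-value unavailable with ties")
  if (all(c(x, y) == c(x, y)[1L])) {
    res <- list(U = n1 * n2 / 2, p_value = 1,
                method = "normal-approximation-with-tie-correction",
                n1 = n1, n2 = n2)
    class(res) <- "UTestResult"
    return(res)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  res <- list(U = unname(wt$statistic), p_value = min(p, 1),
              method = if (exact) "exact"
                       else "normal-approximation-with-tie-correction",
              n1 = n1, n2 = n2)
  class(res) <- "UTestResult"
  res
}

#' @export
print.UTestResult <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1=%d, n2=%d), two-sided p = %.3g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Between-population ratio of category summaries
#'
#' Ratio of two category means (conventionally larger-population /
#' smaller-population, i.e. non-African-like over African-like), with the
#' standard error propagated to first order from the two SEs:
#' \eqn{SE(r) = r \sqrt{(s_1/m_1)^2 + (s_2/m_2)^2}}.
#'
#' @param numerator,denominator Numeric vectors `c(mean, se)` (extra elements
#'   ignored).
#' @return Named numeric vector `c(ratio, se)`; `NA` with a warning when the
#'   denominator mean is zero or missing.
#' @export
category_ratio <- function(numerator, denominator) {
  m1 <- numerator[["mean"]]; s1 <- numerator[["se"]]
  m2 <- denominator[["mean"]]; s2 <- denominator[["se"]]
  if (is.na(m2) || m2 == 0) {
    warning("ratio undefined: zero or missing denominator")
    return(c(ratio = NA_real_, se = NA_real_))
  }
  if (is.na(m1)) return(c(ratio = NA_real_, se = NA_real_))
  r <- m1 / m2
  se <- abs(r) * sqrt((s1 / m1)^2 + (s2 / m2)^2)
  c(ratio = r, se = se)
}
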