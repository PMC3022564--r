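# Convert a coding sequence (character string) to a vector of codon indices
# (1..64); codons containing anything outside A/C/G/T, and stop codons, are
# NA (the skip sentinel used by pairwise deletion).
codon_indices <- function(cds, code) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("coding sequence length not divisible by 3")
  v <- encode_sequence(toupper(cds))
  codon_indices_from_codes(matrix(v, ncol = 3L, byrow = TRUE), code)
}

codon_indices_from_codes <- function(triplets, code) {
  ok <- triplets[, 1L] <= 4L & triplets[, 2L] <= 4L & triplets[, 3L] <= 4L
  idx <- rep(NA_integer_, nrow(triplets))
  idx[ok] <- codon_index(triplets[ok, 1L], triplets[ok, 2L], triplets[ok, 3L])
  idx[!is.na(idx) & code[idx] == "*"] <- NA_integer_
  idx
}

#' Nei-Gojobori counts for a pair of coding sequences
#'
#' Aggregates NG86 synonymous/nonsynonymous site counts (`S`, `N`) and
#' pathway-averaged difference counts (`sd`, `nd`) over the codons of two
#' aligned coding sequences. Codons where either sequence has a gap/`N`, or
#' where either codon is a stop, are skipped entirely (pairwise deletion at
#' codon granularity). Site counts are averaged across the two sequences;
#' differences are summed over codons; `pS = sd/S` and `pN = nd/N` are the
#' per-site proportions of synonymous and nonsynonymous differences.
#'
#' @param cds1,cds2 Equal-length coding sequences (character strings, length
#'   divisible by 3, e.g. concatenated protein genes).
#' @param code Genetic code.
#' @return A list of class `PairwiseCodonCounts` with `S`, `N`, `sd`, `nd`,
#'   `pS`, `pN` and `n_codons` (usable codons). With zero usable codons the
#'   estimate is undefined: `pS`/`pN` are `NA` and `flagged` is `TRUE`.
#' @export
ng_pair <- function(cds1, cds2, code = genetic_code()) {
  if (nchar(cds1) != nchar(cds2)) stop("coding sequences differ in length")
  i1 <- codon_indices(cds1, code)
  i2 <- codon_indices(cds2, code)
  res <- ng_pair_idx(i1, i2, code)
  class(res) <- "PairwiseCodonCounts"
  res
}

ng_pair_idx <- function(i1, i2, code) {
  tabs <- ng_site_table(code)
  dt <- ng_diff_tables(code)
  ok <- !is.na(i1) & !is.na(i2)
  n_ok <- sum(ok)
  if (!n_ok) {
    warning("no usable codons in pair; NG86 estimate undefined")
    return(list(S = 0, N = 0, sd = 0, nd = 0, pS = NA_real_, pN = NA_real_,
                n_codons = 0L, flagged = TRUE))
  }
  S <- sum(tabs$S[i1[ok]] + tabs$S[i2[ok]]) / 2
  N <- 3 * n_ok - S
  sd_ <- sum(dt$sd[cbind(i1[ok], i2[ok])])
  nd_ <- sum(dt$nd[cbind(i1[ok], i2[ok])])
  list(S = S, N = N, sd = sd_, nd = nd_,
       pS = if (S > 0) sd_ / S else NA_real_,
       pN = if (N > 0) nd_ / N else NA_real_,
       n_codons = n_ok, flagged = FALSE)
}

#' @export
print.PairwiseCodonCounts <- function(x, ...) {
  cat(sprintf("NG86 pair: S=%.4f N=%.4f sd=%.4f nd=%.4f (pS=%.5f pN=%.5f, %d codons)\n",
              x$S, x$N, x$sd, x$nd, x$pS, x$pN, x$n_codons))
  invisible(x)
}

# Codon-index matrix (genomes x codons) of the concatenated protein genes,
# strand-aware, against the alignment. Trailing partial codons are dropped.
coding_codon_matrix <- function(genomes, models, rows = seq_len(n_genomes(genomes)),
                                code = genetic_code()) {
  prot <- models[models$feature == "protein", , drop = FALSE]
  if (!nrow(prot)) stop("no protein genes in gene models")
  comp <- c(4L, 3L, 2L, 1L, 5L, 6L)
  blocks <- list()
  col_blocks <- list()
  for (g in seq_len(nrow(prot))) {
    st <- prot$start0[g]; en <- prot$end0[g]
    n_codon <- (en - st) %/% 3L
    if (!n_codon) next
    if (prot$strand[g] == "+") {
      cols <- seq.int(st + 1L, st + 3L * n_codon)
      B <- genomes$seq[rows, cols, drop = FALSE]
    } else {
      cols <- seq.int(en, en - 3L * n_codon + 1L)
      B <- genomes$seq[rows, cols, drop = FALSE]
      B[] <- comp[B]
    }
    k <- length(rows)
    trip <- cbind(as.vector(B[, seq.int(1L, 3L * n_codon, 3L)]),
                  as.vector(B[, seq.int(2L, 3L * n_codon, 3L)]),
                  as.vector(B[, seq.int(3L, 3L * n_codon, 3L)]))
    idx <- codon_indices_from_codes(trip, code)
    blocks[[length(blocks) + 1L]] <- matrix(idx, nrow = k)
    col_blocks[[length(col_blocks) + 1L]] <-
      if (prot$strand[g] == "+") st + 3L * (seq_len(n_codon) - 1L)
      else en - 3L * seq_len(n_codon)
  }
  out <- do.call(cbind, blocks)
  attr(out, "codon_start0") <- unlist(col_blocks)
  out
}

#' Four-fold degenerate alignment columns
#'
#' Positions (0-based) whose major-allele background codon is resolved,
#' non-stop and four-fold degenerate at that codon position.
#'
#' @param models A `gene_models` table.
#' @param background Integer base-code vector from [major_background()].
#' @param code Genetic code.
#' @return Sorted integer vector of 0-based alignment columns.
#' @export
fourfold_columns <- function(models, background, code = genetic_code()) {
  tabs <- ng_site_table(code)
  comp <- c(4L, 3L, 2L, 1L)
  prot <- models[models$feature == "protein", , drop = FALSE]
  out <- integer(0)
  for (g in seq_len(nrow(prot))) {
    st <- prot$start0[g]; en <- prot$end0[g]
    n_codon <- (en - st) %/% 3L
    if (!n_codon) next
    if (prot$strand[g] == "+") {
      cols0 <- matrix(st + 3L * rep(seq_len(n_codon) - 1L, each = 3L) +
                        rep(0:2, n_codon), nrow = 3L)
    } else {
      cols0 <- matrix(en - 1L - 3L * rep(seq_len(n_codon) - 1L, each = 3L) -
                        rep(0:2, n_codon), nrow = 3L)
    }
    b <- background[cols0 + 1L]
    if (prot$strand[g] == "-") b <- comp[b]
    b <- matrix(b, nrow = 3L)
    ok <- !is.na(b[1L, ]) & !is.na(b[2L, ]) & !is.na(b[3L, ]) &
      b[1L, ] <= 4L & b[2L, ] <= 4L & b[3L, ] <= 4L
    idx <- rep(NA_integer_, n_codon)
    idx[ok] <- codon_index(b[1L, ok], b[2L, ok], b[3L, ok])
    idx[!is.na(idx) & code[idx] == "*"] <- NA_integer_
    for (p in 1:3) {
      four <- which(!is.na(idx) & tabs$deg[cbind(idx, p)] == 4L)
      out <- c(out, cols0[p, four])
    }
  }
  sort(unique(out))
}

# Site-wise heterozygosity h_s = 1 - sum_a C(c_a,2)/C(m,2) for columns with
# m >= 2 called bases; equals the per-column fraction of differing pairs.
sitewise_h <- function(counts) {
  m <- colSums(counts)
  usable <- m >= 2L
  h <- rep(NA_real_, ncol(counts))
  cc <- counts[, usable, drop = FALSE]
  mm <- m[usable]
  same <- colSums(cc * (cc - 1L)) / 2
  h[usable] <- 1 - same / (mm * (mm - 1L) / 2)
  h
}

#' Nucleotide diversity of a population
#'
#' Nucleotide diversity \eqn{\pi}: the average per-site proportion of
#' differing alleles over all pairwise sequence comparisons within a
#' population. `class = "all"` uses the algebraically equivalent site-wise
#' formula \eqn{\pi = \sum_s [1 - \sum_a \binom{c_a}{2}/\binom{m_s}{2}] / L}
#' (exact for the mean of pairwise p-distances when no data are missing; with
#' missing data \eqn{L} is the number of columns with at least two called
#' bases). `class = "fourfold"` applies the same formula restricted to
#' four-fold degenerate columns. `class = "syn"` / `"nonsyn"` run the
#' pairwise Nei-Gojobori computation over the concatenated protein genes with
#' pairwise deletion and average the per-pair `pS` / `pN`. Standard errors
#' are obtained by a seeded bootstrap over alignment (or codon) columns.
#'
#' @param genomes An `AlignedGenomeSet`.
#' @param models A `gene_models` table (required for all classes except
#'   `"all"`).
#' @param class One of `"all"`, `"syn"`, `"fourfold"`, `"nonsyn"`.
#' @param population Population label, or `NULL` for the whole set.
#' @param n_boot Bootstrap resamples for the standard error (0 disables).
#' @param seed Seed for the bootstrap (and for the genome subsample when
#'   `max_genomes` truncates).
#' @param max_genomes Cap on the number of genomes used (a seeded random
#'   subsample is taken above the cap; the NG86 classes are quadratic in the
#'   number of genomes).
#' @param code Genetic code.
#' @return A list of class `DiversityEstimate`: `pi`, `se`, `class`,
#'   `population`, `n_genomes`, `n_pairs`, `n_sites`.
#' @export
nucleotide_diversity <- function(genomes, models = NULL,
                                 class = c("all", "syn", "fourfold", "nonsyn"),
                                 population = NULL, n_boot = 1000L,
                                 seed = 1L, max_genomes = Inf,
                                 code = genetic_code()) {
  class <- match.arg(class)
  rows <- if (is.null(population)) seq_len(n_genomes(genomes))
          else population_rows(genomes, population)
  if (length(rows) < 2L)
    stop("population must contain at least 2 genomes")
  if (length(rows) > max_genomes) {
    rows <- with_preserved_seed(seed + 1L,
                                sort(sample(rows, max_genomes)))
  }
  n <- length(rows)

  if (class %in% c("all", "fourfold")) {
    cb <- column_base_counts(genomes, rows)
    cols <- seq_len(ncol(cb$counts))
    if (class == "fourfold") {
      if (is.null(models)) stop("gene models required for class 'fourfold'")
      bg <- major_background(genomes)
      cols <- fourfold_columns(models, bg, code) + 1L
      if (!length(cols)) stop("no four-fold degenerate columns found")
    }
    h <- sitewise_h(cb$counts[, cols, drop = FALSE])
    h <- h[!is.na(h)]
    if (!length(h)) stop("no usable columns for diversity estimate")
    pi_hat <- mean(h)
    se <- NA_real_
    if (n_boot > 0L) {
      se <- with_preserved_seed(seed, {
        reps <- vapply(seq_len(n_boot), function(b)
          mean(h[sample.int(length(h), replace = TRUE)]), 0)
        stats::sd(reps)
      })
    }
    out <- list(pi = pi_hat, se = se, class = class,
                population = population %||% "all",
                n_genomes = n, n_pairs = n * (n - 1L) / 2,
                n_sites = length(h))
  } else {
    if (is.null(models)) stop("gene models required for NG86 classes")
    cm <- coding_codon_matrix(genomes, models, rows, code)
    tabs <- ng_site_table(code)
    dt <- ng_diff_tables(code)
    n_cod <- ncol(cm)
    pairs <- combn(n, 2L)
    n_pairs <- ncol(pairs)
    Ssite <- unname(tabs$S)
    diff_tab <- if (class == "syn") dt$sd else dt$nd
    # per-pair x per-codon contribution matrices (sites and differences)
    SM <- matrix(0, n_pairs, n_cod)
    DM <- matrix(0, n_pairs, n_cod)
    for (p in seq_len(n_pairs)) {
      i1 <- cm[pairs[1L, p], ]
      i2 <- cm[pairs[2L, p], ]
      ok <- !is.na(i1) & !is.na(i2)
      s_ok <- (Ssite[i1[ok]] + Ssite[i2[ok]]) / 2
      if (class == "nonsyn") s_ok <- 3 - s_ok
      SM[p, ok] <- s_ok
      DM[p, ok] <- diff_tab[cbind(i1[ok], i2[ok])]
    }
    Stot <- rowSums(SM)
    Dtot <- rowSums(DM)
    usable_pairs <- Stot > 0
    if (!any(usable_pairs)) stop("no usable pairs for NG86 diversity")
    pi_hat <- mean(Dtot[usable_pairs] / Stot[usable_pairs])
    se <- NA_real_
    if (n_boot > 0L) {
      se <- with_preserved_seed(seed, {
        reps <- vapply(seq_len(n_boot), function(b) {
          w <- tabulate(sample.int(n_cod, replace = TRUE), n_cod)
          sb <- as.vector(SM %*% w)
          db <- as.vector(DM %*% w)
          okp <- sb > 0
          if (!any(okp)) return(NA_real_)
          mean(db[okp] / sb[okp])
        }, 0)
        stats::sd(reps, na.rm = TRUE)
      })
    }
    out <- list(pi = pi_hat, se = se, class = class,
                population = population %||% "all",
                n_genomes = n, n_pairs = n_pairs, n_sites = n_cod)
  }
  if (out$pi > 1) warning("diversity estimate above 1 (degenerate input?)")
  class(out) <- "DiversityEstimate"
  out
}

#' @export
print.DiversityEstimate <- function(x, ...) {
  cat(sprintf("pi[%s] (%s) = %.6g +- %.3g  (%d genomes, %d pairs, %d sites)\n",
              x$class, x$population, x$pi, x$se, x$n_genomes, x$n_pairs,
              x$n_sites))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's state afterwards (all package randomness flows through this).
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
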