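# All 64 codons in fixed lexicographic (A<C<G<T) order; codon index i of a
# codon (b1,b2,b3) with bases coded 1..4 is (b1-1)*16+(b2-1)*4+b3.
CODONS <- {
  b <- c("A", "C", "G", "T")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}

codon_index <- function(b1, b2, b3) (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3

#' Retrieve a genetic code table
#'
#' Returns the codon -> amino-acid map for an NCBI translation table, with
#' stop codons encoded as `"*"`. The package default is the vertebrate
#' mitochondrial code (table 2: `ATA` = Met, `TGA` = Trp, `AGA`/`AGG` = stop).
#'
#' @param id NCBI genetic-code id (integer or character), default `2`.
#' @return Named character vector of length 64 (names are codons).
#' @export
genetic_code <- function(id = 2L) {
  code <- Biostrings::getGeneticCode(as.character(id))
  code <- code[CODONS]
  if (length(code) != 64L || anyNA(code))
    stop("incomplete genetic code table for id ", id)
  attr(code, "code_id") <- as.integer(id)
  code
}

is_stop <- function(codon, code) unname(code[codon] == "*")

#' Translate a single codon
#'
#' @param codon A 3-letter codon string.
#' @param code A genetic code from [genetic_code()].
#' @return The one-letter amino acid, `"*"` for a stop codon, or `NA` (the
#'   "unresolved" sentinel) when the codon contains any character outside
#'   `A/C/G/T` — unresolved codons are never silently translated.
#' @export
translate_codon <- function(codon, code = genetic_code()) {
  stopifnot(nchar(codon) == 3L)
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) return(NA_character_)
  unname(code[codon])
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' Nei-Gojobori (1986) site counting: each of the three codon positions
#' contributes `s/3` synonymous sites, where `s` is the number of the three
#' possible single-nucleotide changes at that position that preserve the
#' amino acid. Changes creating a stop codon count as nonsynonymous.
#' `S + N = 3` for every resolved non-stop codon.
#'
#' @param codon A 3-letter codon over `A/C/G/T`; stop codons are an error
#'   (callers skip them).
#' @param code Genetic code.
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @export
count_syn_sites <- function(codon, code = genetic_code()) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("unresolved codon: ", codon)
  if (is_stop(codon, code)) stop("stop codon has no NG86 site counts: ", codon)
  tabs <- ng_site_table(code)
  S <- tabs$S[codon]
  c(S = unname(S), N = 3 - unname(S))
}

#' Codon degeneracy class at a position
#'
#' The number of nucleotides at the given codon position (including the
#' current one) that yield the same amino acid; a 4-fold position is one at
#' which all four bases are synonymous.
#'
#' @param codon A resolved, non-stop 3-letter codon.
#' @param position Codon position, 1..3.
#' @param code Genetic code.
#' @return Integer in 1..4, or `NA` for an unresolved codon.
#' @export
degeneracy_class <- function(codon, position, code = genetic_code()) {
  stopifnot(position %in% 1:3)
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) return(NA_integer_)
  if (is_stop(codon, code)) stop("stop codon has no degeneracy class: ", codon)
  aa <- code[codon]
  variants <- vapply(c("A", "C", "G", "T"), function(b) {
    v <- codon
    substr(v, position, position) <- b
    v
  }, "")
  sum(code[variants] == aa)
}

# --- precomputed NG86 lookup tables, keyed by genetic-code id ---------------

.ng_cache <- new.env(parent = emptyenv())

# Per-codon S counts and per-position degeneracy for all 64 codons (NA at
# stops), plus pathway-averaged (sd, nd) for all 64x64 codon pairs.
ng_site_table <- function(code) {
  key <- paste0("site_", attr(code, "code_id"))
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  S <- setNames(rep(NA_real_, 64L), CODONS)
  deg <- matrix(NA_integer_, nrow = 64L, ncol = 3L, dimnames = list(CODONS, NULL))
  for (codon in CODONS) {
    if (code[codon] == "*") next
    aa <- code[codon]
    s <- 0
    for (p in 1:3) {
      same <- 0L
      for (b in c("A", "C", "G", "T")) {
        v <- codon
        substr(v, p, p) <- b
        if (code[v] == aa) same <- same + 1L
      }
      deg[codon, p] <- same
      s <- s + (same - 1L) / 3   # exclude the current base
    }
    S[codon] <- s
  }
  res <- list(S = S, deg = deg)
  .ng_cache[[key]] <- res
  res
}

# Pathway-averaged synonymous/nonsynonymous difference counts for every codon
# pair. Pathways stepping through a stop codon are excluded from the average;
# when every pathway is excluded, all pathways are used with stop-passing
# steps counted as nonsynonymous (the MEGA/NG86 convention).
ng_diff_tables <- function(code) {
  key <- paste0("diff_", attr(code, "code_id"))
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  sd_tab <- matrix(NA_real_, 64L, 64L, dimnames = list(CODONS, CODONS))
  nd_tab <- sd_tab
  split3 <- strsplit(CODONS, "")
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(64L)) {
    if (code[i] == "*") next
    for (j in seq_len(64L)) {
      if (code[j] == "*") next
      d <- which(split3[[i]] != split3[[j]])
      if (!length(d)) { sd_tab[i, j] <- 0; nd_tab[i, j] <- 0; next }
      paths <- perms[[length(d)]]
      res <- lapply(paths, function(ord) {
        cur <- split3[[i]]
        sdv <- 0; ndv <- 0; through_stop <- FALSE
        for (p in d[ord]) {
          nxt <- cur
          nxt[p] <- split3[[j]][p]
          aa1 <- code[paste(cur, collapse = "")]
          aa2 <- code[paste(nxt, collapse = "")]
          if (aa2 == "*" || aa1 == "*") through_stop <- TRUE
          # a step touching a stop codon is never synonymous (this only
          # matters on the all-pathways-excluded fallback; stop-free paths
          # are unaffected)
          if (aa1 == aa2 && aa1 != "*") sdv <- sdv + 1 else ndv <- ndv + 1
          cur <- nxt
        }
        # endpoints are non-stop, so through_stop marks intermediate stops
        list(sd = sdv, nd = ndv, stop = through_stop)
      })
      ok <- !vapply(res, `[[`, TRUE, "stop")
      use <- if (any(ok)) res[ok] else res
      sd_tab[i, j] <- mean(vapply(use, `[[`, 0, "sd"))
      nd_tab[i, j] <- mean(vapply(use, `[[`, 0, "nd"))
    }
  }
  res <- list(sd = sd_tab, nd = nd_tab)
  .ng_cache[[key]] <- res
  res
}

#' Pathway-averaged codon difference counts (NG86)
#'
#' Partitions the nucleotide differences between two codons into synonymous
#' (`sd`) and nonsynonymous (`nd`) fractions by averaging over all orderings
#' of the differing positions (1, 2 or 6 pathways). Pathways passing through
#' a stop codon are excluded from the average; if all pathways are excluded,
#' all are used with stop-passing steps counted as nonsynonymous.
#' `sd + nd` equals the Hamming distance of the codons.
#'
#' @param c1,c2 Resolved, non-stop 3-letter codons.
#' @param code Genetic code.
#' @return Named numeric vector `c(sd = ..., nd = ...)`, or `c(NA, NA)` (the
#'   skip sentinel) when either codon is unresolved.
#' @export
pairwise_codon_diffs <- function(c1, c2, code = genetic_code()) {
  c1 <- toupper(c1); c2 <- toupper(c2)
  if (!grepl("^[ACGT]{3}$", c1) || !grepl("^[ACGT]{3}$", c2))
    return(c(sd = NA_real_, nd = NA_real_))
  if (is_stop(c1, code) || is_stop(c2, code))
    stop("stop codon in pairwise_codon_diffs: ", c1, "/", c2)
  tabs <- ng_diff_tables(code)
  c(sd = tabs$sd[c1, c2], nd = tabs$nd[c1, c2])
}
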