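# Independent brute-force oracles. These deliberately share no code with the
# package implementation beyond the genetic-code table itself.

oracle_bases <- c("A", "C", "G", "T")

oracle_translate <- function(codon, code) unname(code[codon])

# NG86 site counts by direct enumeration of the 9 single-nucleotide mutants.
oracle_site_counts <- function(codon, code) {
  aa <- oracle_translate(codon, code)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(oracle_bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (oracle_translate(mut, code) == aa) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# NG86 pathway averaging by explicit enumeration of all orderings of the
# differing positions. Stop-passing pathways excluded; if all are excluded,
# all pathways are used with any step touching a stop counted nonsynonymous.
oracle_pairwise_diffs <- function(c1, c2, code) {
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(d)) return(c(sd = 0, nd = 0))
  paths <- oracle_perms(d)
  walk <- function(ord) {
    cur <- c1
    sd_ <- 0; nd_ <- 0; stopped <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- oracle_translate(cur, code)
      a2 <- oracle_translate(nxt, code)
      if (a1 == "*" || a2 == "*") stopped <- TRUE
      if (a1 == a2 && a1 != "*") sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    list(sd = sd_, nd = nd_, stopped = stopped)
  }
  res <- lapply(paths, walk)
  valid <- !vapply(res, `[[`, TRUE, "stopped")
  use <- if (any(valid)) res[valid] else res
  c(sd = sum(vapply(use, `[[`, 0, "sd")) / length(use),
    nd = sum(vapply(use, `[[`, 0, "nd")) / length(use))
}

# Mean pairwise p-distance by a double loop over genome pairs; per pair the
# denominator is the number of columns where both sequences have a called
# base (pairwise deletion).
oracle_pi_bruteforce <- function(seq_matrix) {
  n <- nrow(seq_matrix)
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- seq_matrix[i, ]; b <- seq_matrix[j, ]
      ok <- a <= 4L & b <= 4L
      vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
    }
  }
  mean(vals)
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to the first sample (tie-free samples only).
oracle_utest_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- combn(n1 + n2, n1)
  all_r <- seq_len(n1 + n2)
  u_all <- apply(splits, 2L, function(s) sum(all_r[s]) - n1 * (n1 + 1) / 2)
  dev_obs <- abs(u_obs - n1 * n2 / 2)
  mean(abs(u_all - n1 * n2 / 2) >= dev_obs - 1e-9)
}
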