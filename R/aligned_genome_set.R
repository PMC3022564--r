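#' @importFrom stats rbinom rbeta sd quantile setNames pnorm
#' @importFrom utils read.delim write.table combn
NULL

# Internal base encoding shared by the whole package. Gap and N are both
# "missing" for every count and denominator; they are kept distinct only so
# alignments round-trip exactly.
BASES <- c("A", "C", "G", "T", "N", "-")
BASE_A <- 1L
BASE_N <- 5L
BASE_GAP <- 6L

base_to_int <- function(x) {
  i <- match(x, BASES)
  if (anyNA(i)) stop("illegal base(s): ", paste(unique(x[is.na(i)]), collapse = ", "))
  i
}

int_to_base <- function(i) BASES[i]

# Fast char -> code conversion for whole sequences via a raw lookup table.
.base_lookup <- local({
  lut <- rep(NA_integer_, 256L)
  chars <- c("A", "C", "G", "T", "N", "-", "a", "c", "g", "t", "n", "U", "u")
  codes <- c(1L, 2L, 3L, 4L, 5L, 6L, 1L, 2L, 3L, 4L, 5L, 4L, 4L)
  lut[as.integer(charToRaw(paste(chars, collapse = ""))) + 1L] <- codes
  lut
})

encode_sequence <- function(s, id = "<sequence>") {
  codes <- .base_lookup[as.integer(charToRaw(s)) + 1L]
  if (anyNA(codes)) {
    col <- which(is.na(codes))[1L]
    stop(sprintf("illegal character '%s' in record '%s' at column %d",
                 substr(s, col, col), id, col))
  }
  codes
}

decode_row <- function(codes) paste(BASES[codes], collapse = "")

#' Construct an aligned genome set
#'
#' The central container of the package: an equal-length multiple alignment of
#' complete genomes together with sample identifiers and a two-population
#' partition. All site-wise statistics operate on this object. Internally the
#' alignment is stored as an integer matrix (one row per genome) over the
#' six-letter alphabet `A,C,G,T,N,-`; `N` and `-` are treated as missing data
#' everywhere.
#'
#' @param sequences Character vector of aligned sequences (equal length,
#'   alphabet `A/C/G/T/N/-`; lowercase and `U` are folded on input).
#' @param sample_ids Character vector of unique sample identifiers.
#' @param population Named character vector mapping every sample id to one of
#'   exactly two population labels (may be `NULL` for unlabelled sets used in
#'   intermediate computations).
#' @return An object of class `AlignedGenomeSet`.
#' @export
aligned_genome_set <- function(sequences, sample_ids, population = NULL) {
  stopifnot(is.character(sequences), is.character(sample_ids))
  if (length(sequences) != length(sample_ids))
    stop("sequences and sample_ids differ in length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L)
    stop("alignment error: ragged sequence lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  L <- lens[1L]
  m <- matrix(0L, nrow = length(sequences), ncol = L)
  for (i in seq_along(sequences)) m[i, ] <- encode_sequence(sequences[i], sample_ids[i])
  new_aligned_genome_set(m, sample_ids, population)
}

# Low-level constructor from an already-encoded matrix.
new_aligned_genome_set <- function(seq_matrix, sample_ids, population = NULL) {
  if (!is.null(population)) {
    population <- validate_population(population, sample_ids)
  }
  structure(list(seq = seq_matrix, sample_ids = sample_ids,
                 population = population),
            class = "AlignedGenomeSet")
}

validate_population <- function(population, sample_ids) {
  missing <- setdiff(sample_ids, names(population))
  if (length(missing))
    stop("samples missing from population metadata: ",
         paste(missing, collapse = ", "))
  population <- population[sample_ids]
  labels <- unique(unname(population))
  if (length(labels) != 2L)
    stop("exactly two population labels required, got ", length(labels), ": ",
         paste(labels, collapse = ", "))
  population
}

#' @export
print.AlignedGenomeSet <- function(x, ...) {
  cat(sprintf("AlignedGenomeSet: %d genomes x %d aligned columns\n",
              n_genomes(x), alignment_length(x)))
  if (!is.null(x$population)) {
    tab <- table(x$population)
    cat("populations:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of genomes in an aligned set
#' @param x An `AlignedGenomeSet`.
#' @return Integer.
#' @export
n_genomes <- function(x) nrow(x$seq)

#' Alignment length (number of columns)
#' @param x An `AlignedGenomeSet`.
#' @return Integer.
#' @export
alignment_length <- function(x) ncol(x$seq)

#' Population labels of an aligned set
#' @param x An `AlignedGenomeSet`.
#' @return Character vector of the (two) distinct labels, sorted by increasing
#'   population size, or `NULL` when the set is unlabelled.
#' @export
population_labels <- function(x) {
  if (is.null(x$population)) return(NULL)
  tab <- sort(table(unname(x$population)))
  names(tab)
}

population_rows <- function(x, population) {
  if (is.null(x$population)) stop("genome set has no population labels")
  rows <- which(unname(x$population) == population)
  if (!length(rows)) stop("unknown or empty population: ", population)
  rows
}

#' Restrict an aligned set to a subset of samples
#'
#' @param x An `AlignedGenomeSet`.
#' @param samples Character vector of sample ids, or integer row indices.
#' @param drop_population Drop population labels in the result (used for
#'   single-population restrictions where the two-label invariant no longer
#'   holds).
#' @return An `AlignedGenomeSet` with the selected genomes, in the given order.
#' @export
restrict_samples <- function(x, samples, drop_population = FALSE) {
  rows <- if (is.numeric(samples)) as.integer(samples)
          else match(samples, x$sample_ids)
  if (anyNA(rows) || any(rows < 1L) || any(rows > n_genomes(x)))
    stop("unknown sample(s) in restriction")
  pop <- x$population
  if (!is.null(pop) && !drop_population) {
    pop <- pop[x$sample_ids[rows]]
    if (length(unique(unname(pop))) != 2L) pop <- NULL
  } else pop <- NULL
  structure(list(seq = x$seq[rows, , drop = FALSE],
                 sample_ids = x$sample_ids[rows],
                 population = pop),
            class = "AlignedGenomeSet")
}

#' Sequences of an aligned set as character strings
#' @param x An `AlignedGenomeSet`.
#' @return Named character vector (names are sample ids).
#' @export
as_sequences <- function(x) {
  out <- vapply(seq_len(n_genomes(x)), function(i) decode_row(x$seq[i, ]), "")
  names(out) <- x$sample_ids
  out
}
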