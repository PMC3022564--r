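#' Read an aligned multi-FASTA of complete genomes
#'
#' Reads an alignment of complete (e.g. mitochondrial) genomes from a
#' multi-FASTA file. Sequences are case-folded to upper case, `U` is mapped to
#' `T`, and any character outside `A/C/G/T/N/-` is an error naming the record
#' and column. All records must have identical aligned length and unique ids.
#'
#' @param path Path to an aligned multi-FASTA file.
#' @param population Optional named character vector (sample id -> population
#'   label) to attach, e.g. from [read_sample_metadata()].
#' @return An [aligned_genome_set()].
#' @export
read_alignment <- function(path, population = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2L) stop("alignment must contain at least 2 records")
  ids <- sub("\\s.*$", "", names(ss))
  aligned_genome_set(as.character(ss), ids, population)
}

#' Write an aligned genome set to multi-FASTA
#'
#' @param x An `AlignedGenomeSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  ss <- Biostrings::BStringSet(as_sequences(x))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read sample metadata (population labels)
#'
#' Two-column TSV with header `sample_id<TAB>population`. The survey is a
#' two-population contrast, so more than two distinct labels is an error.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping sample id to population label.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, colClasses = "character")
  need <- c("sample_id", "population")
  if (!all(need %in% names(df)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  labels <- unique(df$population)
  if (length(labels) > 2L)
    stop("more than two population labels in metadata: ",
         paste(labels, collapse = ", "))
  setNames(df$population, df$sample_id)
}

#' Write sample metadata
#' @param population Named character vector (sample id -> label).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(population, path) {
  write.table(data.frame(sample_id = names(population),
                         population = unname(population)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

GENE_FEATURES <- c("protein", "tRNA", "rRNA")
.gff_type_of <- c(protein = "CDS", tRNA = "tRNA", rRNA = "rRNA")

#' Read gene models from a GFF3 file
#'
#' Accepts GFF3 with feature types `CDS` (protein-coding), `tRNA` and `rRNA`;
#' other types are ignored. Coordinates are 1-based inclusive *alignment*
#' columns per GFF3 convention and are converted internally to 0-based
#' half-open (`start0`, `end0`). Protein features whose length is not a
#' multiple of 3 trigger a warning (trailing partial codons are dropped at
#' classification time). Overlapping protein genes are allowed (mtDNA reality)
#' but reported with a message.
#'
#' @param path Path to the GFF3 file.
#' @return A data.frame of class `gene_models` with columns `name`, `start`,
#'   `end` (1-based inclusive), `start0`, `end0` (0-based half-open), `strand`,
#'   `feature` (`protein`/`tRNA`/`rRNA`) and `code_id` (NCBI genetic-code id;
#'   `transl_table` attribute, default 2).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  keep <- type %in% .gff_type_of
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  if (!length(gr)) stop("no CDS/tRNA/rRNA features in ", path)
  name <- if (!is.null(mc$Name)) as.character(mc$Name) else as.character(mc$ID)
  tt <- if ("transl_table" %in% names(mc)) {
    suppressWarnings(as.integer(as.character(mc$transl_table)))
  } else rep(NA_integer_, length(gr))
  tt[is.na(tt)] <- 2L
  gene_models(name = name,
              start = GenomicRanges::start(gr),
              end = GenomicRanges::end(gr),
              strand = as.character(GenomicRanges::strand(gr)),
              feature = names(.gff_type_of)[match(as.character(mc$type), .gff_type_of)],
              code_id = tt)
}

#' Construct a gene-model table
#'
#' @param name Gene names.
#' @param start,end 1-based inclusive alignment coordinates (`start <= end`).
#' @param strand `"+"` or `"-"`; minus-strand protein genes are translated on
#'   the reverse complement.
#' @param feature One of `"protein"`, `"tRNA"`, `"rRNA"` per gene.
#' @param code_id NCBI genetic-code id per gene (vertebrate mitochondrial = 2).
#' @return A `gene_models` data.frame, sorted by start; see
#'   [read_gene_models()].
#' @export
gene_models <- function(name, start, end, strand, feature, code_id = 2L) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end))
    stop("coordinate error: start > end for gene(s) ",
         paste(name[start > end], collapse = ", "))
  if (any(start < 1L)) stop("coordinates are 1-based; start < 1")
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(feature %in% GENE_FEATURES))
    stop("feature must be one of: ", paste(GENE_FEATURES, collapse = ", "))
  df <- data.frame(name = as.character(name), start = start, end = end,
                   start0 = start - 1L, end0 = end,
                   strand = strand, feature = feature,
                   code_id = as.integer(code_id),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start0), , drop = FALSE]
  rownames(df) <- NULL
  prot <- df[df$feature == "protein", , drop = FALSE]
  bad <- (prot$end0 - prot$start0) %% 3L != 0L
  if (any(bad))
    warning("protein gene length not divisible by 3: ",
            paste(prot$name[bad], collapse = ", "))
  if (nrow(prot) > 1L) {
    ov <- which(prot$start0[-1L] < prot$end0[-nrow(prot)])
    if (length(ov))
      message("overlapping protein genes: ",
              paste(prot$name[ov], prot$name[ov + 1L], sep = "/", collapse = ", "))
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write gene models to GFF3
#' @param models A `gene_models` table.
#' @param path Output path.
#' @param seqname Sequence name to use in the GFF (the alignment itself is the
#'   coordinate system).
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, seqname = "alignment") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = models$strand)
  S4Vectors::mcols(gr)$type <- unname(.gff_type_of[models$feature])
  S4Vectors::mcols(gr)$Name <- models$name
  S4Vectors::mcols(gr)$ID <- models$name
  S4Vectors::mcols(gr)$transl_table <- as.character(models$code_id)
  S4Vectors::mcols(gr)$source <- "mitosurvey"
  S4Vectors::mcols(gr)$phase <- ifelse(models$feature == "protein", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

EFFECT_LABELS <- c("benign", "damaging", "unknown")

#' Read an effect-class annotation table
#'
#' TSV with header `position<TAB>alt_base<TAB>label`, where `position` is a
#' 1-based alignment column, `alt_base` the annotated alternate base, and
#' `label` one of `benign`, `damaging`, `unknown`. These labels are consumed
#' as input (they originate from a variant-effect predictor run upstream;
#' "possibly" and "probably" damaging classes are expected to be pooled into
#' `damaging` before this point).
#'
#' @param path Path to the TSV file.
#' @param alignment_length Optional; when given, positions beyond it are an
#'   error.
#' @return Data.frame of class `effect_annotation` with columns `pos0`
#'   (0-based), `base`, `label`.
#' @export
read_effect_annotation <- function(path, alignment_length = NULL) {
  df <- read.delim(path, colClasses = c("integer", "character", "character"))
  need <- c("position", "alt_base", "label")
  if (!all(need %in% names(df)))
    stop("effect annotation must have columns: ", paste(need, collapse = ", "))
  if (!all(df$alt_base %in% BASES[1:4]))
    stop("effect annotation alt_base must be one of A/C/G/T")
  bad <- setdiff(unique(df$label), EFFECT_LABELS)
  if (length(bad))
    stop("unknown effect label(s): ", paste(bad, collapse = ", "))
  if (!is.null(alignment_length) &&
      any(df$position < 1L | df$position > alignment_length))
    stop("effect annotation position outside alignment")
  out <- data.frame(pos0 = df$position - 1L, base = df$alt_base,
                    label = df$label, stringsAsFactors = FALSE)
  class(out) <- c("effect_annotation", "data.frame")
  out
}

PATHOGENIC_USED <- c("Reported", "Confirmed")

#' Read a pathogenic-mutation catalogue
#'
#' TSV with header `position<TAB>alt_base<TAB>status`. Only entries with
#' status `Reported` or `Confirmed` are retained (the count of discarded rows
#' is reported with a message); an empty catalogue is valid and downstream
#' pathogenic summaries then report zero sites.
#'
#' @param path Path to the TSV file.
#' @param alignment_length Optional position bound check, as in
#'   [read_effect_annotation()].
#' @return Data.frame of class `pathogenic_catalogue` with columns `pos0`,
#'   `base`, `status` (filtered to Reported/Confirmed).
#' @export
read_pathogenic_catalogue <- function(path, alignment_length = NULL) {
  df <- read.delim(path, colClasses = c("integer", "character", "character"))
  need <- c("position", "alt_base", "status")
  if (!all(need %in% names(df)))
    stop("pathogenic catalogue must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) && !all(df$alt_base %in% BASES[1:4]))
    stop("pathogenic catalogue alt_base must be one of A/C/G/T")
  if (!is.null(alignment_length) && nrow(df) &&
      any(df$position < 1L | df$position > alignment_length))
    stop("pathogenic catalogue position outside alignment")
  keep <- df$status %in% PATHOGENIC_USED
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " catalogue entr",
                      if (n_drop == 1L) "y" else "ies",
                      " with status outside Reported/Confirmed discarded")
  df <- df[keep, , drop = FALSE]
  out <- data.frame(pos0 = df$position - 1L, base = df$alt_base,
                    status = df$status, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pathogenic_catalogue", "data.frame")
  out
}

#' Write an effect annotation or pathogenic catalogue back to TSV
#' @param x An `effect_annotation` or `pathogenic_catalogue` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(x, path) {
  if (inherits(x, "effect_annotation")) {
    df <- data.frame(position = x$pos0 + 1L, alt_base = x$base, label = x$label)
  } else if (inherits(x, "pathogenic_catalogue")) {
    df <- data.frame(position = x$pos0 + 1L, alt_base = x$base, status = x$status)
  } else stop("unsupported annotation object")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
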