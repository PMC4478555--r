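## Core I/O: genomes (FASTA), strain trees (Newick), occurrence tables
## (BED-like TSV) and presence/absence matrices (TSV).
##
## Conventions shared by the whole package:
##   * intervals are 0-based half-open [start, end) internally; 1-based
##     inclusive coordinates appear only in human-readable reports;
##   * genomes are circular unless stated otherwise; an interval with
##     wraps_origin = TRUE covers suffix + prefix of the sequence;
##   * sequences are uppercase A/C/G/T/N; N never matches anything.

#' Construct a genome object
#'
#' A light container for one strain's (typically circular, mitochondrial)
#' DNA sequence.
#'
#' @param strain_id Strain identifier (unique within a dataset).
#' @param sequence DNA sequence as a single character string. Lowercase is
#'   accepted and uppercased; `U` is converted to `T`.
#' @param species Species name (optional, used by the horizontal-exchange
#'   classifier).
#' @param circular Logical; treat the molecule as circular (default `TRUE`).
#' @param ambiguity How to treat IUPAC ambiguity codes other than `N`:
#'   `"error"` rejects them, `"N"` masks them to `N`.
#' @return An object of class `"genome"`: a list with elements
#'   `strain_id`, `species`, `sequence`, `circular`.
#' @examples
#' g <- genome("s1", "acgtACGT")
#' g$sequence
#' @export
genome <- function(strain_id, sequence, species = NA_character_,
                   circular = TRUE, ambiguity = c("error", "N")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(strain_id), length(strain_id) == 1L, nzchar(strain_id),
            is.character(sequence), length(sequence) == 1L)
  seq <- chartr("u", "t", toupper(sequence))
  seq <- chartr("U", "T", seq)
  if (!nzchar(seq)) stop("empty sequence for strain '", strain_id, "'")
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    if (ambiguity == "error")
      stop("sequence for strain '", strain_id,
           "' contains non-ACGTN characters: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  structure(list(strain_id = strain_id, species = species,
                 sequence = seq, circular = circular),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s%s: %s bp%s\n", x$strain_id,
              if (is.na(x$species)) "" else paste0(" (", x$species, ")"),
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) ", circular" else ""))
  invisible(x)
}

genome_length <- function(genome) nchar(genome$sequence)

#' Read genomes from a FASTA file
#'
#' @param path Path to a FASTA file. Record ids (first whitespace-delimited
#'   token of each header) become strain ids and must be unique.
#' @param species Optional species name applied to all records, or a named
#'   character vector keyed by strain id.
#' @param circular Logical, applied to all records.
#' @inheritParams genome
#' @return A named list of [genome] objects.
#' @export
read_genomes <- function(path, species = NA_character_, circular = TRUE,
                         ambiguity = c("error", "N")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(set) == 0L))
    stop("empty FASTA record(s): ",
         paste(ids[Biostrings::width(set) == 0L], collapse = ", "))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    sp <- if (length(species) > 1L) unname(species[ids[i]]) else species
    out[[i]] <- genome(ids[i], as.character(set[[i]]), species = sp,
                       circular = circular, ambiguity = ambiguity)
  }
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes A list of [genome] objects.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "strain_id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a strain phylogeny from a Newick file
#'
#' Branch lengths are interpreted throughout the package as expected
#' nucleotide substitutions per site, so fitted turnover rates come out
#' as events per site per nucleotide substitution.
#'
#' @param path Path to a Newick file containing one tree.
#' @param strict If `TRUE` (default), missing branch lengths are an error;
#'   otherwise they are set to 0 with a warning.
#' @return An [ape::phylo] tree.
#' @export
read_strain_tree <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  validate_tree(tree, strict = strict)
}

validate_tree <- function(tree, strict = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (strict) stop("tree has no branch lengths")
    warning("tree has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (strict) stop("tree has missing branch lengths")
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Write occurrences to a BED-like TSV
#'
#' Columns: `strain`, `start` (0-based), `end` (exclusive), `strand`,
#' `family_id`, `identity`. Rows are sorted by (strain, start).
#'
#' @param occurrences A data.frame of element occurrences as produced by
#'   [find_dispersed_repeats()] or [search_homologs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occurrences, path) {
  cols <- c("strain", "start", "end", "strand", "family_id", "identity")
  if (is.null(occurrences) || nrow(occurrences) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  stopifnot(all(cols %in% names(occurrences)))
  occ <- occurrences[order(occurrences$strain, occurrences$start), cols]
  write.table(occ, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read occurrences written by [write_occurrences()]
#' @param path Path to the TSV.
#' @return A data.frame with the canonical occurrence columns.
#' @export
read_occurrences <- function(path) {
  occ <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(strain = "character", start = "integer",
                                   end = "integer", strand = "character",
                                   family_id = "character",
                                   identity = "numeric"))
  occ
}

#' Write a presence/absence matrix to TSV
#'
#' Cells are `1` (present), `0` (absent) or `?` (missing). Rows are
#' homologous positions, columns are strains.
#'
#' @param mat Integer matrix with values 0/1/NA, rownames = position ids,
#'   colnames = strain ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pa_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  sym <- matrix(as.character(mat), nrow(mat), ncol(mat))
  sym[is.na(sym)] <- "?"
  df <- data.frame(position = rownames(mat) %||% seq_len(nrow(mat)),
                   sym, check.names = FALSE)
  colnames(df) <- c("position", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a presence/absence matrix written by [write_pa_matrix()]
#' @param path Path to the TSV.
#' @return Integer matrix with values 0/1/NA.
#' @export
read_pa_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "character"
  out <- suppressWarnings(matrix(as.integer(mat), nrow(mat), ncol(mat),
                                 dimnames = dimnames(mat)))
  out[mat == "?"] <- NA
  bad <- !(out %in% c(0L, 1L)) & !is.na(out)
  if (any(bad)) stop("matrix cells must be 0, 1 or ?")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## -- interval helpers (0-based half-open, circular-aware) -----------------

## extract [start, end) from a genome, wrapping the origin when end > L is
## encoded via wraps = TRUE (end is then interpreted modulo L)
extract_interval <- function(genome, start, end, strand = "+", wraps = FALSE) {
  L <- genome_length(genome)
  stopifnot(start >= 0, start < L)
  if (wraps) {
    stopifnot(genome$circular)
    seq <- paste0(substr(genome$sequence, start + 1L, L),
                  substr(genome$sequence, 1L, end))
  } else {
    stopifnot(end > start, end <= L)
    seq <- substr(genome$sequence, start + 1L, end)
  }
  if (strand == "-") seq <- revcomp(seq)
  seq
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  gc <- nchar(gsub("[^GCgc]", "", seq))
  gc / n
}
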