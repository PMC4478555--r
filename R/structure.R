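## Hairpin structure partitioning and the statistics built on it:
## loop/stem substitution enrichment, nucleotide diversity, element
## density in indel regions, and RPKM normalisation of expression tables.

#' Maximum base-pairing hairpin fold
#'
#' Nussinov-style dynamic programme maximising the number of nested
#' Watson-Crick (and optional G.T wobble) pairs with a minimum hairpin
#' loop size. Traceback is deterministic: closing the outermost pair is
#' preferred over leaving an end unpaired, which is preferred over
#' bifurcation, so ties resolve toward long contiguous stems.
#'
#' @param sequence DNA sequence (>= 8 nt).
#' @param min_loop Minimum number of unpaired positions inside a hairpin
#'   loop.
#' @param wobble Allow G.T pairs (default `TRUE`).
#' @return An object of class `"structure_partition"`: list with
#'   `length`, `pairs` (two-column matrix of 1-based i < j pairs),
#'   `stem` (paired positions), `loop` (unpaired positions),
#'   `pairing` (integer vector, partner index or `NA`).
#' @examples
#' fold_hairpin("GGGGAAACCCC")
#' @export
fold_hairpin <- function(sequence, min_loop = 3L, wobble = TRUE) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stopifnot(n >= 8L)
  s <- strsplit(sequence, "")[[1]]
  can_pair <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (wobble && ((a == "G" && b == "T") || (a == "T" && b == "G")))
  }
  D <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- max(D[i + 1L, j], D[i, j - 1L])
      if (can_pair(s[i], s[j]))
        best <- max(best, D[i + 1L, j - 1L] + 1L)
      if (j > i + 1L) {
        for (k in i:(j - 1L)) {
          v <- D[i, k] + D[k + 1L, j]
          if (v > best) best <- v
        }
      }
      D[i, j] <- best
    }
  }
  pairing <- rep(NA_integer_, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (i >= j || j - i <= min_loop) next
    if (can_pair(s[i], s[j]) && D[i, j] == D[i + 1L, j - 1L] + 1L) {
      pairing[i] <- j; pairing[j] <- i
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
    } else if (D[i, j] == D[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    } else if (D[i, j] == D[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
    } else {
      for (k in i:(j - 1L)) {
        if (D[i, j] == D[i, k] + D[k + 1L, j]) {
          stack[[length(stack) + 1L]] <- c(i, k)
          stack[[length(stack) + 1L]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  paired <- which(!is.na(pairing))
  pairs <- cbind(i = paired[paired < pairing[paired]],
                 j = pairing[paired[paired < pairing[paired]]])
  structure(list(length = n, pairs = pairs, stem = paired,
                 loop = which(is.na(pairing)), pairing = pairing,
                 sequence = sequence),
            class = "structure_partition")
}

#' @export
print.structure_partition <- function(x, ...) {
  cat(sprintf("<structure_partition> %d nt: %d paired (stem), %d unpaired (loop)\n",
              x$length, length(x$stem), length(x$loop)))
  invisible(x)
}

#' Hairpin partition of the 42-nt GC-cluster consensus
#'
#' The maximum-pairing fold of [gc42_consensus()] (Watson-Crick pairs
#' only, minimum loop 3), giving the loop/stem site assignment used for
#' substitution-enrichment analyses of this element.
#' @return A `"structure_partition"` object.
#' @export
gc42_partition <- function() {
  fold_hairpin(gc42_consensus(), min_loop = 3L, wobble = FALSE)
}

#' Count substitutions split by structure partition
#'
#' A "change" is any position at which a homolog differs from the
#' consensus, counted per homolog and per site. Homologs whose length
#' differs from the consensus (indel-containing) are skipped with a
#' warning.
#'
#' @param homologs Character vector of homolog sequences.
#' @param consensus Consensus sequence.
#' @param partition A `"structure_partition"` (or list with `loop` and
#'   `stem` index vectors) for the consensus.
#' @return Named integer vector `c(loop = , stem = )`.
#' @export
count_partition_changes <- function(homologs, consensus, partition) {
  n <- nchar(consensus)
  ok <- nchar(homologs) == n
  if (any(!ok))
    warning(sum(!ok), " homolog(s) differ in length from the consensus; skipped")
  homologs <- toupper(homologs[ok])
  cons <- strsplit(toupper(consensus), "")[[1]]
  loop <- stem <- 0L
  for (h in homologs) {
    d <- which(strsplit(h, "")[[1]] != cons)
    loop <- loop + sum(d %in% partition$loop)
    stem <- stem + sum(d %in% partition$stem)
  }
  c(loop = loop, stem = stem)
}

#' Fisher test of loop versus stem substitution enrichment
#'
#' Two constructions of the 2x2 table are available because the count
#' data admit both. `"counts_vs_sites"` contrasts the change counts with
#' the site counts directly:
#' \preformatted{ [loop_changes, n_loop_sites]
#'  [stem_changes, n_stem_sites]}
#' `"opportunities"` contrasts changes with non-changes given the number
#' of homologs scored (each homolog x site is one opportunity):
#' \preformatted{ [loop_changes, n_loop_sites*n_homologs - loop_changes]
#'  [stem_changes, n_stem_sites*n_homologs - stem_changes]}
#'
#' @param loop_changes,stem_changes Substitution counts.
#' @param n_loop_sites,n_stem_sites Number of sites in each partition.
#' @param mode Table construction, see Details.
#' @param n_homologs Required for `"opportunities"`.
#' @return List of class `"enrichment_test"`: `p_value`, `mode`, `table`.
#' @export
partition_enrichment_test <- function(loop_changes, stem_changes,
                                      n_loop_sites, n_stem_sites,
                                      mode = c("counts_vs_sites",
                                               "opportunities"),
                                      n_homologs = NULL) {
  mode <- match.arg(mode)
  stopifnot(loop_changes >= 0, stem_changes >= 0,
            n_loop_sites >= 0, n_stem_sites >= 0)
  tab <- if (mode == "counts_vs_sites") {
    matrix(c(loop_changes, stem_changes, n_loop_sites, n_stem_sites), 2L, 2L)
  } else {
    stopifnot(!is.null(n_homologs))
    lo <- n_loop_sites * n_homologs
    so <- n_stem_sites * n_homologs
    stopifnot(loop_changes <= lo, stem_changes <= so)
    matrix(c(loop_changes, stem_changes,
             lo - loop_changes, so - stem_changes), 2L, 2L)
  }
  p <- if (all(tab == 0L)) 1 else fisher.test(tab)$p.value
  structure(list(p_value = p, mode = mode, table = tab),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("Fisher exact test (%s): p = %.3g\n", x$mode, x$p_value))
  invisible(x)
}

#' Average pairwise nucleotide diversity over a site set
#'
#' Mean over all sequence pairs of the per-site difference fraction
#' restricted to `site_set`.
#'
#' @param sequences >= 2 equal-length sequences.
#' @param site_set 1-based site indices (non-empty).
#' @return Average pairwise differences per site.
#' @export
nucleotide_diversity <- function(sequences, site_set) {
  stopifnot(length(sequences) >= 2L, length(unique(nchar(sequences))) == 1L)
  if (length(site_set) == 0L) stop("empty site set")
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  mat <- mat[, site_set, drop = FALSE]
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + mean(mat[i, ] != mat[j, ])
  tot / choose(n, 2L)
}

#' Element density inside indel regions versus the whole genome
#'
#' An element is "in" an indel region when its midpoint lies inside one
#' of the intervals. Densities are elements per kb.
#'
#' @param elements Data.frame with 0-based half-open `start`, `end`
#'   columns (element occurrences), or an empty data.frame.
#' @param indel_intervals Data.frame with `start`, `end` columns.
#' @param genome_length Genome length, nt.
#' @return Named numeric vector `c(density_indel = , density_genome = )`.
#' @export
indel_density <- function(elements, indel_intervals, genome_length) {
  stopifnot(genome_length > 0)
  total_iv <- if (nrow(indel_intervals)) {
    stopifnot(all(indel_intervals$end > indel_intervals$start),
              all(indel_intervals$start >= 0),
              all(indel_intervals$end <= genome_length))
    sum(indel_intervals$end - indel_intervals$start)
  } else 0
  n_elem <- nrow(elements)
  in_indel <- 0L
  if (n_elem > 0L && total_iv > 0) {
    mid <- (elements$start + elements$end) / 2
    for (m in mid) {
      if (any(m >= indel_intervals$start & m < indel_intervals$end))
        in_indel <- in_indel + 1L
    }
  }
  c(density_indel = if (total_iv > 0) in_indel / (total_iv / 1000) else 0,
    density_genome = n_elem / (genome_length / 1000))
}

#' Mann-Whitney U test (normal approximation)
#'
#' Two-sided Mann-Whitney U test via [stats::wilcox.test()] with the
#' normal approximation and tie correction, as used to compare element
#' densities in indel regions against whole-genome densities across
#' genome pairs.
#'
#' @param x,y Numeric samples.
#' @return List with `U` (the statistic for `x`) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' RPKM computation and reference-gene normalisation
#'
#' RPKM = count x 10^9 / (feature length x library total mapped reads).
#' After normalisation every library's RPKMs are scaled so that the
#' reference feature's RPKM equals its value in the first library, i.e.
#' libraries are made comparable on the reference gene.
#'
#' @param table Data.frame with columns `feature`, `library`, `count`,
#'   `length`; `total` (library total mapped reads) optional — computed
#'   as the per-library sum of `count` when absent.
#' @param reference Reference feature id present in every library with a
#'   positive count.
#' @return The input with `rpkm` and `rpkm_normalized` columns; the
#'   operation is idempotent on its own output.
#' @export
rpkm_normalize <- function(table, reference = "atp6") {
  stopifnot(all(c("feature", "library", "count", "length") %in% names(table)))
  libs <- unique(table$library)
  if (is.null(table$total)) {
    tot <- tapply(table$count, table$library, sum)
    table$total <- as.numeric(tot[table$library])
  }
  table$rpkm <- table$count * 1e9 / (table$length * table$total)
  ref_rpkm <- setNames(rep(NA_real_, length(libs)), libs)
  for (lb in libs) {
    r <- table$feature == reference & table$library == lb
    if (!any(r)) stop("reference feature '", reference,
                      "' absent from library ", lb)
    if (table$count[r][1L] <= 0) stop("reference feature has zero count in ",
                                      lb)
    ref_rpkm[lb] <- table$rpkm[r][1L]
  }
  factors <- ref_rpkm[[1L]] / ref_rpkm
  table$rpkm_normalized <- table$rpkm * as.numeric(factors[table$library])
  table
}
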