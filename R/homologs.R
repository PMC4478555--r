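## Relaxed homology search for an element family across genomes, flank
## anchoring of homologous positions, and presence/absence matrix
## construction.

#' Search a genome for homologs of an element query
#'
#' Candidate loci are found on both strands with Biostrings pattern
#' matching allowing mismatches and indels, then re-scored by a global
#' (query) / local (subject) alignment. A hit is kept when
#' identity = matches / alignment columns >= `min_identity` and
#' coverage = fraction of the query aligned to subject nucleotides
#' >= `min_coverage`. Overlapping hits are resolved best score first,
#' then leftmost. Circular genomes are scanned across the origin; hits
#' are reported with `start` in `[0, L)` and `end` possibly exceeding
#' `L` when the hit wraps.
#'
#' @param query Element sequence (>= 15 nt).
#' @param genome A [genome] object.
#' @param min_identity Minimum identity fraction.
#' @param min_coverage Minimum query coverage fraction.
#' @return Data.frame with columns `strain`, `start`, `end`, `strand`,
#'   `matched_sequence`, `identity`, `coverage`, `score`, sorted by
#'   `start`.
#' @export
search_homologs <- function(query, genome, min_identity = 0.90,
                            min_coverage = 0.95) {
  stopifnot(nchar(query) >= 15L, inherits(genome, "genome"))
  query <- toupper(query)
  L <- genome_length(genome)
  qlen <- nchar(query)
  budget <- max(1L, floor(qlen * (1 - min_identity)) +
                  floor(qlen * (1 - min_coverage)) + 1L)
  subj_seq <- genome$sequence
  if (genome$circular)
    subj_seq <- paste0(subj_seq, substr(subj_seq, 1L, qlen + budget))
  subj <- Biostrings::DNAString(subj_seq)
  qry <- Biostrings::DNAString(query)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)

  scan_strand <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subj, max.mismatch = budget,
                                  with.indels = TRUE)
    if (length(m) == 0L) return(NULL)
    out <- vector("list", length(m))
    for (i in seq_along(m)) {
      s0 <- max(1L, Biostrings::start(m)[i] - 3L)
      e0 <- min(length(subj), Biostrings::end(m)[i] + 3L)
      win <- subj[s0:e0]
      aln <- Biostrings::pairwiseAlignment(pattern, win,
                                           type = "global-local",
                                           substitutionMatrix = submat,
                                           gapOpening = 2, gapExtension = 1)
      cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      ident <- Biostrings::nmatch(aln) / cols
      sgaps <- sum(strsplit(as.character(Biostrings::alignedSubject(aln)),
                            "")[[1]] == "-")
      cover <- 1 - sgaps / qlen
      hs <- s0 + Biostrings::start(Biostrings::subject(aln)) - 2L  # 0-based
      he <- s0 + Biostrings::end(Biostrings::subject(aln)) - 1L
      out[[i]] <- data.frame(start = hs, end = he, strand = strand,
                             identity = ident, coverage = cover,
                             score = Biostrings::score(aln),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }

  hits <- rbind(scan_strand(qry, "+"),
                scan_strand(Biostrings::reverseComplement(qry), "-"))
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits(genome))
  hits <- hits[hits$identity >= min_identity & hits$coverage >= min_coverage, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(empty_hits(genome))
  ## map circular-extension hits back and drop duplicates of one locus
  hlen <- hits$end - hits$start
  hits$start <- hits$start %% L
  hits$end <- hits$start + hlen
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(hits))
  iv <- cbind(hits$start, hits$end)
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      kk <- which(keep)
      ok <- all(iv[i, 2L] <= iv[kk, 1L] | iv[i, 1L] >= iv[kk, 2L])
    }
    keep[i] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  data.frame(strain = genome$strain_id, start = hits$start, end = hits$end,
             strand = hits$strand,
             matched_sequence = vapply(seq_len(nrow(hits)), function(i)
               extract_interval(genome, hits$start[i],
                                if (hits$end[i] > L) hits$end[i] - L
                                else hits$end[i],
                                strand = hits$strand[i],
                                wraps = hits$end[i] > L), ""),
             identity = hits$identity, coverage = hits$coverage,
             score = hits$score, stringsAsFactors = FALSE)
}

empty_hits <- function(genome) {
  data.frame(strain = character(), start = integer(), end = integer(),
             strand = character(), matched_sequence = character(),
             identity = numeric(), coverage = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

## identity between two flank strings: hamming fast path on equal length,
## with an alignment fallback so that small boundary shifts between the
## compared windows are not scored as wholesale divergence
flank_identity <- function(a, b) {
  if (a == b) return(1)
  ham <- NA_real_
  if (nchar(a) == nchar(b)) {
    av <- charToRaw(a); bv <- charToRaw(b)
    ham <- sum(av == bv) / length(av)
    if (ham >= 0.9) return(ham)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 2, gapExtension = 1)
  gid <- Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
  max(ham, gid, na.rm = TRUE)
}

## step past contiguous GC-rich sequence starting at 0-based pos0 (or
## ending there when dir = -1): advance while the next 6-mer is GC-rich,
## then back off trailing A/T so the boundary sits at the cluster edge
skip_gc_run <- function(genome, pos0, dir = 1L, min_gc = 0.6, window = 8L) {
  L <- genome_length(genome)
  chars <- strsplit(genome$sequence, "")[[1]]
  at <- function(p) chars[(p %% L) + 1L]
  k <- 0L
  repeat {
    win <- vapply(0:(window - 1L), function(w)
      at(pos0 + dir * (k + w) - (dir < 0)), "")
    if (mean(win %in% c("G", "C")) < min_gc) break
    k <- k + 1L
    if (k > L) break
  }
  while (k > 0L && at(pos0 + dir * (k - 1L) - (dir < 0)) %in% c("A", "T"))
    k <- k - 1L
  pos0 + dir * k
}

## find one locus of `pattern` in genome; returns 0-based start or NA;
## staged mismatch budget keeps the common (near-exact) case fast
locate_flank <- function(pattern, genome, max_frac = 0.20) {
  subj <- Biostrings::DNAString(genome$sequence)
  pat <- Biostrings::DNAString(pattern)
  budgets <- c(unique(c(0L, ceiling(nchar(pattern) * c(0.10, max_frac)))),
               ceiling(nchar(pattern) * max_frac))
  indels <- c(rep(FALSE, length(budgets) - 1L), TRUE)
  for (bi in seq_along(budgets)) {
    b <- budgets[bi]
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = b,
                                  with.indels = indels[bi])
    if (length(m) == 1L)
      return(list(start = Biostrings::start(m) - 1L,
                  end = Biostrings::end(m)))
    if (length(m) > 1L) {
      ## distinct loci are ambiguous; stacked near-identical matches are
      ## the same locus
      st <- Biostrings::start(m)
      if (max(st) - min(st) <= nchar(pattern))
        return(list(start = st[1L] - 1L, end = Biostrings::end(m)[1L]))
      return("ambiguous")
    }
  }
  NULL
}

#' Anchor homologous element positions across strains
#'
#' Occurrences from different strains are merged into one homologous
#' position when both their upstream and downstream flanks align at
#' >= `flank_min_identity`. For strains without an occurrence, the
#' position's flank pair is searched in that strain's genome: when both
#' flanks are found adjacent (separated by less than twice the element
#' length) the state is `absent` with the between-flank residue recorded;
#' when the flanks cannot be located the state is `missing`. A strain
#' whose flanks match two distinct loci is ambiguous for that position
#' and is set to missing with a message; a position whose occurrences
#' include two loci from one strain is excluded entirely.
#'
#' @param occurrences Data.frame of hits from [search_homologs()] over
#'   several genomes (rows bound together).
#' @param genomes Named list of [genome] objects covering all strains in
#'   the analysis (not only those with occurrences).
#' @param flank Flank length, nt.
#' @param flank_min_identity Minimum flank identity for merging.
#' @param reference Strain used to order positions (default: first genome).
#' @return List of class `"homologous_positions"`; each element has
#'   `position_id`, `upstream_flank`, `downstream_flank`,
#'   `per_strain_state` (named: `"present"`, `"absent"`, `"missing"`),
#'   `per_strain_element`, `per_strain_residue` (between-flank sequence,
#'   including the single target-site copy, for non-missing strains),
#'   `per_strain_upstream`/`per_strain_downstream` (each strain's own
#'   flank sequences, for co-conversion analysis), `anchors` (data.frame
#'   of the member occurrences).
#' @export
anchor_positions <- function(occurrences, genomes, flank = 100L,
                             flank_min_identity = 0.80,
                             reference = names(genomes)[1L]) {
  stopifnot(is.data.frame(occurrences), length(genomes) >= 1L,
            !is.null(names(genomes)))
  strains <- names(genomes)
  if (nrow(occurrences) == 0L)
    return(structure(list(), class = "homologous_positions"))
  occ <- occurrences
  n <- nrow(occ)
  L <- vapply(genomes, genome_length, 0L)

  ## Flanks in element orientation, anchored at the residue boundary:
  ## the residue runs from the upstream target-site copy through the
  ## element and any contiguous GC-rich continuation (a merged cluster),
  ## so strains carrying stand-alone and merged forms of one position
  ## share the same backbone flanks.
  up <- character(n); down <- character(n); res <- character(n)
  for (i in seq_len(n)) {
    g <- genomes[[occ$strain[i]]]
    s <- occ$start[i]; e <- occ$end[i]  # e may exceed genome length (wrap)
    tl <- nchar(detect_tsd(g, s, e, occ$strand[i]))
    if (occ$strand[i] == "+") {
      rs <- s - tl
      re <- skip_gc_run(g, e, dir = 1L)
      up[i] <- circ_substr(g, rs - flank, rs)
      down[i] <- circ_substr(g, re, re + flank)
      res[i] <- circ_substr(g, rs, re)
    } else {
      rs <- e + tl                       # residue 5' end, genomic right
      re <- skip_gc_run(g, s, dir = -1L) # residue 3' end, genomic left
      up[i] <- revcomp(circ_substr(g, rs, rs + flank))
      down[i] <- revcomp(circ_substr(g, re - flank, re))
      res[i] <- revcomp(circ_substr(g, re, rs))
    }
  }

  ## single-linkage clustering on joint flank identity
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (flank_identity(up[i], up[j]) >= flank_min_identity &&
          flank_identity(down[i], down[j]) >= flank_min_identity) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  groups <- unname(split(seq_len(n), vapply(seq_len(n), find, 0L)))

  ## order positions by first occurrence in the reference strain, then by
  ## the first member strain's coordinate
  gkey <- vapply(groups, function(g) {
    r <- which(occ$strain[g] == reference)
    if (length(r)) min(occ$start[g][r]) else
      1e9 + min(occ$start[g])
  }, 0)
  groups <- groups[order(gkey)]

  positions <- list()
  for (g in groups) {
    if (anyDuplicated(occ$strain[g])) {
      message("position with two loci in strain ",
              occ$strain[g][duplicated(occ$strain[g])][1L],
              " is ambiguous; excluded")
      next
    }
    ## flank reference: the member with the shortest residue, i.e. a
    ## stand-alone element rather than a merged cluster, so the
    ## downstream pattern is backbone sequence that every strain carries
    ref_i <- g[order(nchar(res[g]), occ$strain[g])[1L]]
    upf <- up[ref_i]; downf <- down[ref_i]
    elen <- max(occ$end[g] - occ$start[g])
    state <- setNames(rep("missing", length(strains)), strains)
    elem <- setNames(rep(NA_character_, length(strains)), strains)
    residue <- setNames(rep(NA_character_, length(strains)), strains)
    up_st <- setNames(rep(NA_character_, length(strains)), strains)
    down_st <- setNames(rep(NA_character_, length(strains)), strains)
    for (i in g) {
      st <- occ$strain[i]
      state[st] <- "present"
      elem[st] <- occ$matched_sequence[i]
      residue[st] <- res[i]
      ## flanks aligned to the reference patterns (a merged strain's own
      ## greedy boundary can sit a few bases off); fall back to the
      ## strain's own boundary flanks when the patterns cannot be placed
      lu <- locate_flank(upf, genomes[[st]])
      ld <- locate_flank(downf, genomes[[st]])
      ok <- function(x) !is.null(x) && !identical(x, "ambiguous")
      up_st[st] <- if (ok(lu))
        circ_substr(genomes[[st]], lu$start, lu$end) else up[i]
      down_st[st] <- if (ok(ld))
        circ_substr(genomes[[st]], ld$start, ld$end) else down[i]
    }
    for (st in setdiff(strains, occ$strain[g])) {
      gst <- genomes[[st]]
      lu <- locate_flank(upf, gst)
      ld <- locate_flank(downf, gst)
      if (identical(lu, "ambiguous") || identical(ld, "ambiguous")) {
        message("flanks of a position match two loci in strain ", st,
                "; state set to missing")
        next
      }
      if (is.null(lu) || is.null(ld)) next
      gap <- ld$start - lu$end
      ## a slightly negative gap means the fuzzy matches overlap at an
      ## empty site; a strongly negative one is an origin wrap
      if (gap < 0 && gap >= -10L) gap <- 0L
      if (gap < 0 && gst$circular) gap <- gap + genome_length(gst)
      if (gap >= 0 && gap < 2L * elen) {
        state[st] <- "absent"
        residue[st] <- if (gap == 0L) "" else
          circ_substr(gst, lu$end, lu$end + gap)
        up_st[st] <- circ_substr(gst, lu$start, lu$end)
        down_st[st] <- circ_substr(gst, ld$start, ld$end)
      }
    }
    positions[[length(positions) + 1L]] <-
      list(position_id = NA_character_, upstream_flank = upf,
           downstream_flank = downf, per_strain_state = state,
           per_strain_element = elem, per_strain_residue = residue,
           per_strain_upstream = up_st, per_strain_downstream = down_st,
           anchors = occ[g, c("strain", "start", "end", "strand"),
                         drop = FALSE])
  }
  for (i in seq_along(positions))
    positions[[i]]$position_id <- sprintf("pos%03d", i)
  structure(positions, class = "homologous_positions")
}

## circular-aware substring, 0-based half-open, offsets may fall outside
## [0, L)
circ_substr <- function(genome, start, end) {
  L <- genome_length(genome)
  idx <- ((seq.int(start, end - 1L) %% L) + 1L)
  paste(strsplit(genome$sequence, "")[[1]][idx], collapse = "")
}

#' @export
print.homologous_positions <- function(x, ...) {
  cat(sprintf("<homologous_positions> %d position%s\n", length(x),
              if (length(x) == 1L) "" else "s"))
  for (p in head(x, 10L)) {
    tab <- table(factor(p$per_strain_state,
                        levels = c("present", "absent", "missing")))
    cat(sprintf("  %s: %d present / %d absent / %d missing\n",
                p$position_id, tab[["present"]], tab[["absent"]],
                tab[["missing"]]))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Build the presence/absence matrix from anchored positions
#'
#' @param positions A `"homologous_positions"` list from
#'   [anchor_positions()].
#' @param strains Strain order for the columns.
#' @return Integer matrix, positions x strains, 1 = present, 0 = absent,
#'   `NA` = missing. All-missing rows are dropped.
#' @export
build_pa_matrix <- function(positions, strains) {
  stopifnot(length(positions) >= 1L)
  mat <- t(vapply(positions, function(p) {
    s <- p$per_strain_state[strains]
    ifelse(s == "present", 1L, ifelse(s == "absent", 0L, NA_integer_))
  }, integer(length(strains))))
  dimnames(mat) <- list(vapply(positions, `[[`, "", "position_id"), strains)
  mat[rowSums(!is.na(mat)) > 0L, , drop = FALSE]
}
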