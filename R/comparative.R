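## Per-position comparative analyses: residue classification (clean
## absence, footprint, stand-alone, merged, subunit), co-conversion
## tract detection, prefix-sharing cluster families, and cross-species
## horizontal-exchange calls supported by a flank neighbour-joining tree.

#' Classify the per-strain residue at a homologous position
#'
#' The residue is the sequence between the anchored flanks, including the
#' single upstream copy of the target-site nucleotides. Categories:
#' \describe{
#'   \item{absent_clean}{residue is exactly one copy of the target-site
#'     nucleotides.}
#'   \item{standalone}{one element unit (>= `identity_threshold` identity
#'     to `unit`, similar length).}
#'   \item{merged}{an element unit followed by additional contiguous
#'     GC-rich sequence (>= `merged_min_extra` nt, GC > `merged_min_gc`).}
#'   \item{subunit}{a proper sub-segment of the unit listed in
#'     `subunits` (e.g. the unit's 18-nt 3' terminus).}
#'   \item{footprint}{any other element fragment bounded by two copies of
#'     the target-site nucleotides.}
#'   \item{other}{unclassifiable residue (evidence retained).}
#' }
#'
#' @param residues Named character vector, strain -> between-flank
#'   residue (`NA` for strains with missing state).
#' @param tsd Target-site nucleotides.
#' @param unit Element unit sequence (ending with `tsd`).
#' @param subunits Optional character vector of known smaller units.
#' @param identity_threshold Identity required to call a unit match.
#' @param merged_min_extra,merged_min_gc Thresholds for the extra
#'   GC-rich segment of a merged cluster.
#' @return Data.frame with columns `strain`, `category`, `evidence`.
#' @export
classify_position <- function(residues, tsd, unit, subunits = character(),
                              identity_threshold = 0.90,
                              merged_min_extra = 10L, merged_min_gc = 0.50) {
  stopifnot(!is.null(names(residues)), nzchar(tsd))
  unit <- toupper(unit); tsd <- toupper(tsd)
  ulen <- nchar(unit)
  one <- function(res) {
    if (is.na(res)) return(c(NA_character_, "state missing"))
    res <- toupper(res)
    if (res == tsd) return(c("absent_clean", "single target-site copy"))
    if (!startsWith(res, tsd))
      return(c("other", paste0("residue does not start with TSD: ",
                               substr(res, 1L, 20L))))
    core <- substr(res, nchar(tsd) + 1L, nchar(res))
    if (!nzchar(core)) return(c("absent_clean", "single target-site copy"))
    clen <- nchar(core)
    ## full unit?
    if (abs(clen - ulen) <= ceiling(0.1 * ulen) &&
        seq_identity_short(core, unit) >= identity_threshold)
      return(c("standalone",
               sprintf("unit match, identity %.2f",
                       seq_identity_short(core, unit))))
    ## unit + extra GC-rich segment?
    if (clen >= ulen + merged_min_extra) {
      head_part <- substr(core, 1L, ulen)
      extra <- substr(core, ulen + 1L, clen)
      if (seq_identity_short(head_part, unit) >= identity_threshold &&
          gc_fraction(extra) > merged_min_gc)
        return(c("merged",
                 sprintf("unit + %d nt extra segment (GC %.0f%%): %s",
                         nchar(extra), 100 * gc_fraction(extra), extra)))
    }
    ## known smaller unit?
    for (su in toupper(subunits)) {
      if (abs(clen - nchar(su)) <= ceiling(0.1 * nchar(su)) &&
          seq_identity_short(core, su) >= identity_threshold)
        return(c("subunit", paste0("matches subunit ", su)))
    }
    ## fragment of the unit with a second TSD copy?
    if (clen < ulen && endsWith(core, tsd)) {
      frag <- substr(core, 1L, clen - nchar(tsd))
      if (!nzchar(frag) ||
          grepl(frag, unit, fixed = TRUE) ||
          seq_identity_short(frag, substr(unit, 1L, nchar(frag))) >= 0.8)
        return(c("footprint",
                 sprintf("%d nt fragment with two target-site copies", clen)))
    }
    c("other", paste0("unrecognised residue: ", substr(res, 1L, 30L)))
  }
  out <- t(vapply(residues, one, character(2L)))
  data.frame(strain = names(residues), category = out[, 1L],
             evidence = out[, 2L], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Detect co-conversion tract sites in the flanks of a position
#'
#' A flank alignment column is called as part of the co-conversion tract
#' when element presence/absence perfectly partitions its alleles: all
#' present strains share one base, all absent strains share a different
#' one. Calls are restricted to within `window` nt of the element
#' boundary. Requires at least `min_informative` present and
#' `min_informative` absent strains.
#'
#' @param states Named vector, strain -> 1/0 (or "present"/"absent");
#'   missing strains excluded beforehand.
#' @param upstream,downstream Named character vectors of equal-length
#'   aligned flank sequences per strain (upstream ends at the element
#'   boundary; downstream starts at it).
#' @param window Tract search width on each side, nt.
#' @param min_informative Minimum strains per state class.
#' @param perfect Require a perfect partition (default). When `FALSE`, a
#'   site is called when the majority alleles differ and the association
#'   fraction is >= 0.9.
#' @return List of class `"coconversion_call"`: `sites` (data.frame
#'   `offset` — negative upstream —, `present_allele`, `absent_allele`,
#'   `association`), `reason` (why empty, or `NA`).
#' @export
detect_coconversion <- function(states, upstream, downstream, window = 30L,
                                min_informative = 2L, perfect = TRUE) {
  st <- states
  if (is.character(st)) st <- ifelse(st == "present", 1L,
                                     ifelse(st == "absent", 0L, NA))
  st <- st[!is.na(st)]
  pres <- names(st)[st == 1L]
  abs_ <- names(st)[st == 0L]
  empty <- function(reason)
    structure(list(sites = data.frame(offset = integer(),
                                      present_allele = character(),
                                      absent_allele = character(),
                                      association = numeric()),
                   reason = reason), class = "coconversion_call")
  if (length(pres) < min_informative || length(abs_) < min_informative)
    return(empty("insufficient strains in one state class"))
  stopifnot(all(c(pres, abs_) %in% names(upstream)),
            all(c(pres, abs_) %in% names(downstream)))
  scan_side <- function(flanks, side) {
    fl <- flanks[c(pres, abs_)]
    ## strains whose flank length deviates (indel-containing) cannot be
    ## placed in the ungapped alignment; drop them from the scan
    modal <- as.integer(names(which.max(table(nchar(fl)))))
    fl <- fl[nchar(fl) == modal]
    if (sum(names(fl) %in% pres) < min_informative ||
        sum(names(fl) %in% abs_) < min_informative) return(NULL)
    w <- min(window, modal)
    mat <- do.call(rbind, strsplit(toupper(fl), ""))
    rownames(mat) <- names(fl)
    pres_k <- intersect(names(fl), pres)
    abs_k <- intersect(names(fl), abs_)
    ncolf <- ncol(mat)
    cols <- if (side == "up") (ncolf - w + 1L):ncolf else 1L:w
    offs <- if (side == "up") -(w:1L) else 1L:w
    res <- list()
    for (ci in seq_along(cols)) {
      colv <- mat[, cols[ci]]
      pa <- colv[pres_k]; ab <- colv[abs_k]
      if (perfect) {
        if (length(unique(pa)) == 1L && length(unique(ab)) == 1L &&
            pa[1L] != ab[1L])
          res[[length(res) + 1L]] <-
            data.frame(offset = offs[ci], present_allele = pa[1L],
                       absent_allele = ab[1L], association = 1,
                       stringsAsFactors = FALSE)
      } else {
        mp <- names(which.max(table(pa))); ma <- names(which.max(table(ab)))
        assoc <- (sum(pa == mp) + sum(ab == ma)) / (length(pa) + length(ab))
        if (mp != ma && assoc >= 0.9)
          res[[length(res) + 1L]] <-
            data.frame(offset = offs[ci], present_allele = mp,
                       absent_allele = ma, association = assoc,
                       stringsAsFactors = FALSE)
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  }
  sites <- rbind(scan_side(upstream, "up"), scan_side(downstream, "down"))
  if (is.null(sites)) return(empty("no associated site"))
  structure(list(sites = sites[order(sites$offset), , drop = FALSE],
                 reason = NA_character_),
            class = "coconversion_call")
}

#' @export
print.coconversion_call <- function(x, ...) {
  if (nrow(x$sites) == 0L) {
    cat("<coconversion_call> no sites (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("<coconversion_call> %d tract site(s) at offsets %s\n",
                nrow(x$sites), paste(x$sites$offset, collapse = ", ")))
  }
  invisible(x)
}

#' Scan genomes for GC clusters sharing a 5' prefix
#'
#' Locates exact occurrences of `prefix` on both strands, extends each
#' through contiguous GC-rich sequence (extension continues while the
#' next `lookahead` nucleotides have GC fraction >= `min_gc`, then
#' trailing A/T are trimmed), and groups identical full sequences into
#' types.
#'
#' @param genomes Named list of [genome] objects.
#' @param prefix Shared 5' prefix (>= 8 nt).
#' @param min_gc GC threshold for extension.
#' @param lookahead Extension lookahead window, nt.
#' @return List with `types` (data.frame `sequence`, `length`,
#'   `n_copies`, `n_strains`, sorted by length then sequence) and
#'   `by_length` (data.frame `length`, `n_types`).
#' @export
prefix_family_scan <- function(genomes, prefix, min_gc = 0.50,
                               lookahead = 6L) {
  stopifnot(nchar(prefix) >= 8L)
  prefix <- toupper(prefix)
  occs <- list()
  for (g in genomes) {
    L <- genome_length(g)
    chars <- strsplit(g$sequence, "")[[1]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") prefix else revcomp(prefix)
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                    Biostrings::DNAString(g$sequence))
      for (st in Biostrings::start(m)) {
        ## extend 3' (element orientation) through GC-rich sequence
        at <- function(pos0) chars[(pos0 %% L) + 1L]
        if (strand == "+") {
          e <- st - 1L + nchar(prefix)  # 0-based, first base after prefix
          step <- function(k) at(e + k)
        } else {
          e <- st - 2L                  # 0-based, base before the match
          step <- function(k) comp(at(e - k))
        }
        ext <- character(0)
        k <- 0L
        repeat {
          look <- vapply(k:(k + lookahead - 1L), step, "")
          if (mean(look %in% c("G", "C")) < min_gc) break
          ext <- c(ext, step(k))
          k <- k + 1L
          if (k > L) break
        }
        full <- paste0(prefix, paste(ext, collapse = ""))
        full <- sub("[AT]+$", "", full)
        occs[[length(occs) + 1L]] <-
          data.frame(strain = g$strain_id, sequence = full,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(occs) == 0L)
    return(list(types = data.frame(sequence = character(), length = integer(),
                                   n_copies = integer(), n_strains = integer()),
                by_length = data.frame(length = integer(),
                                       n_types = integer())))
  occ <- do.call(rbind, occs)
  types <- do.call(rbind, lapply(split(occ, occ$sequence), function(d)
    data.frame(sequence = d$sequence[1L], length = nchar(d$sequence[1L]),
               n_copies = nrow(d), n_strains = length(unique(d$strain)),
               stringsAsFactors = FALSE)))
  types <- types[order(types$length, types$sequence), , drop = FALSE]
  rownames(types) <- NULL
  bl <- as.data.frame(table(types$length), stringsAsFactors = FALSE)
  names(bl) <- c("length", "n_types")
  bl$length <- as.integer(bl$length)
  list(types = types, by_length = bl)
}

#' Neighbour-joining tree from an alignment
#'
#' Jukes-Cantor distances and neighbour joining via \pkg{ape}. Input
#' sequences are sorted by label first, so the result does not depend on
#' input order.
#'
#' @param sequences Named character vector of aligned, equal-length
#'   sequences (>= 3).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(sequences) {
  stopifnot(length(sequences) >= 3L, !is.null(names(sequences)),
            length(unique(nchar(sequences))) == 1L)
  sequences <- sequences[order(names(sequences))]
  mat <- do.call(rbind, strsplit(tolower(sequences), ""))
  rownames(mat) <- names(sequences)
  d <- ape::dist.dna(ape::as.DNAbin(mat), model = "JC69",
                     pairwise.deletion = TRUE)
  d[is.na(d) | !is.finite(d)] <- 0
  ape::nj(d)
}

#' Flag horizontal exchange of an element between species
#'
#' A strain is flagged as a recipient from another species when both
#' criteria hold: (i) its element is strictly closer to the other
#' species' element consensus than to its own species' consensus, by at
#' least `margin` identity; and (ii) a neighbour-joining tree of the
#' concatenated ±flank sequences places the strain inside the other
#' species' clade (the other species' tips plus the candidate set are
#' monophyletic). A species with fewer than 2 elements has no consensus;
#' criterion (i) is then skipped for comparisons against it and the
#' strain is reported unflagged.
#'
#' @param elements Named character vector, strain -> element sequence at
#'   the position (`NA` when absent/missing).
#' @param species_map Named character vector, strain -> species.
#' @param upstream,downstream Named character vectors of aligned flank
#'   sequences per strain (used for the flank tree).
#' @param margin Minimum identity difference (fraction) for criterion (i).
#' @return Data.frame with one row per strain carrying the element:
#'   `strain`, `species`, `other_species`, `identity_own`,
#'   `identity_other`, `closer_to_other`, `flank_support`, `flagged`.
#' @export
classify_transfer <- function(elements, species_map, upstream, downstream,
                              margin = 0.02) {
  carriers <- names(elements)[!is.na(elements)]
  stopifnot(length(carriers) >= 1L, all(carriers %in% names(species_map)))
  species <- unique(unname(species_map[carriers]))
  if (length(species) < 2L)
    stop("position must span at least two species")
  cons <- list()
  for (sp in species) {
    el <- elements[carriers[species_map[carriers] == sp]]
    cons[[sp]] <- if (length(el) >= 2L) consensus_sequence(el) else NULL
  }
  flank_strains <- intersect(names(upstream), names(downstream))
  flanks <- setNames(paste0(toupper(upstream[flank_strains]),
                            toupper(downstream[flank_strains])),
                     flank_strains)
  tree <- if (length(flanks) >= 3L) nj_tree(flanks) else NULL

  rows <- list()
  for (st in carriers) {
    own <- unname(species_map[st])
    other <- setdiff(species, own)[1L]
    id_own <- if (!is.null(cons[[own]]))
      seq_identity_short(elements[[st]], cons[[own]]) else NA_real_
    id_other <- if (!is.null(cons[[other]]))
      seq_identity_short(elements[[st]], cons[[other]]) else NA_real_
    closer <- !is.na(id_own) && !is.na(id_other) &&
      (id_other - id_own >= margin)
    rows[[st]] <- data.frame(strain = st, species = own,
                             other_species = other,
                             identity_own = id_own,
                             identity_other = id_other,
                             closer_to_other = closer,
                             flank_support = FALSE, flagged = FALSE,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(tree)) {
    for (sp in species) {
      cand <- out$strain[out$closer_to_other & out$species == sp]
      if (length(cand) == 0L) next
      other <- setdiff(species, sp)[1L]
      other_tips <- intersect(names(flanks),
                              names(species_map)[species_map == other])
      supported <- logical(length(cand))
      grp <- c(other_tips, cand)
      if (all(grp %in% tree$tip.label) &&
          length(grp) < length(tree$tip.label) &&
          ape::is.monophyletic(tree, grp)) {
        supported[] <- TRUE
      } else {
        for (i in seq_along(cand)) {
          grp1 <- c(other_tips, cand[i])
          supported[i] <- all(grp1 %in% tree$tip.label) &&
            length(grp1) < length(tree$tip.label) &&
            ape::is.monophyletic(tree, grp1)
        }
      }
      out$flank_support[match(cand, out$strain)] <- supported
    }
  }
  out$flagged <- out$closer_to_other & out$flank_support
  out
}

## column-majority consensus of equal-length sequences (modal length is
## used when lengths differ); ties resolve in A,C,G,T order
consensus_sequence <- function(sequences) {
  sequences <- toupper(sequences[!is.na(sequences)])
  lens <- nchar(sequences)
  modal <- as.integer(names(which.max(table(lens))))
  sequences <- sequences[lens == modal]
  mat <- do.call(rbind, strsplit(sequences, ""))
  paste(apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)]
  }), collapse = "")
}
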