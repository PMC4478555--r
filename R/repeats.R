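## Dispersed-repeat detection in a single genome: maximal exact repeats
## found by seeding on duplicated min_len-mers and extending each
## occurrence group as far as all copies stay identical, followed by a
## deterministic target-site-duplication boundary trim, GC filtering,
## single-linkage clustering into families, and family statistics.

#' Find GC-rich dispersed repeats in one genome
#'
#' Seeds on every duplicated `min_len`-mer (both strands when
#' `both_strands`, canonicalised so a copy and its reverse complement are
#' one occurrence), extends each occurrence group maximally while all
#' copies remain identical, trims a leading target-site-duplication copy
#' when the extended repeat begins with a tandem of its own terminal
#' nucleotides (see Details), removes repeats wholly contained in longer
#' ones, filters on GC content, and groups the remaining exact-copy sets
#' into families with [cluster_copies()].
#'
#' @details The boundary convention replaces manual inspection with a
#' deterministic rule: if the extended repeat starts with `k` nucleotides
#' (`2 <= k <= max_tsd`) that equal both the following `k` nucleotides and
#' the final `k` nucleotides, the leading `k`-mer is taken to be the
#' upstream copy of the target-site duplication and is trimmed, so that
#' the reported element starts at the duplicated target site and ends
#' with it.
#'
#' @param genome A [genome] object.
#' @param min_len Minimum repeat length (nt).
#' @param min_gc Minimum GC fraction of a family representative.
#' @param cluster_identity,cluster_coverage Thresholds passed to
#'   [cluster_copies()].
#' @param both_strands Count reverse-strand copies.
#' @param max_tsd Longest target-site duplication considered.
#' @return A list of class `"repeat_families"`: one element per family,
#'   each a list with `family_id`, `representative`, `length`, `n_copies`,
#'   `tsd`, `gc_percent`, and `copies` (data.frame `strain`, `start`,
#'   `end`, `strand`, `family_id`, `identity`; 0-based half-open, `end`
#'   may exceed the genome length for origin-wrapping copies). Families
#'   are sorted by copy count, then length, then representative.
#' @export
find_dispersed_repeats <- function(genome, min_len = 30L, min_gc = 0.30,
                                   cluster_identity = 1.0,
                                   cluster_coverage = 0.70,
                                   both_strands = TRUE, max_tsd = 4L) {
  stopifnot(inherits(genome, "genome"), min_len >= 8L)
  L <- genome_length(genome)
  if (L < 2L * min_len + 1L) {
    warning("genome shorter than twice min_len; no repeats reported")
    return(structure(list(), class = "repeat_families"))
  }
  seq <- genome$sequence
  chars <- strsplit(seq, "")[[1]]
  circ <- isTRUE(genome$circular)
  scan_seq <- if (circ) paste0(seq, substr(seq, 1L, min_len - 1L)) else seq
  nwin <- if (circ) L else L - min_len + 1L
  windows <- substring(scan_seq, seq_len(nwin), seq_len(nwin) + min_len - 1L)
  valid <- !grepl("N", windows, fixed = TRUE)
  ## Seed only on windows at or above the GC threshold: any repeat whose
  ## overall GC fraction reaches min_gc contains at least one window at
  ## or above its own mean, so no qualifying family is lost, while the
  ## AT-rich background (and low-complexity runs) stop generating seed
  ## groups.
  if (any(valid)) {
    wgc <- Biostrings::letterFrequency(
      Biostrings::DNAStringSet(windows[valid]), "GC", as.prob = TRUE)[, 1L]
    valid[valid] <- wgc >= min_gc
  }

  keys <- windows
  strands <- rep("+", nwin)
  if (both_strands && any(valid)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(windows[valid])))
    flip <- rc < windows[valid]
    keys[valid][flip] <- rc[flip]
    strands[valid][flip] <- "-"
  }
  keys[!valid] <- NA

  grp <- split(seq_len(nwin), keys)
  grp <- grp[lengths(grp) >= 2L]
  if (length(grp) == 0L) return(structure(list(), class = "repeat_families"))

  ## circular character lookup, 0-based offset
  at <- function(pos0) chars[(pos0 %% L) + 1L]

  ## maximal extension of one occurrence group; occurrences given as
  ## 0-based start of the window and strand relative to the canonical key
  extend_group <- function(starts0, strand) {
    len <- min_len
    off5 <- 0L  # extension upstream of the canonical 5' end
    ## position (0-based, genomic) of canonical offset i for occurrence k:
    ## "+": starts0 + i ; "-": starts0 + (min_len - 1) - i
    base_at <- function(k, i) {
      if (strand[k] == "+") at(starts0[k] + i)
      else comp(at(starts0[k] + min_len - 1L - i))
    }
    n <- length(starts0)
    repeat {  # 5' extension
      i <- -off5 - 1L
      b <- vapply(seq_len(n), base_at, "", i = i)
      if (len + off5 + 1L > L || b[1L] == "N" || length(unique(b)) != 1L) break
      off5 <- off5 + 1L
    }
    off3 <- 0L
    repeat {  # 3' extension
      i <- min_len + off3
      b <- vapply(seq_len(n), base_at, "", i = i)
      if (len + off5 + off3 + 1L > L || b[1L] == "N" ||
          length(unique(b)) != 1L) break
      off3 <- off3 + 1L
    }
    len <- min_len + off5 + off3
    ## genomic starts of the extended repeat (canonical orientation)
    gstart <- ifelse(strand == "+", starts0 - off5, starts0 - off3)
    gstart <- gstart %% L
    rep_seq <- paste(vapply(seq_len(len) - 1L, function(i)
      if (strand[1L] == "+") at(gstart[1L] + i)
      else comp(at(gstart[1L] + len - 1L - i)), ""), collapse = "")
    list(seq = rep_seq, start = gstart, strand = strand, len = len)
  }

  cands <- list()
  seen <- new.env(parent = emptyenv())
  for (key in names(grp)) {
    idx <- grp[[key]]
    starts0 <- idx - 1L
    strand <- strands[idx]
    ## palindromic windows: "+" and "-" readings at one locus collapse
    dup <- duplicated(starts0)
    starts0 <- starts0[!dup]; strand <- strand[!dup]
    if (length(starts0) < 2L) next
    ext <- extend_group(starts0, strand)
    if (ext$len < min_len) next
    o <- order(ext$start)
    sig <- paste(ext$seq, paste(ext$start[o], ext$strand[o], collapse = ";"))
    if (!is.null(seen[[sig]])) next
    seen[[sig]] <- TRUE
    cands[[length(cands) + 1L]] <- ext
  }
  if (length(cands) == 0L) return(structure(list(), class = "repeat_families"))

  ## Overlapping candidates compete for the same loci: a chance flank
  ## extension shared by a few copies yields a longer, rarer candidate,
  ## and a sub-segment shared between near-identical families yields a
  ## shorter, commoner one. Resolve by greedy cover: repeatedly select
  ## the candidate explaining the most uncovered repeat sequence
  ## (uncovered copies x length), marking a copy covered when its
  ## midpoint falls inside a selected occurrence.
  kept <- list()
  covered <- matrix(numeric(0), ncol = 2L)  # selected occurrence intervals
  uncov <- function(cd) {
    mids <- cd$start + cd$len / 2
    if (nrow(covered) == 0L) return(rep(TRUE, length(mids)))
    vapply(mids, function(m)
      !any(m >= covered[, 1L] & m < covered[, 2L]), TRUE)
  }
  repeat {
    nu <- vapply(cands, function(cd) sum(uncov(cd)), 0L)
    live <- which(nu >= 2L)
    if (length(live) == 0L) break
    lens <- vapply(cands, `[[`, 0L, "len")
    score <- nu * lens
    pick <- live[order(-score[live], -nu[live], -lens[live],
                       vapply(cands[live], `[[`, "", "seq"))[1L]]
    cd <- cands[[pick]]
    sel <- uncov(cd)
    cd$start <- cd$start[sel]; cd$strand <- cd$strand[sel]
    kept[[length(kept) + 1L]] <- cd
    covered <- rbind(covered, cbind(cd$start, cd$start + cd$len))
    cands <- cands[-pick]
  }
  ## deterministic TSD boundary trim on the selected units
  kept <- lapply(kept, function(cd) {
    trimmed <- trim_tsd_boundary(cd$seq, max_tsd)
    if (trimmed > 0L && cd$len - trimmed >= min_len) {
      cd$start <- ifelse(cd$strand == "+", (cd$start + trimmed) %% L,
                         cd$start)
      cd$len <- cd$len - trimmed
      cd$seq <- substr(cd$seq, trimmed + 1L, nchar(cd$seq))
    }
    cd
  })
  kept <- Filter(function(cd) gc_fraction(cd$seq) >= min_gc, kept)
  if (length(kept) == 0L) return(structure(list(), class = "repeat_families"))

  ## single-linkage clustering of the exact-copy sets into families
  seqs <- vapply(kept, `[[`, "", "seq")
  groups <- cluster_copies(seqs, identity = cluster_identity,
                           coverage = cluster_coverage)
  fams <- lapply(groups, function(g) {
    members <- kept[g]
    ncop <- vapply(members, function(m) length(m$start), 0L)
    pick <- order(-ncop, -vapply(members, `[[`, 0L, "len"),
                  vapply(members, `[[`, "", "seq"))[1L]
    rep_seq <- members[[pick]]$seq
    occ <- do.call(rbind, lapply(members, function(m)
      data.frame(strain = genome$strain_id, start = m$start,
                 end = m$start + m$len, strand = m$strand,
                 identity = 1.0, stringsAsFactors = FALSE)))
    occ <- occ[order(occ$start), , drop = FALSE]
    tsds <- vapply(seq_len(nrow(occ)), function(r)
      detect_tsd(genome, occ$start[r], occ$end[r], occ$strand[r],
                 max_tsd = max_tsd), "")
    tsd <- names(sort(table(tsds[nzchar(tsds)]), decreasing = TRUE))[1L] %||%
      ""
    if (is.na(tsd)) tsd <- ""
    list(representative = rep_seq, length = nchar(rep_seq),
         n_copies = nrow(occ), tsd = tsd,
         gc_percent = gc_percent_trimmed(rep_seq, tsd), copies = occ)
  })
  ord <- order(-vapply(fams, `[[`, 0L, "n_copies"),
               -vapply(fams, `[[`, 0L, "length"),
               vapply(fams, `[[`, "", "representative"))
  fams <- fams[ord]
  for (i in seq_along(fams)) {
    fams[[i]]$family_id <- sprintf("fam%03d", i)
    fams[[i]]$copies$family_id <- fams[[i]]$family_id
  }
  structure(fams, class = "repeat_families")
}

#' @export
print.repeat_families <- function(x, n = 10L, ...) {
  cat(sprintf("<repeat_families> %d famil%s\n", length(x),
              if (length(x) == 1L) "y" else "ies"))
  for (f in head(x, n)) {
    cat(sprintf("  %s: %d nt x %d copies, GC%% %.1f, TSD '%s'\n",
                f$family_id, f$length, f$n_copies, f$gc_percent, f$tsd))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

comp <- function(b) chartr("ACGTN", "TGCAN", b)

## trim a leading TSD copy: largest k in [2, max_tsd] with
## prefix(k) == next k bases == suffix(k)
trim_tsd_boundary <- function(seq, max_tsd = 4L) {
  n <- nchar(seq)
  for (k in seq(from = min(max_tsd, floor((n - 1L) / 2L)), to = 2L)) {
    if (k < 2L) break
    pre <- substr(seq, 1L, k)
    nxt <- substr(seq, k + 1L, 2L * k)
    suf <- substr(seq, n - k + 1L, n)
    if (pre == nxt && pre == suf) return(k)
  }
  0L
}

#' Group sequences by identity and length coverage (single linkage)
#'
#' Two sequences are linked when their global identity computed over the
#' shorter sequence is at least `identity` and the shorter/longer length
#' ratio is at least `coverage`; groups are the transitive closure of the
#' links.
#'
#' @param sequences Character vector of DNA sequences.
#' @param identity Minimum identity (fraction of the shorter sequence).
#' @param coverage Minimum shorter/longer length ratio.
#' @return A list of integer index vectors, one per group.
#' @export
cluster_copies <- function(sequences, identity = 1.0, coverage = 0.70) {
  n <- length(sequences)
  stopifnot(n >= 1L, identity > 0, identity <= 1, coverage > 0, coverage <= 1)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    lens <- nchar(sequences)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      lr <- min(lens[i], lens[j]) / max(lens[i], lens[j])
      if (lr < coverage) next
      if (seq_identity_short(sequences[i], sequences[j]) >= identity) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(split(seq_len(n), roots))
}

## global identity over the shorter sequence: matches in a global
## alignment of the shorter within the longer, divided by the shorter
## length
seq_identity_short <- function(a, b) {
  if (a == b) return(1)
  na <- nchar(a); nb <- nchar(b)
  if (na == nb) {
    ## hamming fast path
    av <- charToRaw(a); bv <- charToRaw(b)
    return(sum(av == bv) / na)
  }
  if (na > nb) { tmp <- a; a <- b; b <- tmp; tmp <- na; na <- nb; nb <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) / na
}

#' Target-site duplication of one element occurrence
#'
#' Looks for the longest `k`-mer (`2 <= k <= max_tsd`) such that the `k`
#' nucleotides immediately 5' of the element (in element orientation)
#' equal the element's final `k` nucleotides — the direct repeat
#' straddling the insertion boundary. If none, falls back to equal
#' `k`-mers immediately flanking both sides. Returns `""` when no direct
#' repeat of length at least 2 exists.
#'
#' @param genome A [genome] object.
#' @param start,end 0-based half-open occurrence interval (`end` may
#'   exceed the genome length for an origin-wrapping occurrence).
#' @param strand `"+"` or `"-"`.
#' @param max_tsd Longest duplication considered.
#' @return The duplicated target-site nucleotides, possibly `""`.
#' @export
detect_tsd <- function(genome, start, end, strand = "+", max_tsd = 4L) {
  L <- genome_length(genome)
  chars <- strsplit(genome$sequence, "")[[1]]
  at <- function(pos0) chars[(pos0 %% L) + 1L]
  len <- end - start
  elem <- paste(vapply(seq_len(len) - 1L, function(i)
    if (strand == "+") at(start + i) else comp(at(end - 1L - i)), ""),
    collapse = "")
  up <- function(k) paste(vapply(seq_len(k), function(i)
    if (strand == "+") at(start - k + i - 1L) else comp(at(end + k - i)), ""),
    collapse = "")
  down <- function(k) paste(vapply(seq_len(k) - 1L, function(i)
    if (strand == "+") at(end + i) else comp(at(start - 1L - i)), ""),
    collapse = "")
  for (k in seq(from = min(max_tsd, len), to = 2L)) {
    if (k < 2L) break
    if (up(k) == substr(elem, len - k + 1L, len)) return(up(k))
  }
  for (k in seq(from = min(max_tsd, len), to = 2L)) {
    if (k < 2L) break
    if (up(k) == down(k)) return(up(k))
  }
  ""
}

#' GC percentage with the leading-TSD trim convention
#'
#' The element's first `nchar(tsd)` nucleotides are one copy of the
#' target-site duplication and are excluded before computing GC content;
#' with an empty TSD the full sequence is used. Reported to one decimal.
#'
#' @param sequence Element sequence.
#' @param tsd Target-site duplication (possibly `""`).
#' @return GC percentage in \[0, 100\], rounded to 1 decimal.
#' @examples
#' gc_percent_trimmed("AGTTCCGGGGCCCGGCCACGGGAGCCGGAACCCCGAAAGGAG", "AG")
#' @export
gc_percent_trimmed <- function(sequence, tsd = "") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  core <- substr(sequence, nchar(tsd) + 1L, nchar(sequence))
  if (!nzchar(core)) stop("nothing left after trimming the TSD")
  round(100 * gc_fraction(core), 1L)
}
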