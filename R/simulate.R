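## Forward simulator: multi-strain genome sets with a known element
## history, so detection, mapping, fitting and classification can all be
## validated against a truth table.
##
## The generative model mirrors the biology of GC-cluster mobile elements
## in AT-rich yeast mitochondrial genomes: a shared circular AT-rich
## backbone; a fixed set of homologous insertion loci, each carrying one
## copy of the target-site nucleotides; element presence evolving along
## the strain tree as a two-state continuous-time Markov process
## (simulated event-by-event so gain/loss counts are part of the truth);
## target-site duplication on insertion; optional excision footprints;
## loop-biased substitution within elements; co-conversion substitutions
## in the immediate flanks of a gain; occasional merger with a second
## GC-rich segment; and optional cross-lineage (horizontal) exchange.

#' Random Yule tree with a fixed total length
#'
#' @param n_taxa Number of tips (>= 2).
#' @param total_length Desired sum of branch lengths, in substitutions per
#'   site.
#' @param seed Optional integer seed.
#' @param tip_prefix Prefix for tip labels (default `"s"`).
#' @return An [ape::phylo] tree whose edge lengths sum to `total_length`.
#' @export
yule_tree <- function(n_taxa, total_length, seed = NULL, tip_prefix = "s") {
  stopifnot(n_taxa >= 2, total_length > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / sum(tree$edge.length) * total_length
  tree$tip.label <- paste0(tip_prefix, seq_len(n_taxa))
  tree
}

#' Simulate a presence/absence matrix under the gain/loss model
#'
#' Exact simulation of tip states: the root state is drawn from the root
#' prior and states are propagated along branches using the closed-form
#' two-state transition probabilities.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param n_positions Number of independent homologous positions.
#' @param gain,loss Rates per site per branch-length unit.
#' @param root_prior `"stationary"`, `"uniform"` or a numeric probability
#'   of presence at the root.
#' @param seed Optional integer seed.
#' @return Integer matrix, positions x strains (0/1).
#' @export
simulate_pa_matrix <- function(tree, n_positions, gain, loss,
                               root_prior = "stationary", seed = NULL) {
  stopifnot(gain >= 0, loss >= 0, gain + loss > 0, n_positions >= 1)
  if (!is.null(seed)) set.seed(seed)
  tree <- stats::reorder(validate_tree(tree), "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  prior <- root_prior_vector(root_prior, gain, loss)
  st <- matrix(NA_integer_, nnode, n_positions)
  st[ntip + 1L, ] <- rbinom(n_positions, 1L, prior[2L])
  for (k in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    P <- gl_transition_matrix(gain, loss, tree$edge.length[k])
    p1 <- ifelse(st[pa, ] == 1L, P[2L, 2L], P[1L, 2L])
    st[ch, ] <- rbinom(n_positions, 1L, p1)
  }
  m <- t(st[seq_len(ntip), , drop = FALSE])
  colnames(m) <- tree$tip.label
  rownames(m) <- sprintf("pos%03d", seq_len(n_positions))
  m
}

#' Simulation parameters
#'
#' Collects and validates all knobs of [simulate_dataset()]. Defaults
#' describe the study conditions the package is built around: an 18-strain
#' sample with a total tree length of 0.17 substitutions/site (mean branch
#' about 0.005), gain and loss rates of 135.2 and 235.2 events per site
#' per substitution, a 42-nt GC-rich palindromic element with an `AG`
#' target-site duplication, loop sites mutating much faster than stem
#' sites, and an 82% AT circular background genome.
#'
#' @param tree Optional [ape::phylo] tree; when `NULL` a Yule tree with
#'   `n_taxa` tips and total length `total_length` is drawn.
#' @param n_taxa,total_length Used only when `tree` is `NULL`.
#' @param n_positions Number of homologous element loci.
#' @param gain,loss Gain/loss rates per site per nucleotide substitution.
#' @param consensus Element consensus sequence; must end with `tsd` so
#'   that an inserted element regenerates the target-site duplication.
#' @param tsd Target-site nucleotides duplicated on insertion.
#' @param loop_rate,stem_rate Substitution rates within the element, per
#'   site per branch-length unit, for unpaired (loop) and paired (stem)
#'   positions of the element's hairpin fold.
#' @param background_at AT fraction of the backbone genome.
#' @param genome_length Backbone length in nt.
#' @param coconversion_prob Probability that a gain event co-converts the
#'   flanking nucleotides within `coconversion_window` of the boundary.
#' @param coconversion_window Tract width on each side, nt.
#' @param footprint_prob Probability that a loss leaves an element
#'   fragment bounded by two copies of the target-site nucleotides.
#' @param footprint_len Length of the retained element prefix in a
#'   footprint.
#' @param merger_prob Probability that a gained element is the merged form
#'   (element plus `merger_segment`).
#' @param merger_segment GC-rich segment appended in the merged form.
#' @param transfer_events List of `list(donor=, recipient=, position=)`
#'   tip-level horizontal exchanges applied after the tree simulation.
#' @param seed Integer seed driving all randomness.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(tree = NULL, n_taxa = 18, total_length = 0.17,
                       n_positions = 20,
                       gain = 135.2, loss = 235.2,
                       consensus = gc42_consensus(),
                       tsd = "AG",
                       loop_rate = 5, stem_rate = 0.2,
                       background_at = 0.82, genome_length = 20000,
                       coconversion_prob = 0.5, coconversion_window = 10,
                       footprint_prob = 0.17, footprint_len = 12,
                       merger_prob = 0.1,
                       merger_segment = default_merger_segment(),
                       transfer_events = list(), seed = 1) {
  p <- list(tree = tree, n_taxa = n_taxa, total_length = total_length,
            n_positions = n_positions, gain = gain, loss = loss,
            consensus = toupper(consensus), tsd = toupper(tsd),
            loop_rate = loop_rate, stem_rate = stem_rate,
            background_at = background_at, genome_length = genome_length,
            coconversion_prob = coconversion_prob,
            coconversion_window = coconversion_window,
            footprint_prob = footprint_prob, footprint_len = footprint_len,
            merger_prob = merger_prob,
            merger_segment = toupper(merger_segment),
            transfer_events = transfer_events, seed = seed)
  stopifnot(p$gain >= 0, p$loss >= 0, p$gain + p$loss > 0,
            p$n_positions >= 1, p$genome_length >= 1000,
            p$background_at > 0, p$background_at < 1,
            all(c(p$coconversion_prob, p$footprint_prob, p$merger_prob) >= 0),
            all(c(p$coconversion_prob, p$footprint_prob, p$merger_prob) <= 1),
            p$loop_rate >= 0, p$stem_rate >= 0)
  if (grepl("N", p$consensus)) stop("consensus must not contain N")
  if (nchar(p$consensus) > p$genome_length / 10)
    stop("element longer than genome/10")
  if (!endsWith(p$consensus, p$tsd))
    stop("consensus must end with the target-site nucleotides ('", p$tsd, "')")
  structure(p, class = "sim_params")
}

#' The focal 42-nt GC-cluster consensus sequence
#'
#' The most abundant dispersed repeat of the S. cerevisiae reference
#' mitochondrial genome, used as the simulator's default element.
#' @return A character string of length 42.
#' @export
gc42_consensus <- function() "AGTTCCGGGGCCCGGCCACGGGAGCCGGAACCCCGAAAGGAG"

## GC-rich 44-nt segment used as the default second unit of a merged
## cluster (42 + 44 = 86-nt merged form).
default_merger_segment <- function() {
  "CCGGGGCTCGGCCCACGGGCCGGTCCGCGGGGACCGCCAAGGGC"
}

random_dna <- function(n, at = 0.82) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

## substitute each site of `seq` listed in `sites` with prob `p`, drawing
## a uniform different base
mutate_sites <- function(seq, sites, p) {
  if (p <= 0 || length(sites) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- sites[runif(length(sites)) < p]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

## Deterministic derived allele for co-conversion substitutions: A -> T,
## other bases unchanged. The map is idempotent, so repeated independent
## gains at one position leave identical tract alleles and presence
## associates perfectly with the derived state; it also keeps the tract
## AT-rich, so the tract is not confusable with a fused GC cluster.
derived_base <- function(base) {
  chartr("ACGT", "TCGT", base)
}

#' Simulate a multi-strain genome dataset with truth tables
#'
#' Runs the full generative model described in [sim_params()] and emits
#' one genome per strain plus a truth object recording everything a
#' pipeline stage could be checked against.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{genomes}{named list of [genome] objects, one per tip.}
#'     \item{truth}{list with `matrix` (positions x strains, 0/1),
#'       `classification` (positions x strains category matrix),
#'       `coordinates` (data.frame strain/position/start/end of each
#'       inserted residue, 0-based half-open),
#'       `elements` (positions x strains element sequences),
#'       `residues` (positions x strains between-flank residues, TSD
#'       included), `anchors` (backbone anchor offsets), `flanks`
#'       (per-position upstream/downstream 100-nt backbone flanks),
#'       `tract_sites` (co-conversion offsets per position),
#'       `n_gains`, `n_losses` (event counts over the tree),
#'       `tree`, `params`.}
#'   }
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  tree <- params$tree
  if (is.null(tree))
    tree <- yule_tree(params$n_taxa, params$total_length)
  tree <- stats::reorder(validate_tree(tree), "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npos <- params$n_positions
  elen <- nchar(params$consensus)
  tlen <- nchar(params$tsd)

  ## element hairpin partition drives the loop/stem substitution bias
  part <- fold_hairpin(params$consensus)
  loop_sites <- part$loop
  stem_sites <- part$stem

  ## backbone with one TSD copy ending at each anchor point
  backbone <- random_dna(params$genome_length, params$background_at)
  margin <- 300L
  anchors <- round(seq(margin, params$genome_length - margin,
                       length.out = npos))
  anchors <- as.integer(anchors + sample(-30:30, npos, replace = TRUE))
  if (any(diff(anchors) < 250L))
    stop("genome too short for the requested number of positions")
  bb <- strsplit(backbone, "")[[1]]
  for (a in anchors) {
    bb[(a - tlen + 1L):a] <- strsplit(params$tsd, "")[[1]]
  }
  backbone <- paste(bb, collapse = "")

  ## per-node, per-position lineage state
  blank <- list(state = 0L, elem = NA_character_, merged = FALSE,
                footprint = NA_character_, flank_subs = integer(0))
  node_state <- replicate(nnode, replicate(npos, blank, simplify = FALSE),
                          simplify = FALSE)
  prior <- root_prior_vector("stationary", params$gain, params$loss)
  n_gains <- 0L; n_losses <- 0L
  root <- ntip + 1L

  apply_gain <- function(s) {
    s$state <- 1L
    s$elem <- params$consensus
    s$merged <- runif(1) < params$merger_prob
    s$footprint <- NA_character_
    if (runif(1) < params$coconversion_prob) {
      w <- params$coconversion_window
      offs <- c(-(1:w), 1:w)
      subs <- rep(1L, length(offs))
      names(subs) <- as.character(offs)
      s$flank_subs <- subs
    }
    s
  }
  ## loss restores the pre-insertion site: the element (and its
  ## co-converted flank alleles) are replaced by the ancestral-allele
  ## configuration, optionally leaving an element fragment bounded by a
  ## second copy of the target-site nucleotides
  apply_loss <- function(s) {
    s$state <- 0L
    s$elem <- NA_character_
    s$merged <- FALSE
    s$flank_subs <- integer(0)
    s$footprint <- if (runif(1) < params$footprint_prob) {
      paste0(substr(params$consensus, 1L, params$footprint_len), params$tsd)
    } else NA_character_
    s
  }

  ## a position present at the root carries the marks of its (ancient)
  ## gain, including any co-conversion tract
  for (j in seq_len(npos)) {
    if (runif(1) < prior[2L])
      node_state[[root]][[j]] <- apply_gain(node_state[[root]][[j]])
  }

  for (k in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    t_branch <- tree$edge.length[k]
    for (j in seq_len(npos)) {
      s <- node_state[[pa]][[j]]
      ## event-by-event simulation of the gain/loss process
      t_left <- t_branch
      t_since_gain <- if (s$state == 1L) t_branch else 0
      repeat {
        rate <- if (s$state == 0L) params$gain else params$loss
        if (rate <= 0) break
        w <- rexp(1L, rate)
        if (w >= t_left) break
        t_left <- t_left - w
        if (s$state == 0L) {
          s <- apply_gain(s); n_gains <- n_gains + 1L
          t_since_gain <- t_left
        } else {
          s <- apply_loss(s); n_losses <- n_losses + 1L
        }
      }
      ## element sequence divergence while present
      if (s$state == 1L && t_since_gain > 0) {
        s$elem <- mutate_sites(s$elem, loop_sites,
                               -expm1(-params$loop_rate * t_since_gain))
        s$elem <- mutate_sites(s$elem, stem_sites,
                               -expm1(-params$stem_rate * t_since_gain))
      }
      node_state[[ch]][[j]] <- s
    }
  }

  tip_state <- lapply(seq_len(ntip), function(i) node_state[[i]])
  names(tip_state) <- tree$tip.label

  ## horizontal exchange: copy element + flank alleles donor -> recipient
  transfers <- list()
  for (ev in params$transfer_events) {
    d <- ev$donor; r <- ev$recipient; j <- ev$position
    stopifnot(d %in% tree$tip.label, r %in% tree$tip.label,
              j >= 1, j <= npos)
    tip_state[[r]][[j]] <- tip_state[[d]][[j]]
    transfers[[length(transfers) + 1L]] <-
      list(donor = d, recipient = r, position = j)
  }

  ## assemble per-tip genomes and the truth tables
  strains <- tree$tip.label
  pos_ids <- sprintf("pos%03d", seq_len(npos))
  pa <- matrix(0L, npos, ntip, dimnames = list(pos_ids, strains))
  classif <- matrix("absent_clean", npos, ntip,
                    dimnames = list(pos_ids, strains))
  elements <- matrix(NA_character_, npos, ntip,
                     dimnames = list(pos_ids, strains))
  residues <- matrix(NA_character_, npos, ntip,
                     dimnames = list(pos_ids, strains))
  coords <- list()
  genomes <- vector("list", ntip)
  w <- params$coconversion_window

  for (i in seq_len(ntip)) {
    chars <- strsplit(backbone, "")[[1]]
    ## apply flank substitutions first (coordinates unchanged)
    for (j in seq_len(npos)) {
      s <- tip_state[[i]][[j]]
      if (length(s$flank_subs)) {
        offs <- as.integer(names(s$flank_subs))
        for (o in offs) {
          p <- if (o < 0) anchors[j] - tlen + o + 1L else anchors[j] + o
          chars[p] <- derived_base(chars[p])
        }
      }
    }
    ## insert residues 3' of each anchor, from the last anchor backwards
    ## so earlier coordinates stay valid during assembly
    ins <- character(npos)
    for (j in seq_len(npos)) {
      s <- tip_state[[i]][[j]]
      ins[j] <- if (s$state == 1L) {
        if (s$merged) paste0(s$elem, params$merger_segment) else s$elem
      } else if (!is.na(s$footprint)) s$footprint else ""
    }
    out2 <- character(2L * npos + 1L)
    prev <- 0L
    for (j in seq_len(npos)) {
      out2[2L * j - 1L] <- paste(chars[(prev + 1L):anchors[j]], collapse = "")
      out2[2L * j] <- ins[j]
      prev <- anchors[j]
    }
    out2[2L * npos + 1L] <-
      paste(chars[(prev + 1L):params$genome_length], collapse = "")
    gseq <- paste(out2, collapse = "")
    genomes[[i]] <- genome(strains[i], gseq, circular = TRUE)

    ## truth bookkeeping with cumulative offsets
    shift <- 0L
    for (j in seq_len(npos)) {
      s <- tip_state[[i]][[j]]
      start <- anchors[j] + shift          # 0-based start of the residue
      end <- start + nchar(ins[j])
      pa[j, i] <- s$state
      elements[j, i] <- s$elem
      residues[j, i] <- paste0(params$tsd, ins[j])
      classif[j, i] <- if (s$state == 1L) {
        if (s$merged) "merged" else "standalone"
      } else if (!is.na(s$footprint)) "footprint" else "absent_clean"
      if (nchar(ins[j]) > 0L)
        coords[[length(coords) + 1L]] <-
          data.frame(strain = strains[i], position = pos_ids[j],
                     start = start, end = end, sequence = ins[j],
                     stringsAsFactors = FALSE)
      shift <- shift + nchar(ins[j])
    }
  }
  names(genomes) <- strains
  coords <- if (length(coords)) do.call(rbind, coords) else
    data.frame(strain = character(), position = character(),
               start = integer(), end = integer(), sequence = character())

  ## self-audit: every recorded interval must re-extract to its sequence
  for (r in seq_len(nrow(coords))) {
    g <- genomes[[coords$strain[r]]]
    got <- extract_interval(g, coords$start[r], coords$end[r])
    if (!identical(got, coords$sequence[r]))
      stop("simulator truth/FASTA inconsistency at ", coords$strain[r],
           " ", coords$position[r])
  }

  flanks <- data.frame(
    position = pos_ids,
    upstream = vapply(anchors, function(a)
      substr(backbone, a - tlen - 99L, a - tlen), ""),
    downstream = vapply(anchors, function(a)
      substr(backbone, a + 1L, a + 100L), ""),
    stringsAsFactors = FALSE)

  ## informative tract offsets per position: sites inside the window at
  ## which the derived (GC-ward) allele differs from the backbone allele
  bbv <- strsplit(backbone, "")[[1]]
  tract <- lapply(seq_len(npos), function(j) {
    offs <- if (params$coconversion_prob > 0) c(-(w:1L), 1:w) else integer(0)
    if (length(offs) == 0L) return(integer(0))
    pos1 <- ifelse(offs < 0, anchors[j] - tlen + offs + 1L, anchors[j] + offs)
    offs[bbv[pos1] == "A"]
  })
  names(tract) <- pos_ids

  list(genomes = genomes,
       truth = list(matrix = pa, classification = classif,
                    coordinates = coords, elements = elements,
                    residues = residues, anchors = anchors,
                    flanks = flanks, tract_sites = tract,
                    n_gains = n_gains, n_losses = n_losses,
                    tree = tree, params = params))
}
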