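---
title: "Models and methods behind gcturnover"
author: "gcturnover authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gcturnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcturnover)
```

# The scientific problem

Yeast mitochondrial genomes are extremely AT-rich (around 80–85% AT),
yet they are dotted with short GC-rich palindromic sequences — "GC
clusters" — that fold into hairpins, sit mostly in intergenic regions,
and show every hallmark of mobile DNA: high copy number, sporadic
presence/absence among closely related strains, short direct repeats at
their boundaries resembling target-site duplications (TSDs), and
occasional sharing across species boundaries. `gcturnover` packages the
quantitative workflow needed to study such elements from multi-strain
genome collections: find the repeats, map homologous insertion sites
across strains, and measure how fast elements are gained and lost on
the strain phylogeny.

# The gain/loss model

The core of the package is a two-state continuous-time Markov model of
element presence at a homologous site. State 0 is absence, state 1 is
presence; gains occur at rate $\alpha$ and losses at rate $\beta$, both
expressed per site per unit of branch length. Because the input trees
carry branch lengths in expected nucleotide substitutions per site, the
fitted rates read directly as *events per site per nucleotide
substitution* — a rate of 135 means the element is gained two orders of
magnitude faster than the underlying point-substitution process.

The transition probabilities over a branch of length $t$ have the
closed form implemented in `gl_transition_matrix()`:

$$P(t) = \frac{1}{\alpha+\beta}\begin{pmatrix}
\beta + \alpha e^{-(\alpha+\beta)t} & \alpha(1-e^{-(\alpha+\beta)t})\\
\beta(1-e^{-(\alpha+\beta)t}) & \alpha + \beta e^{-(\alpha+\beta)t}
\end{pmatrix}$$

`turnover_loglik()` computes the likelihood of a presence/absence
matrix by Felsenstein pruning, treating `?` cells as uninformative
partial likelihoods $(1,1)$ rather than dropping rows; identical
tip-state patterns are collapsed and weighted, and per-node rescaling
guards against underflow on large trees. `fit_turnover()` maximises the
likelihood on the log-rate scale, either with one rate
($\alpha=\beta=\mu$) or with separate gain and loss rates. The two-rate
search starts from several deterministic points that always include the
one-rate optimum, which guarantees the nesting inequality
$\ln L_2 \ge \ln L_1$ up to optimiser tolerance ($10^{-8}$ in log
likelihood; rate bounds $[10^{-6}, 10^{6}]$). Standard errors come from
the inverse observed information (central differences with step
$10^{-4}$ on the log scale, delta-method back-transform); all-present
or all-absent matrices are flagged as boundary cases with no SEs.

`likelihood_ratio_test()` contrasts the two fits with
$2\Delta\ln L \sim \chi^2_1$. `ancestral_posteriors()` computes
marginal posterior probabilities of presence at the root (and
optionally all internal nodes) by the standard inside/outside two-pass
algorithm; the binary summary calls a position "ancestrally present"
when the posterior exceeds 0.5, and reports exact ties as ties.

**Root prior.** The default prior on the root state is the stationary
distribution $(\beta, \alpha)/(\alpha+\beta)$. This is the natural
choice for a process observed at stationarity and is used by the
acceptance checks; `uniform` and fixed priors are available because the
choice is not forced by the model and mildly affects ancestral-state
pies (much less so the rate estimates).

`pairwise_difference()` implements the companion descriptive statistic
(share of differing states among pairwise-comparable sites, missing
sites excluded per pair), which remains usable when matrices are too
gappy for likelihood work.

# Repeat detection and boundary conventions

`find_dispersed_repeats()` replaces an interactive repeat-finder +
manual-curation workflow with a deterministic one:

1. **Seeding and extension.** Every duplicated `min_len`-mer (default
   30 nt, canonicalised across strands) seeds an occurrence group that
   is extended while all copies remain identical, giving maximal
   exact-repeat candidates.
2. **Greedy cover.** Overlapping candidates compete: a chance flank
   extension shared by a few copies yields a longer-but-rarer
   candidate, while a segment shared between two near-identical
   families yields a shorter-but-commoner one. Candidates are selected
   greedily by uncovered copies × length, which keeps the unit that
   explains the most repeat sequence and discards both artefacts.
3. **TSD trim.** When a selected repeat begins with $k$ nucleotides
   ($2 \le k \le 4$) equal to both the next $k$ and the final $k$
   nucleotides, the leading $k$-mer is the upstream target-site copy
   and is trimmed, so elements start and end on the duplicated target
   site.

Families are then formed by single-linkage clustering
(`cluster_copies()`, 100% identity at 70% length coverage by default)
and ranked by copy count, length, and sequence. One convention is worth
flagging prominently: **family GC% excludes one leading TSD copy**
(`gc_percent_trimmed()`). The element carries the target-site
nucleotides at both ends, so including both copies would double-count
two AT-leaning bases; trimming one copy is the convention under which
the reference families' published GC values (75, 85.7, 82.8, 77.5) are
reproduced exactly.

# Homolog mapping

`search_homologs()` finds relaxed homologs (default: ≥90% identity over
≥95% of the query) with Biostrings pattern matching as the candidate
generator and a global(query)/local(subject) alignment as the scorer;
hits are resolved best-score-first, non-overlapping, on both strands,
across the origin of circular genomes.

`anchor_positions()` merges occurrences from different strains into
homologous positions when both 100-nt flanks agree at ≥80% identity —
a threshold chosen for low intraspecific mitochondrial intergenic
divergence, and configurable. Flanks are anchored *beyond* the residue:
the residue runs from the single upstream target-site copy through the
element and any contiguous GC-rich continuation, so strains carrying a
stand-alone element and strains carrying a merged (element + second
GC cluster) form at the same site share the same backbone flanks. The
GC-run boundary uses an 8-nt lookahead at ≥60% GC with trailing-A/T
backoff; it can sit a few bases inside the true end of a merged
segment whose tail mixes in A/T — states and classifications are
unaffected, but recovered merged residues may be a short prefix of the
truth.

A deliberate distinction: **absence requires positive evidence** (both
flanks found, adjacent, with a between-flank gap shorter than twice the
element length); a strain where the flanks cannot be located is
*missing* (`?`), not absent. Only absent/present cells inform the
likelihood; this choice determines which cells enter the model and is
therefore surfaced in the matrix rather than hidden in the fit.

# Structure statistics

`fold_hairpin()` is a maximum-base-pairing (Nussinov-style) fold with a
minimum loop of 3 and optional G·T wobble, with a deterministic
traceback biased toward long contiguous stems. It is *not* a
thermodynamic folder: its role is to give a reproducible stem/loop
partition for substitution-accounting, not a minimum-free-energy
structure. For the 42-nt element consensus the Watson–Crick fold
partitions 28 stem and 14 loop sites (`gc42_partition()`); thermodynamic
treatments of the same hairpin assign 30/12. Enrichment tests take the
site counts as arguments, so either partition can be supplied.

`partition_enrichment_test()` offers two 2×2 constructions. The default
`counts_vs_sites` table `[[loop_changes, n_loop_sites], [stem_changes,
n_stem_sites]]` is the construction that reproduces the published
loop/stem Fisher probabilities exactly (e.g. 367/174 changes at 12/30
sites gives $p = 8.04\times10^{-7}$); the `opportunities` mode
(changes vs non-changes over homologs × sites) is also implemented
because it is the construction a reader might expect, and the output
records which was used.

`nucleotide_diversity()`, `indel_density()` (midpoint rule, densities
per kb, Mann–Whitney U with normal approximation and tie correction via
`wilcox.test`), and `rpkm_normalize()` (RPKM with equalisation of a
reference gene across libraries; idempotent) complete the module.

# Comparative classification

`classify_position()` types the between-flank residue of every strain:
a single target-site copy (`absent_clean`); an element unit
(`standalone`); a unit plus ≥10 nt of additional >50% GC sequence
(`merged` — thresholds chosen so a 42+44 fused cluster classifies
correctly); a listed smaller unit such as the element's 18-nt 3′
terminus (`subunit`); any other element fragment bounded by two
target-site copies (`footprint`); otherwise `other` with the evidence
retained. `detect_coconversion()` calls flank alignment columns whose
alleles perfectly partition by element presence within a window of the
boundary (a fractional mode exists for noisy data).
`classify_transfer()` flags a strain as a horizontal-exchange recipient
only when *both* its element is closer to the other species' consensus
by ≥2 identity points *and* a neighbour-joining tree of the ±100-nt
flanks (Jukes–Cantor distances, `nj_tree()`) places it inside the other
species' clade — an automated stand-in for visual inspection of a
maximum-likelihood flank tree.

# The simulator and what it does (not) emulate

`simulate_dataset()` generates multi-strain genome sets with a complete
truth table. Its defaults are the study conditions the package is
validated under: 18 strains, total tree length 0.17 substitutions/site
(mean branch ≈ 0.005), gain 135.2 and loss 235.2 per substitution, a
42-nt GC-rich consensus with `AG` TSD, 82% AT background. Default sizes
used in tests (20 positions, 20-kb genomes) keep whole-pipeline
validation comfortably fast while leaving realistic intergenic spacing
between insertion loci; rate-recovery checks use matrix-level
simulation at 1000 sites.

Design choices worth knowing:

* **Pre-assigned loci.** Insertion anchors are fixed on a shared
  backbone at dataset start, so "homologous position" is well-defined
  by construction and anchoring can be scored against truth.
* **Event-level simulation.** Presence evolves by drawing exponential
  waiting times (not just endpoint sampling), so gain/loss *counts*
  are part of the truth; their expectations follow
  $E[\text{gains}] = \alpha\,\pi_0\,L\,n$ under stationarity.
* **Elements diverge; the backbone does not.** Loop and stem sites of
  the element mutate at separate rates (defaults 5 and 0.2 per
  substitution unit: loops above, stems below the neutral rate,
  mirroring the observed diversity contrast), but the backbone carries
  no background substitution process. Flank-tree methods therefore
  need constructed fixtures for positive controls, and passing tests
  say nothing about anchoring under heavy intergenic divergence.
* **Co-conversion semantics.** A gain converts flanking nucleotides
  within the tract window with a deterministic, idempotent A→T map,
  root-present elements carry their (ancient) tract, and a loss
  restores the pre-insertion flanks. Under these semantics presence
  associates *perfectly* with derived tract alleles — the clean
  situation the tract caller is specified against; real data will be
  noisier, which is why a fractional association mode exists.
* **Footprints and mergers.** A loss leaves a footprint (12-nt element
  prefix plus a second TSD copy) with probability 0.17 — matching the
  observed 5 footprints among 30 characterised absence sites — and a
  gain produces the merged form with probability 0.1.

# Numerical choices and degenerate inputs

* Interval arithmetic is 0-based half-open throughout; only
  human-readable reports are 1-based.
* Circular genomes are scanned across the origin; an origin-spanning
  occurrence is reported once with `end` past the sequence length.
* `N` never matches anything, including `N`.
* Ties in family ranking break by copy count, then length, then
  lexicographic sequence; NJ input is sorted by label so tree output
  is independent of input order.
* All-`?` matrix rows are rejected; all-present/all-absent matrices
  yield boundary fits with `NA` standard errors rather than spurious
  precision.
* Every simulated dataset self-audits: each recorded truth interval is
  re-extracted from the emitted FASTA and must match exactly.

# Known limitations

* The fold is maximum-pairing, not thermodynamic; supply an external
  partition for structure-critical work.
* Ancestral-state output (and weakly the rates) depend on the root
  prior; compare `stationary` and `uniform` if it matters.
* The repeat-boundary and merged-residue conventions are deterministic
  substitutes for expert curation and can clip a few bases from a
  merged segment's tail.
* Rate heterogeneity across positions (e.g. gamma-distributed
  turnover) is not modelled; all positions share one $(\alpha,\beta)$.
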