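## Shared fixture builders: AT-rich random background, planted-element
## genomes, and point-mutated variants. All randomness is driven by the
## caller's seed.

at_rich <- function(n, at = 0.82) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

## genome with `n` copies of `element` planted at regular spacing, each
## immediately preceded by `tsd` (so the element sits in its natural
## target-site context); returns the genome and the 0-based starts
plant_copies <- function(element, n, spacing = 1200, tsd = "AG",
                         strain = "planted", tail = 900) {
  pieces <- character(2L * n + 1L)
  starts <- integer(n)
  off <- 0L
  for (i in seq_len(n)) {
    bgp <- paste0(at_rich(spacing), tsd)
    pieces[2L * i - 1L] <- bgp
    off <- off + nchar(bgp)
    starts[i] <- off
    pieces[2L * i] <- element
    off <- off + nchar(element)
  }
  pieces[2L * n + 1L] <- at_rich(tail)
  list(genome = genome(strain, paste(pieces, collapse = "")),
       starts = starts)
}

## substitute k random sites of a sequence (never to the original base)
mutate_k <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), k)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

## brute-force pruning oracle: sum the joint probability of the tip
## states over every assignment of states to internal nodes
enum_loglik <- function(tree, tip_states, gain, loss, prior = NULL) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  if (is.null(prior)) prior <- c(loss, gain) / (gain + loss)
  internal <- (ntip + 1L):nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    gl_transition_matrix(gain, loss, tree$edge.length[k]))
  total <- 0
  combos <- expand.grid(rep(list(0:1), length(internal)))
  for (r in seq_len(nrow(combos))) {
    st <- integer(nnode)
    st[seq_len(ntip)] <- tip_states[tree$tip.label]
    st[internal] <- as.integer(combos[r, ])
    pr <- prior[st[ntip + 1L] + 1L]
    for (k in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
      pr <- pr * P[[k]][st[pa] + 1L, st[ch] + 1L]
    }
    total <- total + pr
  }
  log(total)
}

## as enum_loglik, but with the root state clamped (for ancestral-state
## oracles: joint probability of tips and root state)
enum_loglik_rootstate <- function(tree, tip_states, gain, loss, prior,
                                  root_state) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  others <- setdiff((ntip + 1L):nnode, root)
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    gl_transition_matrix(gain, loss, tree$edge.length[k]))
  total <- 0
  combos <- if (length(others))
    expand.grid(rep(list(0:1), length(others))) else data.frame(row.names = 1)
  for (r in seq_len(nrow(combos))) {
    st <- integer(nnode)
    st[seq_len(ntip)] <- tip_states[tree$tip.label]
    st[root] <- root_state
    if (length(others)) st[others] <- as.integer(combos[r, ])
    pr <- prior[root_state + 1L]
    for (k in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
      pr <- pr * P[[k]][st[pa] + 1L, st[ch] + 1L]
    }
    total <- total + pr
  }
  log(total)
}

## brute-force maximum nested pairing (Watson-Crick + optional wobble,
## minimum loop), by exhaustive recursion
enum_max_pairs <- function(seq, min_loop = 3L, wobble = TRUE) {
  s <- strsplit(toupper(seq), "")[[1]]
  ok <- function(a, b) {
    pairs <- c("AT", "TA", "GC", "CG")
    if (wobble) pairs <- c(pairs, "GT", "TG")
    paste0(a, b) %in% pairs
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(s[i], s[k])) {
        inner <- rec(i + 1L, k - 1L)
        rest <- if (k < j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + rest)
      }
    }
    best
  }
  rec(1L, length(s))
}
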