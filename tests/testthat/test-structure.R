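test_that("hairpin fold matches the enumeration maximum", {
  p <- fold_hairpin("GGGGAAACCCC")
  expect_identical(nrow(p$pairs), 4L)
  expect_identical(length(p$loop), 3L)
  expect_identical(sort(p$loop), 5:7)
  p2 <- fold_hairpin("AAAAAAAA")
  expect_identical(nrow(p2$pairs), 0L)
  expect_identical(length(p2$loop), 8L)
  set.seed(201)
  for (i in 1:25) {
    n <- sample(8:12, 1L)
    seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    got <- nrow(fold_hairpin(seq)$pairs)
    expect_identical(got, enum_max_pairs(seq),
                     info = paste("sequence:", seq))
  }
  ## partition invariants: stem/loop partition all sites, pairing is an
  ## involution with nested pairs
  f <- fold_hairpin(gc42_consensus())
  expect_setequal(c(f$stem, f$loop), 1:42)
  expect_identical(f$pairing[f$pairing[f$stem]], f$stem)
  if (nrow(f$pairs) > 1L) {
    for (a in seq_len(nrow(f$pairs) - 1L)) for (b in (a + 1L):nrow(f$pairs)) {
      i <- f$pairs[a, ]; j <- f$pairs[b, ]
      nested <- (i[1] < j[1] && j[2] < i[2]) || (j[1] < i[1] && i[2] < j[2]) ||
        (i[2] < j[1]) || (j[2] < i[1])
      expect_true(nested)
    }
  }
})

test_that("partition change counts split total mismatches", {
  cons <- gc42_consensus()
  part <- gc42_partition()
  expect_identical(count_partition_changes(c(cons, cons), cons, part),
                   c(loop = 0L, stem = 0L))
  ## the "36G" single-substitution variant: position 36 is a loop site
  v36 <- cons
  substr(v36, 36, 36) <- "G"
  expect_true(36 %in% part$loop)
  expect_identical(count_partition_changes(rep(v36, 3), cons, part),
                   c(loop = 3L, stem = 0L))
  ## loop + stem changes sum to all mismatches
  set.seed(202)
  homs <- replicate(10, mutate_k(cons, sample(0:5, 1L)))
  cc <- count_partition_changes(homs, cons, part)
  total <- sum(vapply(homs, function(h)
    sum(strsplit(h, "")[[1]] != strsplit(cons, "")[[1]]), 0))
  expect_identical(unname(sum(cc)), as.integer(total))
  expect_warning(count_partition_changes(c(cons, substr(cons, 1, 30)),
                                         cons, part), "length")
})

test_that("loop-biased mutation produces the expected enrichment", {
  set.seed(203)
  sp <- sim_params(n_taxa = 12, n_positions = 15, genome_length = 16000,
                   loop_rate = 10, stem_rate = 1, seed = 203)
  sim <- simulate_dataset(sp)
  homs <- as.vector(sim$truth$elements)
  homs <- homs[!is.na(homs)]
  part <- fold_hairpin(sp$consensus)
  cc <- count_partition_changes(homs, sp$consensus, part)
  nl <- length(part$loop); ns <- length(part$stem)
  ratio <- (cc[["loop"]] / nl) / (cc[["stem"]] / ns)
  ## per-site loop/stem change ratio should reflect the 10x rate ratio
  expect_gt(ratio, 3)
  expect_lt(ratio, 30)
})

test_that("Fisher enrichment modes reproduce the printed group tests", {
  expect_equal(partition_enrichment_test(0, 0, 12, 30)$p_value, 1)
  ## printed loop/stem contrasts at the 12 loop / 30 stem site split
  expect_equal(partition_enrichment_test(367, 174, 12, 30)$p_value,
               8.04e-7, tolerance = 1e-2)
  expect_equal(partition_enrichment_test(48, 2, 12, 30)$p_value,
               2.42e-12, tolerance = 1e-2)
  ## loops:stems ratio contrast between the two species' counts
  expect_equal(fisher.test(matrix(c(48, 2, 367, 174), 2))$p.value,
               3.27e-6, tolerance = 1e-2)
  ## opportunities mode is also available and reported as such
  e <- partition_enrichment_test(48, 2, 12, 30, mode = "opportunities",
                                 n_homologs = 113)
  expect_identical(e$mode, "opportunities")
  expect_lt(e$p_value, 1e-12)
  ## equal per-site change rates: p near-uniform under resampling
  set.seed(204)
  ps <- replicate(200, {
    ch <- rbinom(2, c(120, 300), 0.1)
    partition_enrichment_test(ch[1], ch[2], 120, 300)$p_value
  })
  expect_gt(mean(ps < 0.05), 0.0)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("nucleotide diversity equals the all-pairs oracle", {
  expect_equal(nucleotide_diversity(c("ACGT", "ACGT", "ACGT"), 1:4), 0)
  seqs <- c(strrep("A", 12), paste0(strrep("A", 11), "G"))
  expect_equal(nucleotide_diversity(seqs, 1:12), 1 / 12)
  set.seed(205)
  rs <- replicate(6, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                           collapse = ""))
  sites <- sample(20, 7)
  oracle <- {
    tot <- 0; np <- 0
    for (i in 1:5) for (j in (i + 1):6) {
      a <- strsplit(rs[i], "")[[1]][sites]
      b <- strsplit(rs[j], "")[[1]][sites]
      tot <- tot + mean(a != b); np <- np + 1
    }
    tot / np
  }
  expect_equal(nucleotide_diversity(rs, sites), oracle, tolerance = 1e-12)
  expect_error(nucleotide_diversity(rs, integer(0)), "empty")
})

test_that("indel densities follow the midpoint rule", {
  expect_equal(indel_density(data.frame(start = integer(), end = integer()),
                             data.frame(start = 0L, end = 1000L), 1e5),
               c(density_indel = 0, density_genome = 0))
  elems <- data.frame(start = c(100, 500, 5000, 90000),
                      end = c(142, 542, 5042, 90042))
  iv <- data.frame(start = 0L, end = 1000L)
  d <- indel_density(elems, iv, 1e5)
  expect_equal(unname(d["density_indel"]), 2.0)
  expect_equal(unname(d["density_genome"]), 0.04)
  expect_identical(d, indel_density(elems, iv[1, ], 1e5))
  expect_true(all(d >= 0))
})

test_that("Mann-Whitney U equals the brute-force rank statistic", {
  set.seed(206)
  for (i in 1:10) {
    x <- round(runif(sample(4:9, 1)), 2)
    y <- round(runif(sample(4:9, 1)), 2)
    got <- mann_whitney_u(x, y)
    ## U = number of (x, y) pairs with x > y, ties counting 1/2
    U <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(got$U, U)
    expect_equal(got$p_value,
                 wilcox.test(x, y, exact = FALSE)$p.value)
  }
})

test_that("RPKM normalisation equalises the reference gene and is idempotent", {
  tab <- data.frame(
    feature = rep(c("atp6", "atp8", "gc42_01"), 2),
    library = rep(c("L1", "L2"), each = 3),
    count = c(10, 5, 2, 30, 6, 9),
    length = rep(c(1000, 500, 42), 2),
    total = rep(c(1e6, 3e6), each = 3))
  out <- rpkm_normalize(tab, reference = "atp6")
  expect_equal(out$rpkm[1], 10)  # 10 * 1e9 / (1000 * 1e6)
  ref <- out$rpkm_normalized[out$feature == "atp6"]
  expect_equal(ref[1], ref[2])
  ## hand computation for the second library
  x <- 10; y <- 30 * 1e9 / (1000 * 3e6)
  expect_equal(out$rpkm_normalized[out$feature == "gc42_01" &
                                     out$library == "L2"],
               (9 * 1e9 / (42 * 3e6)) * x / y)
  again <- rpkm_normalize(out, reference = "atp6")
  expect_equal(again$rpkm_normalized, out$rpkm_normalized)
  expect_error(rpkm_normalize(tab[tab$feature != "atp6", ], "atp6"),
               "absent")
})
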