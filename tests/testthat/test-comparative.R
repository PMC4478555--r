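gc42 <- gc42_consensus()

test_that("residue classification matches the category definitions", {
  sub18 <- substr(gc42, 25, 42)  # the unit's 18-nt 3' terminus
  res <- c(
    clean = "AG",
    stand = paste0("AG", gc42),
    ## unit + a 44-nt GC-rich block: the 86-nt merged form
    merged = paste0("AG", gc42, "CCGGGGCTCGGCCCACGGGCCGGTCCGCGGGGACCGCCAAGGGC"),
    sub = paste0("AG", sub18),
    foot = paste0("AG", substr(gc42, 1, 12), "AG"),
    miss = NA_character_,
    other = "AGTTTTTTTTTTTT")
  cl <- classify_position(res, "AG", gc42, subunits = sub18)
  got <- setNames(cl$category, cl$strain)
  expect_identical(unname(got["clean"]), "absent_clean")
  expect_identical(unname(got["stand"]), "standalone")
  expect_identical(unname(got["merged"]), "merged")
  expect_identical(unname(got["sub"]), "subunit")
  expect_identical(unname(got["foot"]), "footprint")
  expect_true(is.na(got["miss"]))
  expect_identical(unname(got["other"]), "other")
  expect_match(cl$evidence[cl$strain == "merged"], "44 nt")
})

test_that("classification confusion matrix against simulator truth is diagonal", {
  sp <- sim_params(n_taxa = 8, n_positions = 10, genome_length = 12000,
                   seed = 11)
  sim <- simulate_dataset(sp)
  for (j in seq_len(nrow(sim$truth$residues))) {
    cl <- classify_position(sim$truth$residues[j, ], sp$tsd, sp$consensus)
    expect_identical(unname(setNames(cl$category, cl$strain)),
                     unname(sim$truth$classification[j, ]))
  }
})

test_that("co-conversion calls recover all informative tract sites", {
  sp <- sim_params(n_taxa = 10, n_positions = 6, genome_length = 9000,
                   seed = 9, coconversion_prob = 1, coconversion_window = 10,
                   footprint_prob = 0, merger_prob = 0)
  sim <- simulate_dataset(sp)
  occ <- do.call(rbind, lapply(sim$genomes,
                               function(g) search_homologs(gc42, g)))
  pos <- anchor_positions(occ, sim$genomes)
  co <- sim$truth$coordinates
  n_checked <- 0L
  for (p in pos) {
    a <- p$anchors[1L, ]
    tp <- co$position[co$strain == a$strain & co$start <= a$start &
                        co$end >= a$end][1L]
    st <- ifelse(p$per_strain_state == "present", 1L,
                 ifelse(p$per_strain_state == "absent", 0L, NA))
    if (sum(st == 1L, na.rm = TRUE) < 2L ||
        sum(st == 0L, na.rm = TRUE) < 2L) next
    cc <- detect_coconversion(st, p$per_strain_upstream,
                              p$per_strain_downstream, window = 10)
    expect_identical(sort(cc$sites$offset),
                     sort(sim$truth$tract_sites[[tp]]))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 3L)
})

test_that("no false tract calls when co-conversion is off", {
  sp <- sim_params(n_taxa = 10, n_positions = 10, genome_length = 12000,
                   seed = 10, coconversion_prob = 0, footprint_prob = 0,
                   merger_prob = 0)
  sim <- simulate_dataset(sp)
  occ <- do.call(rbind, lapply(sim$genomes,
                               function(g) search_homologs(gc42, g)))
  pos <- anchor_positions(occ, sim$genomes)
  fp <- 0L
  for (p in pos) {
    st <- ifelse(p$per_strain_state == "present", 1L,
                 ifelse(p$per_strain_state == "absent", 0L, NA))
    cc <- detect_coconversion(st, p$per_strain_upstream,
                              p$per_strain_downstream, window = 30)
    fp <- fp + nrow(cc$sites)
  }
  expect_identical(fp, 0L)
})

test_that("insufficient state classes yield an empty call with a reason", {
  st <- c(a = 1L, b = 0L, c = 0L)
  up <- setNames(rep(strrep("A", 40), 3), names(st))
  cc <- detect_coconversion(st, up, up, window = 10)
  expect_identical(nrow(cc$sites), 0L)
  expect_match(cc$reason, "insufficient")
  ## no association at all
  st2 <- c(a = 1L, b = 1L, c = 0L, d = 0L)
  up2 <- setNames(rep(strrep("A", 40), 4), names(st2))
  cc2 <- detect_coconversion(st2, up2, up2, window = 10)
  expect_identical(nrow(cc2$sites), 0L)
})

test_that("prefix-family scan groups full-length sequence types", {
  set.seed(211)
  pre <- "ACTCCTTCGGGGT"
  c1 <- paste0(pre, "CCGCCCCGCGGGGGCGGGCCGG")
  c2 <- paste0(pre, "CCCCGCCGGGGCGGGG")
  ## fixed AT spacers pin the greedy extension boundary across contexts
  sp6 <- strrep("TA", 3)
  g1 <- genome("a", paste0(at_rich(500), c1, sp6, at_rich(500), c2, sp6,
                           at_rich(400), c1, sp6, at_rich(300)))
  g2 <- genome("b", paste0(at_rich(600), c2, sp6, at_rich(700)))
  fs <- prefix_family_scan(list(a = g1, b = g2), pre)
  expect_identical(nrow(fs$types), 2L)
  expect_identical(sum(fs$types$n_copies), 4L)
  expect_identical(fs$types$n_strains, c(2L, 1L))
  ## a minus-strand cluster is found too
  g3 <- genome("c", paste0(at_rich(500), gcturnover:::revcomp(paste0(c1, sp6)),
                           at_rich(500)))
  fs3 <- prefix_family_scan(list(c = g3), pre)
  expect_identical(nrow(fs3$types), 1L)
  ## absent prefix
  expect_identical(nrow(prefix_family_scan(list(a = genome("x",
    at_rich(2000))), pre)$types), 0L)
})

test_that("neighbour joining recovers topology deterministically", {
  s <- c(A = paste0(strrep("A", 10), strrep("T", 10)),
         B = paste0(strrep("A", 10), strrep("T", 8), "AA"),
         C = paste0(strrep("C", 10), strrep("T", 10)),
         D = paste0(strrep("C", 10), strrep("T", 8), "GG"))
  t1 <- nj_tree(s)
  expect_true(ape::is.monophyletic(t1, c("A", "B")))
  expect_true(ape::is.monophyletic(t1, c("C", "D")))
  t2 <- nj_tree(s[c(3, 1, 4, 2)])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  ## three taxa: the unique unrooted topology
  expect_identical(ape::Ntip(nj_tree(s[1:3])), 3L)
  ## identical sequences resolve deterministically
  same <- setNames(rep(strrep("ACGT", 5), 4), letters[1:4])
  expect_equal(as.numeric(ape::dist.topo(nj_tree(same), nj_tree(same))), 0)
})

test_that("horizontal-exchange calls require both identity and flank support", {
  set.seed(212)
  upA <- at_rich(100); dnA <- at_rich(100)
  upB <- mutate_k(upA, 12); dnB <- mutate_k(dnA, 12)
  elemA <- gc42
  elemB <- mutate_k(elemA, 5)
  strains <- c(paste0("cer", 1:4), paste0("par", 1:4))
  species <- setNames(rep(c("cerevisiae", "paradoxus"), each = 4), strains)
  up <- setNames(c(mutate_k(upA, 1), mutate_k(upA, 2), mutate_k(upA, 1),
                   mutate_k(upA, 2), mutate_k(upB, 1), mutate_k(upB, 2),
                   mutate_k(upB, 1), mutate_k(upB, 1)), strains)
  dn <- setNames(c(mutate_k(dnA, 1), mutate_k(dnA, 2), mutate_k(dnA, 1),
                   mutate_k(dnA, 2), mutate_k(dnB, 1), mutate_k(dnB, 2),
                   mutate_k(dnB, 1), mutate_k(dnB, 1)), strains)
  elems <- setNames(c(mutate_k(elemA, 1), mutate_k(elemA, 1),
                      mutate_k(elemA, 2), mutate_k(elemA, 1),
                      mutate_k(elemB, 1), mutate_k(elemB, 1),
                      mutate_k(elemB, 2), mutate_k(elemB, 1)), strains)
  ## concordant position: nothing flagged
  t0 <- classify_transfer(elems, species, up, dn)
  expect_identical(sum(t0$flagged), 0L)
  ## transfer into par4: element and flanks come from the other species
  elems["par4"] <- elemA
  up["par4"] <- mutate_k(upA, 1); dn["par4"] <- mutate_k(dnA, 1)
  t1 <- classify_transfer(elems, species, up, dn)
  expect_identical(t1$strain[t1$flagged], "par4")
  r <- t1[t1$strain == "par4", ]
  ## the recipient's element is far closer to the donor-species consensus
  expect_gt(r$identity_other, 0.97)
  expect_lt(r$identity_own, 0.92)
  ## identity margin alone (without flank support) does not flag:
  ## restore paradoxus-like flanks but keep the cerevisiae-like element
  up["par4"] <- mutate_k(upB, 1); dn["par4"] <- mutate_k(dnB, 1)
  t2 <- classify_transfer(elems, species, up, dn)
  expect_identical(sum(t2$flagged), 0L)
  expect_true(t2$closer_to_other[t2$strain == "par4"])
})

test_that("no transfers are flagged on transfer-free simulated data", {
  sp <- sim_params(n_taxa = 10, n_positions = 8, genome_length = 10000,
                   seed = 13)
  sim <- simulate_dataset(sp)
  species <- setNames(rep(c("spA", "spB"), each = 5), names(sim$genomes))
  flank <- sim$truth$flanks
  n_flagged <- 0L
  for (j in seq_len(nrow(sim$truth$elements))) {
    el <- sim$truth$elements[j, ]
    carriers <- names(el)[!is.na(el)]
    if (length(unique(species[carriers])) < 2L) next
    up <- setNames(rep(flank$upstream[j], length(names(el))), names(el))
    dn <- setNames(rep(flank$downstream[j], length(names(el))), names(el))
    tc <- classify_transfer(el, species, up, dn)
    n_flagged <- n_flagged + sum(tc$flagged)
  }
  expect_identical(n_flagged, 0L)
})
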