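# popgen statistics: pi against brute force, NG86 site counting, Tajima's D,
# inbreeding F, Hudson F_ST, ratio classification, site filter, PCA.

test_that("pi equals brute-force pairwise difference counting", {
  set.seed(101)
  for (rep in 1:30) {
    n_hap <- 2 * sample(3:8, 1)
    L <- 3 * sample(2:8, 1)
    wild <- random_alignment(n_hap, L,
      n_alleles = sample(2:4, 1),
      missing = sample(c(0, 0.15), 1)
    )
    crop <- random_alignment(n_hap, L, n_alleles = 2)
    g <- toy_gene(wild, crop)
    # reconstruct the full alignments the object represents
    full_w <- as_alignment_matrix(g, "wild")
    full_c <- as_alignment_matrix(g, "crop")
    expect_equal(nucleotide_diversity(g, "wild"), brute_pi(full_w),
      tolerance = 1e-12
    )
    expect_equal(nucleotide_diversity(g, "crop"), brute_pi(full_c),
      tolerance = 1e-12
    )
  }
})

test_that("pi matches hand-computed toy values", {
  # 4 haplotypes, 12 sites, one site split 2/2: pi = (4/6)/12
  # (mean over the 6 haplotype pairs: 4 differing pairs, scaled per site)
  wild <- matrix("A", 4, 12)
  wild[3:4, 5] <- "T"
  g <- toy_gene(wild, matrix("A", 4, 12))
  expect_equal(nucleotide_diversity(g, "wild"), (4 / 6) / 12)

  # all four alleles distinct at one site, n = 4: site pi = (1 - 1/4)*(4/3)
  wild2 <- matrix("A", 4, 9)
  wild2[, 1] <- c("A", "C", "G", "T")
  g2 <- toy_gene(wild2, matrix("A", 4, 9))
  expect_equal(nucleotide_diversity(g2, "wild"), (1 - 0.25) * (4 / 3) / 9)

  # monomorphic alignment
  g3 <- toy_gene(matrix("C", 6, 6), matrix("C", 6, 6))
  expect_equal(nucleotide_diversity(g3, "wild"), 0)
})

test_that("NG86 site counts follow the code table and sum to 3", {
  counts <- ng86_site_counts("TTT")
  expect_equal(unname(counts["syn"]), 1 / 3)
  expect_equal(unname(counts["nonsyn"]), 8 / 3)
  # every sense codon sums to exactly 3
  gc <- Biostrings::GENETIC_CODE
  for (cod in names(gc)[gc != "*"]) {
    cnt <- ng86_site_counts(cod)
    expect_equal(unname(cnt["syn"] + cnt["nonsyn"]), 3)
  }
})

test_that("synonymous-only divergence yields piS > 0 and piN = 0", {
  # two haplotype classes differing only by TTT <-> TTC (Phe, synonymous)
  wild <- matrix(rep(strsplit("TTTGCAAAG", "")[[1]], each = 4), nrow = 4)
  wild[3:4, 3] <- "C"
  g <- toy_gene(wild, wild)
  sn <- syn_nonsyn_diversity(g, "wild")
  expect_gt(sn$pi_s, 0)
  expect_equal(sn$pi_n, 0)
  expect_equal(sn$pin_pis, 0)

  # nonsynonymous-only: TTT <-> GTT (Phe -> Val)
  wild2 <- matrix(rep(strsplit("TTTGCAAAG", "")[[1]], each = 4), nrow = 4)
  wild2[3:4, 1] <- "G"
  g2 <- toy_gene(wild2, wild2)
  sn2 <- syn_nonsyn_diversity(g2, "wild")
  expect_equal(sn2$pi_s, 0)
  expect_gt(sn2$pi_n, 0)
  expect_true(is.na(sn2$pin_pis))
})

test_that("pathway averaging handles multi-hit codons and excludes stops", {
  # TTT (Phe) vs GTA (Val): path via GTT gives 1 syn + 1 nonsyn, path via
  # TTA gives 2 nonsyn; averaging over both -> 0.5 syn, 1.5 nonsyn
  d <- wildcrop:::codon_pair_diffs("TTT", "GTA")
  expect_equal(unname(d["syn"]), 0.5)
  expect_equal(unname(d["nonsyn"]), 1.5)
  # TAT (Tyr) vs TGG (Trp): the path via TAG crosses a stop and is
  # excluded, leaving the single valid path with 2 nonsyn steps
  d2 <- wildcrop:::codon_pair_diffs("TAT", "TGG")
  expect_equal(unname(d2["syn"]), 0)
  expect_equal(unname(d2["nonsyn"]), 2)
  # single-difference codon pairs are trivial
  d3 <- wildcrop:::codon_pair_diffs("TTT", "TTC")
  expect_equal(unname(d3["syn"]), 1)
  expect_equal(unname(d3["nonsyn"]), 0)
})

test_that("genome-wide piN/piS reproduces the generator's planted ratio", {
  p <- sim_params(n_genes = 250, pin_pis_ratio = 0.16, missing_rate = 0, seed = 21)
  sim <- simulate_genotypes(p)
  ps <- popgen_stats(sim)
  w <- ps[ps$pool == "wild", ]
  ratio <- mean(w$pi_n, na.rm = TRUE) / mean(w$pi_s, na.rm = TRUE)
  expect_equal(ratio, 0.16, tolerance = 0.25)
})

test_that("Tajima's D machinery matches independent evaluations", {
  # constants for n = 10, frozen from an exact-fraction computation
  cons <- tajima_constants(10)
  expect_equal(cons[["a1"]], 2.828968253968254, tolerance = 1e-10)
  expect_equal(cons[["a2"]], 1.5397677311665408, tolerance = 1e-10)
  expect_equal(cons[["b1"]], 0.4074074074074074, tolerance = 1e-10)
  expect_equal(cons[["b2"]], 0.27901234567901234, tolerance = 1e-10)
  expect_equal(cons[["c1"]], 0.05392164502839212, tolerance = 1e-10)
  expect_equal(cons[["c2"]], 0.04722677200132802, tolerance = 1e-10)
  expect_equal(cons[["e1"]], 0.01906053380159183, tolerance = 1e-10)
  expect_equal(cons[["e2"]], 0.004948927769896327, tolerance = 1e-10)

  # n = 4, S = 3, kbar = 1.5: frozen independent closed-form value
  expect_equal(tajima_d_stat(1.5, 3, 4), -0.7544510776527723,
    tolerance = 1e-10
  )
  # kbar = S/a1 makes the numerator exactly zero
  a1 <- tajima_constants(10)[["a1"]]
  expect_equal(tajima_d_stat(5 / a1, 5, 10), 0)
  # undefined cases
  expect_true(is.na(tajima_d_stat(0, 0, 10)))
  expect_true(is.na(tajima_d_stat(1, 2, 3)))
})

test_that("neutral simulation centres Tajima's D near zero", {
  p <- sim_params(
    n_genes = 1000, f_wild = 0, f_crop = 0, missing_rate = 0,
    prop_swept = 0, gene_length_codons = 200, seed = 31
  )
  sim <- simulate_genotypes(p)
  d <- popgen_stats(sim)
  dw <- d$tajima_d[d$pool == "wild"]
  expect_lt(abs(mean(dw, na.rm = TRUE)), 0.15)
  expect_lt(abs(median(dw, na.rm = TRUE)), 0.15)
})

test_that("site filter drops under-called sites codon-wise", {
  # 3 codons; one site of codon 2 called in 4/9 wild individuals
  wild <- random_alignment(18, 9, n_alleles = 1)
  wild[, 5] <- "A"
  gone <- 1:5 # 5 individuals missing -> 4 called
  wild[c(2 * gone - 1, 2 * gone), 5] <- "N"
  crop <- random_alignment(22, 9, n_alleles = 1)
  g <- toy_gene(wild, crop)
  gf <- filter_sites(g, min_called = 5)
  expect_equal(gf$L, 6) # codon 2 dropped entirely
  expect_equal(attr(gf, "n_codons_removed"), 1)

  # no missing data: identity
  g2 <- toy_gene(
    random_alignment(18, 12, n_alleles = 2),
    random_alignment(22, 12, n_alleles = 2)
  )
  gf2 <- filter_sites(g2, min_called = 5)
  expect_equal(gf2$L, 12)
  expect_identical(gf2$wild_hap, g2$wild_hap)
  expect_equal(attr(gf2, "n_codons_removed"), 0)
})

test_that("inbreeding F behaves at its fixed points and recovers HWE", {
  # every individual homozygous, allele frequency 0.5 -> F = 1
  wild <- matrix(rep(c("A", "A", "T", "T"), 3), nrow = 12, ncol = 6)
  g <- toy_gene(wild, wild)
  expect_equal(fixation_index(g, "wild")$f_hat, 1)

  # Hardy-Weinberg genotypes at many sites -> F near 0
  set.seed(7)
  n_ind <- 40
  L <- 300
  hw <- matrix("A", 2 * n_ind, L)
  for (s in seq_len(L)) {
    p <- runif(1, 0.2, 0.8)
    hw[, s] <- ifelse(runif(2 * n_ind) < p, "A", "G")
  }
  ghw <- toy_gene(hw, hw)
  expect_lt(abs(fixation_index(ghw, "wild")$f_hat), 0.05)
})

test_that("Hudson F_ST matches fixed points and a site-by-site oracle", {
  # fixed difference -> F_ST = 1
  wild <- matrix("A", 8, 3)
  crop <- matrix("A", 8, 3)
  wild[, 2] <- "A"
  crop[, 2] <- "T"
  g <- toy_gene(wild, crop)
  expect_equal(hudson_fst(g), 1)

  # identical allele frequencies -> F_ST ~ 0 (negative expected value of
  # the unbiased estimator is ~0 at matched frequencies)
  set.seed(11)
  base <- random_alignment(20, 30, n_alleles = 2)
  g2 <- toy_gene(base, base[sample(20), ])
  expect_lt(abs(hudson_fst(g2)), 0.12)

  # two-site toy gene against the brute-force Hudson oracle
  wild3 <- matrix("A", 10, 6)
  crop3 <- matrix("A", 10, 6)
  wild3[1:2, 1] <- "G" # p_wild = 0.2
  crop3[1:8, 1] <- "G" # p_crop = 0.8
  wild3[1:5, 4] <- "C" # 0.5 vs 0.5
  crop3[1:5, 4] <- "C"
  g3 <- toy_gene(wild3, crop3)
  expect_equal(hudson_fst(g3), brute_fst(wild3, crop3), tolerance = 1e-12)
})

test_that("F_ST increases with simulated pool divergence", {
  fst_at <- function(b, seed) {
    p <- sim_params(
      n_genes = 150, bottleneck_ratio = b, prop_swept = 0,
      gene_length_codons = 150, seed = seed
    )
    mean(pairwise_stats(simulate_genotypes(p))$fst, na.rm = TRUE)
  }
  f_weak <- fst_at(0.95, 13)
  f_strong <- fst_at(0.35, 13)
  expect_gt(f_strong, f_weak)
})

test_that("diversity-ratio classification follows its definitions", {
  cl <- classify_diversity_ratio(
    pi_crop = c(0, 0, 1.3e-3, 2.5e-3, 1e-3, 0.5e-3),
    pi_wild = c(2e-3, 0, 2e-3, 2e-3, 2e-3, 2e-3)
  )
  expect_equal(
    as.character(cl$selection_class),
    c("sweep_candidate", "undefined", "baseline", "elevated", "reduced", "reduced")
  )
  expect_equal(cl$ratio[3], 0.65)
  expect_true(is.na(cl$ratio[2]))
  # x/0 is infinite
  cl2 <- classify_diversity_ratio(1e-3, 0)
  expect_true(is.infinite(cl2$ratio))
})

test_that("genotype PCA separates the pools and is deterministic", {
  sim <- simulate_genotypes(sim_params(n_genes = 120, seed = 17))
  gm <- genotype_matrix(sim)
  labels <- tibble::tibble(
    accession = rownames(gm),
    pool = ifelse(grepl("^W", rownames(gm)), "wild", "crop")
  )
  pc <- genotype_pca(gm, labels)
  # PC1 linearly separates the pools
  w <- pc$scores$PC1[pc$scores$pool == "wild"]
  cr <- pc$scores$PC1[pc$scores$pool == "crop"]
  expect_true(max(w) < min(cr) || max(cr) < min(w))
  expect_true(all(pc$var_explained >= 0))
  expect_lte(sum(pc$var_explained), 1 + 1e-8)

  # duplicated samples get identical coordinates
  gm2 <- rbind(gm, dup = gm[1, ])
  pc2 <- genotype_pca(gm2)
  expect_equal(
    unlist(pc2$scores[nrow(gm2), -1]),
    unlist(pc2$scores[1, -1]),
    tolerance = 1e-8
  )
})
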