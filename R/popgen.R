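# Per-gene population-genetic statistics: pi, piS/piN (NG86), Tajima's D,
# inbreeding F, Hudson's F_ST, diversity-ratio classification.

site_allele_freqs <- function(hap_col) {
  called <- hap_col[hap_col != "N"]
  n <- length(called)
  if (n < 2) {
    return(list(n = n, het = NA_real_, freqs = NULL))
  }
  p <- table(called) / n
  list(n = n, het = (1 - sum(p^2)) * n / (n - 1), freqs = p)
}

#' Per-site nucleotide diversity of one pool
#'
#' Unbiased average pairwise difference per site:
#' `pi = mean over sites of (1 - sum p_a^2) * n/(n-1)` with `n` the called
#' haplotypes at the site; equals the mean pairwise Hamming distance per
#' site. Sites with fewer than two called haplotypes contribute zero and the
#' gene is flagged undefined if no site has two calls.
#'
#' @param gene A `gene_geno` object.
#' @param pool `"wild"` or `"crop"`.
#' @return Per-site pi (numeric scalar; `NA` if undefined).
#' @export
nucleotide_diversity <- function(gene, pool) {
  stopifnot(inherits(gene, "gene_geno"))
  if (gene$L == 0) {
    return(NA_real_)
  }
  hap <- pool_hap(gene, pool)
  if (ncol(hap) == 0) {
    return(0)
  }
  het <- vapply(seq_len(ncol(hap)), function(s) {
    a <- site_allele_freqs(hap[, s])
    if (is.na(a$het)) 0 else a$het
  }, numeric(1))
  sum(het) / gene$L
}

# mean pairwise difference count (kbar = pi * L), used by Tajima's D
mean_pairwise_diffs <- function(gene, pool) {
  pi <- nucleotide_diversity(gene, pool)
  pi * gene$L
}

segregating_sites <- function(gene, pool) {
  hap <- pool_hap(gene, pool)
  if (ncol(hap) == 0) {
    return(0L)
  }
  poly <- vapply(seq_len(ncol(hap)), function(s) {
    alleles <- unique(hap[hap[, s] != "N", s])
    length(alleles) >= 2
  }, logical(1))
  sum(poly)
}

#' Tajima's D constants
#'
#' The standard normalization constants (a1, a2, b1, b2, c1, c2, e1, e2) for
#' a sample of `n` haplotypes.
#'
#' @param n Number of sampled haplotypes (>= 2).
#' @return Named numeric vector.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D from summary quantities
#'
#' `D = (kbar - S/a1) / sqrt(e1*S + e2*S*(S-1))` with `kbar` the mean
#' pairwise difference count and `S` the number of segregating sites.
#'
#' @param kbar Mean pairwise differences.
#' @param S Segregating sites (must be >= 1 for a defined D).
#' @param n Number of haplotypes (>= 4).
#' @return Tajima's D, or `NA` when `S = 0` or `n < 4`.
#' @export
tajima_d_stat <- function(kbar, S, n) {
  if (is.na(S) || S < 1 || is.na(n) || n < 4) {
    return(NA_real_)
  }
  cons <- tajima_constants(n)
  denom <- sqrt(cons[["e1"]] * S + cons[["e2"]] * S * (S - 1))
  (kbar - S / cons[["a1"]]) / denom
}

#' Tajima's D of one pool of a gene
#'
#' Uses the unbiased per-site pi summed over the callable length for `kbar`.
#' Under missing data the sample size `n` is the median per-site count of
#' called haplotypes at segregating sites.
#'
#' @inheritParams nucleotide_diversity
#' @return Tajima's D (`NA` when there is no segregating site).
#' @export
tajimas_d <- function(gene, pool) {
  S <- segregating_sites(gene, pool)
  if (S == 0) {
    return(NA_real_)
  }
  hap <- pool_hap(gene, pool)
  n_site <- colSums(hap != "N")
  n <- stats::median(n_site[n_site >= 2])
  tajima_d_stat(mean_pairwise_diffs(gene, pool), S, n)
}

#' Synonymous and nonsynonymous diversity (NG86)
#'
#' Nei-Gojobori site counting with the universal genetic code: synonymous and
#' nonsynonymous site totals are averaged over called haplotype codons;
#' pairwise synonymous/nonsynonymous differences average over the shortest
#' mutational pathways between codon pairs, excluding pathways through stop
#' codons. Codons containing missing data are skipped for the affected
#' haplotypes. `piN/piS` is undefined (`NA`) when `piS = 0`.
#'
#' @inheritParams nucleotide_diversity
#' @return A tibble with columns `pi_s`, `pi_n`, `pin_pis`, `syn_sites`,
#'   `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`.
#' @export
syn_nonsyn_diversity <- function(gene, pool) {
  stopifnot(inherits(gene, "gene_geno"))
  empty <- tibble::tibble(
    pi_s = NA_real_, pi_n = NA_real_, pin_pis = NA_real_,
    syn_sites = NA_real_, nonsyn_sites = NA_real_,
    syn_diffs = NA_real_, nonsyn_diffs = NA_real_
  )
  if (gene$L == 0) {
    return(empty)
  }
  hap <- pool_hap(gene, pool)
  anc_chars <- strsplit(gene$anc, "")[[1]]
  n_codon <- gene$L %/% 3L
  anc_codons <- substring(
    gene$anc, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon)
  )
  var_codon <- if (length(gene$pos) > 0) {
    sort(unique((gene$pos - 1L) %/% 3L + 1L))
  } else {
    integer(0)
  }

  Ls <- 0
  Ln <- 0
  Sd <- 0
  Nd <- 0
  # invariant codons: ancestral counts, weight 1
  inv_codon <- setdiff(seq_len(n_codon), var_codon)
  if (length(inv_codon) > 0) {
    counts <- vapply(anc_codons[inv_codon], ng86_site_counts, numeric(2))
    Ls <- Ls + sum(counts["syn", ], na.rm = TRUE)
    Ln <- Ln + sum(counts["nonsyn", ], na.rm = TRUE)
  }
  for (ci in var_codon) {
    sites_in <- which((gene$pos - 1L) %/% 3L + 1L == ci)
    offs <- (gene$pos[sites_in] - 1L) %% 3L + 1L
    base_cod <- strsplit(anc_codons[ci], "")[[1]]
    n_hap <- nrow(hap)
    cods <- vapply(seq_len(n_hap), function(h) {
      cc <- base_cod
      cc[offs] <- hap[h, sites_in]
      paste(cc, collapse = "")
    }, character(1))
    ok <- !grepl("N", cods, fixed = TRUE)
    cods <- cods[ok]
    if (length(cods) == 0) next
    tb <- table(cods)
    types <- names(tb)
    m <- as.numeric(tb)
    site_counts <- vapply(types, ng86_site_counts, numeric(2))
    w <- m / sum(m)
    Ls <- Ls + sum(site_counts["syn", ] * w, na.rm = TRUE)
    Ln <- Ln + sum(site_counts["nonsyn", ] * w, na.rm = TRUE)
    n_called <- sum(m)
    if (n_called >= 2 && length(types) >= 2) {
      npairs <- n_called * (n_called - 1) / 2
      for (a in seq_along(types)[-length(types)]) {
        for (b in (a + 1):length(types)) {
          d <- codon_pair_diffs(types[a], types[b])
          Sd <- Sd + m[a] * m[b] * d[["syn"]] / npairs
          Nd <- Nd + m[a] * m[b] * d[["nonsyn"]] / npairs
        }
      }
    }
  }
  pi_s <- if (Ls > 0) Sd / Ls else NA_real_
  pi_n <- if (Ln > 0) Nd / Ln else NA_real_
  tibble::tibble(
    pi_s = pi_s, pi_n = pi_n,
    pin_pis = ifelse(!is.na(pi_s) && pi_s > 0, pi_n / pi_s, NA_real_),
    syn_sites = Ls, nonsyn_sites = Ln, syn_diffs = Sd, nonsyn_diffs = Nd
  )
}

# observed / expected heterozygosity sums of one pool of one gene
het_sums <- function(gene, pool) {
  hap <- pool_hap(gene, pool)
  n_ind <- if (pool == "wild") gene$n_wild else gene$n_crop
  if (ncol(hap) == 0) {
    return(c(hobs = 0, hexp = 0))
  }
  hobs <- 0
  hexp <- 0
  for (s in seq_len(ncol(hap))) {
    a1 <- hap[2 * seq_len(n_ind) - 1, s]
    a2 <- hap[2 * seq_len(n_ind), s]
    called <- a1 != "N" & a2 != "N"
    if (sum(called) < 2) next
    alleles <- c(a1[called], a2[called])
    p <- table(alleles) / length(alleles)
    if (length(p) < 2) next
    n_hap <- length(alleles)
    hexp <- hexp + (1 - sum(p^2)) * n_hap / (n_hap - 1)
    hobs <- hobs + mean(a1[called] != a2[called])
  }
  c(hobs = hobs, hexp = hexp)
}

#' Inbreeding coefficient F from diploid genotypes
#'
#' `F = 1 - H_obs / H_exp`, aggregated as a ratio of sums over all
#' polymorphic sites of the supplied genes (per pool). `H_exp` uses the
#' unbiased (n/(n-1)) sample heterozygosity.
#'
#' @param genes A `genotype_sim`, a tibble with a `geno` list-column, or a
#'   list of `gene_geno` objects.
#' @param pool `"wild"` or `"crop"`.
#' @param n_boot Optional bootstrap replicates (over genes) for a 95% CI.
#' @return A tibble with `pool`, `f_hat`, and CI columns when `n_boot > 0`.
#' @export
fixation_index <- function(genes, pool, n_boot = 0L) {
  gl <- gene_list(genes)
  sums <- vapply(gl, het_sums, numeric(2), pool = pool)
  f_from <- function(idx) {
    ho <- sum(sums["hobs", idx])
    he <- sum(sums["hexp", idx])
    if (he == 0) NA_real_ else 1 - ho / he
  }
  out <- tibble::tibble(pool = pool, f_hat = f_from(seq_len(ncol(sums))))
  if (n_boot > 0) {
    reps <- vapply(seq_len(n_boot), function(i) {
      f_from(sample.int(ncol(sums), replace = TRUE))
    }, numeric(1))
    qs <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    out$f_lo <- qs[1]
    out$f_hi <- qs[2]
  }
  out
}

#' Hudson's F_ST of a gene
#'
#' Ratio-of-averages Hudson estimator:
#' `F_ST = 1 - sum(Hw) / sum(Hb)` over sites, where `Hw` is the mean of the
#' two unbiased within-pool heterozygosities and
#' `Hb = p1(1-p2) + p2(1-p1)` the between-pool heterozygosity. Negative
#' estimates are kept (not truncated). `NA` when no site has between-pool
#' heterozygosity.
#'
#' @param gene A `gene_geno` object.
#' @return F_ST (numeric scalar, possibly negative, `NA` if undefined).
#' @export
hudson_fst <- function(gene) {
  stopifnot(inherits(gene, "gene_geno"))
  if (length(gene$pos) == 0) {
    return(NA_real_)
  }
  hw_sum <- 0
  hb_sum <- 0
  any_site <- FALSE
  for (s in seq_along(gene$pos)) {
    w <- gene$wild_hap[, s]
    c_ <- gene$crop_hap[, s]
    w <- w[w != "N"]
    c_ <- c_[c_ != "N"]
    if (length(w) < 2 || length(c_) < 2) next
    alleles <- unique(c(w, c_))
    if (length(alleles) < 2) next
    pw <- vapply(alleles, function(a) mean(w == a), numeric(1))
    pc <- vapply(alleles, function(a) mean(c_ == a), numeric(1))
    hw <- ((1 - sum(pw^2)) * length(w) / (length(w) - 1) +
      (1 - sum(pc^2)) * length(c_) / (length(c_) - 1)) / 2
    hb <- 1 - sum(pw * pc)
    any_site <- TRUE
    hw_sum <- hw_sum + hw
    hb_sum <- hb_sum + hb
  }
  if (!any_site || hb_sum == 0) {
    return(NA_real_)
  }
  1 - hw_sum / hb_sum
}

#' Classify the crop/wild diversity ratio of genes
#'
#' `r = pi_crop / pi_wild` with 0/0 undefined and x/0 infinite. Classes:
#' `sweep_candidate` (r = 0 with polymorphic wild), `reduced`
#' (0 < r < baseline), `baseline` (baseline <= r <= 1), `elevated` (r > 1)
#' and `undefined` (pi_wild = 0).
#'
#' @param pi_crop,pi_wild Numeric vectors of per-gene diversity.
#' @param baseline Genome-wide bottleneck ratio taken as the neutral
#'   expectation (default 0.65).
#' @return A tibble with `ratio` and `selection_class`.
#' @export
classify_diversity_ratio <- function(pi_crop, pi_wild, baseline = 0.65) {
  stopifnot(length(pi_crop) == length(pi_wild))
  ratio <- ifelse(
    pi_wild > 0, pi_crop / pi_wild,
    ifelse(pi_crop > 0, Inf, NA_real_)
  )
  eps <- 1e-9 # guard the class boundaries against floating-point noise
  cls <- dplyr::case_when(
    is.na(pi_wild) | is.na(pi_crop) ~ "undefined",
    pi_wild == 0 ~ "undefined",
    pi_crop == 0 ~ "sweep_candidate",
    ratio < baseline - eps ~ "reduced",
    ratio <= 1 + eps ~ "baseline",
    TRUE ~ "elevated"
  )
  tibble::tibble(
    ratio = ratio,
    selection_class = factor(
      cls,
      levels = c(
        "sweep_candidate", "reduced", "baseline", "elevated", "undefined"
      )
    )
  )
}

gene_list <- function(genes) {
  if (inherits(genes, "genotype_sim")) {
    return(genes$genes$geno)
  }
  if (is.data.frame(genes) && "geno" %in% names(genes)) {
    return(genes$geno)
  }
  if (inherits(genes, "gene_geno")) {
    return(list(genes))
  }
  stopifnot(is.list(genes))
  genes
}

#' Per-gene diversity statistics for both pools
#'
#' Applies the site filter then computes, per gene and pool: per-site pi,
#' synonymous/nonsynonymous pi and their ratio, segregating sites, Tajima's D
#' and the number of sites used.
#'
#' @param genes A `genotype_sim`, tibble with `geno` list-column, or list of
#'   `gene_geno` objects.
#' @param min_called Site filter threshold (called individuals per pool).
#' @return A tibble, one row per gene x pool.
#' @examples
#' sim <- simulate_genotypes(sim_params(n_genes = 3, seed = 1))
#' popgen_stats(sim)
#' @export
popgen_stats <- function(genes, min_called = 5L) {
  gl <- gene_list(genes)
  purrr::map_dfr(gl, function(g) {
    gf <- filter_sites(g, min_called = min_called)
    purrr::map_dfr(c("wild", "crop"), function(pool) {
      sn <- syn_nonsyn_diversity(gf, pool)
      tibble::tibble(
        gene_id = gf$gene_id,
        pool = pool,
        n_sites_used = gf$L,
        s_seg = segregating_sites(gf, pool),
        pi = nucleotide_diversity(gf, pool),
        pi_s = sn$pi_s,
        pi_n = sn$pi_n,
        pin_pis = sn$pin_pis,
        tajima_d = tajimas_d(gf, pool)
      )
    })
  })
}

#' Per-gene between-pool comparison statistics
#'
#' Hudson's F_ST, the crop/wild diversity ratio and its selection class
#' (after site filtering).
#'
#' @inheritParams popgen_stats
#' @param baseline Neutral bottleneck ratio for classification.
#' @return A tibble, one row per gene.
#' @export
pairwise_stats <- function(genes, min_called = 5L, baseline = 0.65) {
  gl <- gene_list(genes)
  purrr::map_dfr(gl, function(g) {
    gf <- filter_sites(g, min_called = min_called)
    pw <- nucleotide_diversity(gf, "wild")
    pc <- nucleotide_diversity(gf, "crop")
    cl <- classify_diversity_ratio(pc, pw, baseline = baseline)
    tibble::tibble(
      gene_id = gf$gene_id,
      fst = hudson_fst(gf),
      pi_wild = pw, pi_crop = pc,
      ratio = cl$ratio, selection_class = cl$selection_class
    )
  })
}

#' Genotype matrix (derived-allele dosage) across genes
#'
#' Assembles an individuals-by-sites dosage matrix (0/1/2 copies of the
#' non-ancestral allele, `NA` for missing genotypes) over all polymorphic
#' sites, for use with [diversity_pca()].
#'
#' @inheritParams popgen_stats
#' @return Numeric matrix, rownames = accessions.
#' @export
genotype_matrix <- function(genes) {
  gl <- gene_list(genes)
  blocks <- purrr::map(gl, function(g) {
    if (length(g$pos) == 0) {
      return(NULL)
    }
    anc_chars <- strsplit(g$anc, "")[[1]]
    hap <- rbind(g$wild_hap, g$crop_hap)
    n_ind <- nrow(hap) / 2L
    dos <- matrix(NA_real_, n_ind, ncol(hap))
    anc_b <- anc_chars[g$pos]
    for (s in seq_len(ncol(hap))) {
      a1 <- hap[2 * seq_len(n_ind) - 1, s]
      a2 <- hap[2 * seq_len(n_ind), s]
      d <- (a1 != anc_b[s]) + (a2 != anc_b[s])
      d[a1 == "N" | a2 == "N"] <- NA
      dos[, s] <- d
    }
    rn <- rownames(hap)[2 * seq_len(n_ind)]
    rownames(dos) <- sub("_[12]$", "", rn)
    colnames(dos) <- paste0(g$gene_id, ":", g$pos)
    dos
  })
  do.call(cbind, purrr::compact(blocks))
}
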