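# Coalescent-free genotype simulator: per-gene segregating sites drawn from
# the neutral folded SFS, a lineage-thinning bottleneck in the crop pool,
# selfing modeled as probability-f haplotype duplication, and coverage-style
# missingness. Marginal diversity/SFS structure only; no recombination or
# linkage between genes.

a1_constant <- function(n) sum(1 / seq_len(n - 1))

# Solve the thinning size m from the target per-gene diversity ratio.
# Measured expectations (unbiased pi estimators):
#   wild per seg site: 2*p(1-p) * nw/(nw-1) * (nw-1-fw)/(nw-1)
#   crop per seg site: 2*p(1-p) * nw/(nw-1) * (m-1)/m * (nc-1-fc)/(nc-1)
# so  ratio = (m-1)/m * d_crop / d_wild,   d = (n-1-f)/(n-1).
# Returns the target t = (m-1)/m and the integer mixture that attains it.
thinning_plan <- function(params) {
  nw <- 2L * params$n_wild
  nc <- 2L * params$n_crop
  d_w <- (nw - 1 - params$f_wild) / (nw - 1)
  d_c <- (nc - 1 - params$f_crop) / (nc - 1)
  t_target <- params$bottleneck_ratio * d_w / d_c
  t_target <- max(0, t_target)
  max_t <- (nw - 1) / nw # m cannot exceed the number of wild haplotypes
  if (t_target >= max_t) {
    return(list(m_lo = nw, m_hi = nw, w_hi = 0))
  }
  m_star <- 1 / (1 - t_target)
  m_lo <- max(1L, floor(m_star))
  m_hi <- m_lo + 1L
  t_lo <- (m_lo - 1) / m_lo
  t_hi <- (m_hi - 1) / m_hi
  w_hi <- (t_target - t_lo) / (t_hi - t_lo)
  list(m_lo = m_lo, m_hi = m_hi, w_hi = min(1, max(0, w_hi)))
}

# Draw an ancestral coding sequence with no internal stop codons.
draw_ancestral <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

#' Simulate per-gene coding-sequence genotype data for two pools
#'
#' For each gene, segregating sites are drawn with wild-pool allele counts
#' from the neutral folded site frequency spectrum (P(i) proportional to
#' 1/i); derived alleles are placed at random codon positions with
#' nonsynonymous changes down-weighted to plant a target piN/piS, and changes
#' creating stop codons are never introduced. Crop haplotypes resample a
#' thinned subset of the wild lineages so that the expected per-gene
#' pi_crop/pi_wild equals `bottleneck_ratio`; swept genes get monomorphic
#' crop alignments. Diploid individuals pair haplotypes such that with
#' probability f the two haplotypes of an individual are identical (selfing),
#' and genotypes are masked at random with probability `missing_rate`.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `genotype_sim` with elements `genes` (a tibble
#'   with a `geno` list-column of `gene_geno` objects), `truth` (the
#'   ground-truth ledger tibble) and `params`.
#' @examples
#' sim <- simulate_genotypes(sim_params(n_genes = 5, seed = 1))
#' sim$truth
#' @export
simulate_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  set.seed(params$seed)

  nw_hap <- 2L * params$n_wild
  nc_hap <- 2L * params$n_crop
  L <- 3L * params$gene_length_codons
  a1 <- a1_constant(nw_hap)
  # theta_wild is the expected *observed* pi; invert the selfing-duplication
  # loss to get the segregating-site intensity.
  dup_w <- (nw_hap - 1 - params$f_wild) / (nw_hap - 1)
  s_rate <- params$theta_wild * L * a1 / dup_w
  plan <- thinning_plan(params)
  sfs_i <- seq_len(nw_hap - 1L)
  sfs_p <- (1 / sfs_i) / a1
  w_nonsyn <- params$pin_pis_ratio / nonstop_nonsyn_fraction()
  mut_tab <- codon_mutation_table()

  n_swept <- round(params$prop_swept * params$n_genes)
  swept <- rep(FALSE, params$n_genes)
  if (n_swept > 0) swept[sample.int(params$n_genes, n_swept)] <- TRUE

  gene_ids <- sprintf("gene_%04d", seq_len(params$n_genes))
  wild_acc <- sprintf("W%02d", seq_len(params$n_wild))
  crop_acc <- sprintf("C%02d", seq_len(params$n_crop))

  genes <- vector("list", params$n_genes)
  true_pi_w <- true_pi_c <- true_fst <- numeric(params$n_genes)

  for (g in seq_len(params$n_genes)) {
    anc <- draw_ancestral(params$gene_length_codons)
    anc_chars <- strsplit(anc, "")[[1]]
    S <- if (params$theta_wild > 0) stats::rpois(1, s_rate) else 0L
    S <- min(S, L)
    site <- draw_sites(S, anc_chars, mut_tab, w_nonsyn)
    S <- length(site$pos)

    # wild haplotype slots: exact SFS count i placed on random slots
    wild_mat <- matrix(FALSE, nw_hap, max(S, 0L))
    i_count <- if (S > 0) sample(sfs_i, S, replace = TRUE, prob = sfs_p) else integer(0)
    for (s in seq_len(S)) {
      wild_mat[sample.int(nw_hap, i_count[s]), s] <- TRUE
    }

    # crop: per-site hypergeometric thinning of the realized wild lineages
    crop_mat <- matrix(FALSE, nc_hap, max(S, 0L))
    if (!swept[g] && S > 0) {
      m_site <- ifelse(stats::runif(S) < plan$w_hi, plan$m_hi, plan$m_lo)
      for (s in seq_len(S)) {
        founders <- sample.int(nw_hap, m_site[s])
        p_c <- mean(wild_mat[founders, s])
        crop_mat[, s] <- stats::runif(nc_hap) < p_c
      }
    }

    # true (pre-selfing, pre-missingness) quantities for the ledger
    p_w <- colMeans(wild_mat)
    p_c <- colMeans(crop_mat)
    pi_w_sites <- 2 * p_w * (1 - p_w) * nw_hap / (nw_hap - 1)
    pi_c_sites <- 2 * p_c * (1 - p_c) * nc_hap / (nc_hap - 1)
    true_pi_w[g] <- sum(pi_w_sites) / L
    true_pi_c[g] <- sum(pi_c_sites) / L
    hb <- p_w * (1 - p_c) + p_c * (1 - p_w)
    hw <- (pi_w_sites + pi_c_sites) / 2
    true_fst[g] <- if (sum(hb) > 0) 1 - sum(hw) / sum(hb) else NA_real_

    # selfing: whole-gene haplotype duplication within individuals
    wild_mat <- apply_selfing(wild_mat, params$n_wild, params$f_wild)
    crop_mat <- apply_selfing(crop_mat, params$n_crop, params$f_crop)

    # genotype-level missingness
    miss_w <- matrix(
      stats::runif(params$n_wild * S) < params$missing_rate,
      params$n_wild, max(S, 0L)
    )
    miss_c <- matrix(
      stats::runif(params$n_crop * S) < params$missing_rate,
      params$n_crop, max(S, 0L)
    )

    hap_w <- allele_matrix(wild_mat, site, anc_chars, miss_w, wild_acc)
    hap_c <- allele_matrix(crop_mat, site, anc_chars, miss_c, crop_acc)

    called_w <- called_counts(params$n_wild, L, params$missing_rate,
      pos = site$pos, miss = miss_w
    )
    called_c <- called_counts(params$n_crop, L, params$missing_rate,
      pos = site$pos, miss = miss_c
    )

    genes[[g]] <- new_gene_geno(
      gene_id = gene_ids[g], L = L, anc = anc, pos = site$pos,
      wild_hap = hap_w, crop_hap = hap_c,
      wild_called = called_w, crop_called = called_c,
      n_wild = params$n_wild, n_crop = params$n_crop
    )
  }

  truth <- tibble::tibble(
    gene_id = gene_ids,
    is_swept = swept,
    true_pi_wild = true_pi_w,
    true_pi_crop = ifelse(swept, 0, true_pi_c),
    true_fst = true_fst,
    is_de = FALSE, true_lfc = 0, module_id = 0L, is_candidate = FALSE,
    is_expr_only = FALSE
  )

  structure(
    list(
      genes = tibble::tibble(gene_id = gene_ids, geno = genes),
      truth = truth,
      params = params
    ),
    class = "genotype_sim"
  )
}

# Sample segregating-site positions (probability proportional to their total
# mutation-acceptance weight) and a derived base per position.
draw_sites <- function(S, anc_chars, mut_tab, w_nonsyn) {
  if (S == 0) {
    return(list(pos = integer(0), der = character(0)))
  }
  L <- length(anc_chars)
  n_codon <- L %/% 3L
  codons <- substring(
    paste(anc_chars, collapse = ""),
    3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon)
  )
  # per-position weights and alternative classification
  cls <- lapply(codons, function(cod) mut_tab[[cod]])
  w_pos <- numeric(L)
  for (ci in seq_len(n_codon)) {
    cl <- cls[[ci]]$class
    w <- rowSums((cl == "syn") * 1 + (cl == "nonsyn") * w_nonsyn)
    w_pos[(3 * ci - 2):(3 * ci)] <- w
  }
  S <- min(S, sum(w_pos > 0))
  pos <- sort(sample.int(L, S, prob = w_pos))
  der <- vapply(pos, function(p) {
    ci <- (p - 1L) %/% 3L + 1L
    off <- (p - 1L) %% 3L + 1L
    cl <- cls[[ci]]$class[off, ]
    alts <- cls[[ci]]$alts[off, ]
    w <- (cl == "syn") * 1 + (cl == "nonsyn") * w_nonsyn
    alts[sample.int(3L, 1L, prob = w)]
  }, character(1))
  list(pos = pos, der = der)
}

apply_selfing <- function(hap, n_ind, f) {
  if (ncol(hap) == 0 || f <= 0) {
    return(hap)
  }
  selfed <- stats::runif(n_ind) < f
  for (k in which(selfed)) hap[2 * k, ] <- hap[2 * k - 1, ]
  hap
}

allele_matrix <- function(derived, site, anc_chars, miss, acc) {
  S <- length(site$pos)
  n_hap <- nrow(derived)
  m <- matrix("N", n_hap, S)
  if (S > 0) {
    anc_b <- anc_chars[site$pos]
    for (s in seq_len(S)) {
      m[, s] <- ifelse(derived[, s], site$der[s], anc_b[s])
      gone <- miss[, s]
      if (any(gone)) {
        rows <- c(2 * which(gone) - 1, 2 * which(gone))
        m[rows, s] <- "N"
      }
    }
  }
  rownames(m) <- paste0(rep(acc, each = 2), "_", rep(1:2, length(acc)))
  m
}

# Per-site called-individual counts: observed at segregating sites, drawn
# binomially at invariant sites (only counts matter there).
called_counts <- function(n_ind, L, missing_rate, pos, miss) {
  counts <- stats::rbinom(L, n_ind, 1 - missing_rate)
  if (length(pos) > 0) {
    counts[pos] <- n_ind - colSums(miss)
  }
  as.integer(counts)
}

#' @export
print.genotype_sim <- function(x, ...) {
  cat(sprintf(
    "<genotype_sim> %d genes, %d wild + %d crop accessions\n",
    nrow(x$genes), x$params$n_wild, x$params$n_crop
  ))
  invisible(x)
}
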