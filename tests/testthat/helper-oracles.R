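# Independent oracles and small fixture builders used across the suite.

# random haplotype alignment (character matrix) with optional missing data
random_alignment <- function(n_hap, L, n_alleles = 2, missing = 0) {
  m <- matrix(sample(c("A", "C", "G", "T")[seq_len(n_alleles)],
    n_hap * L,
    replace = TRUE
  ), n_hap, L)
  if (missing > 0) {
    # missing at the genotype level: both haplotypes of an individual
    for (k in seq_len(n_hap / 2)) {
      gone <- runif(L) < missing
      m[2 * k - 1, gone] <- "N"
      m[2 * k, gone] <- "N"
    }
  }
  rownames(m) <- paste0(
    rep(sprintf("a%02d", seq_len(n_hap / 2)), each = 2), "_", rep(1:2, n_hap / 2)
  )
  m
}

# gene_geno from two alignments with accession names W*/C*
toy_gene <- function(wild, crop, gene_id = "toy") {
  rownames(wild) <- paste0(
    rep(sprintf("W%02d", seq_len(nrow(wild) / 2)), each = 2), "_",
    rep(1:2, nrow(wild) / 2)
  )
  rownames(crop) <- paste0(
    rep(sprintf("C%02d", seq_len(nrow(crop) / 2)), each = 2), "_",
    rep(1:2, nrow(crop) / 2)
  )
  gene_geno_from_alignment(gene_id, wild, crop)
}

# brute-force pi: mean pairwise difference per site over called pairs
brute_pi <- function(hap) {
  L <- ncol(hap)
  total <- 0
  for (s in seq_len(L)) {
    col <- hap[, s]
    col <- col[col != "N"]
    n <- length(col)
    if (n < 2) next
    diffs <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) diffs <- diffs + (col[i] != col[j])
    }
    total <- total + diffs / choose(n, 2)
  }
  unname(total / L)
}

# brute-force Hudson F_ST from two allele matrices (site-by-site sums)
brute_fst <- function(wild, crop) {
  hw_sum <- 0
  hb_sum <- 0
  for (s in seq_len(ncol(wild))) {
    w <- wild[, s]
    cc <- crop[, s]
    w <- w[w != "N"]
    cc <- cc[cc != "N"]
    if (length(w) < 2 || length(cc) < 2) next
    alleles <- unique(c(w, cc))
    if (length(alleles) < 2) next
    pw <- sapply(alleles, function(a) mean(w == a))
    pc <- sapply(alleles, function(a) mean(cc == a))
    hw <- ((1 - sum(pw^2)) * length(w) / (length(w) - 1) +
      (1 - sum(pc^2)) * length(cc) / (length(cc) - 1)) / 2
    hb <- 1 - sum(pw * pc)
    hw_sum <- hw_sum + hw
    hb_sum <- hb_sum + hb
  }
  unname(1 - hw_sum / hb_sum)
}

# step-by-step TMM oracle (weighted doubly trimmed mean of M-values)
oracle_tmm <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(counts)
  cpm75 <- apply(counts, 2, function(x) quantile(x / sum(x), p = 0.75))
  ref <- which.min(abs(cpm75 - mean(cpm75)))
  one_factor <- function(obs, obs_lib) {
    refc <- counts[, ref]
    ref_lib <- lib[ref]
    ok <- obs > 0 & refc > 0
    o <- obs[ok] / obs_lib
    r <- refc[ok] / ref_lib
    M <- log2(o / r)
    A <- (log2(o) + log2(r)) / 2
    w <- (obs_lib - obs[ok]) / (obs_lib * obs[ok]) +
      (ref_lib - refc[ok]) / (ref_lib * refc[ok])
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    f <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    if (!is.finite(f)) f <- 1
    f
  }
  f <- vapply(
    seq_len(ncol(counts)),
    function(j) one_factor(counts[, j], lib[j]), numeric(1)
  )
  f / exp(mean(log(f)))
}

# brute-force TOM (O(n^3) triple sum)
oracle_tom <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  k <- colSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        tom[i, j] <- 1
        next
      }
      num <- a[i, j]
      for (u in seq_len(n)) {
        if (u != i && u != j) num <- num + a[i, u] * a[u, j]
      }
      tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# two-sided Fisher p by hypergeometric enumeration (point-probability rule)
oracle_fisher_p <- function(n11, n10, n01, n00) {
  m <- n11 + n10 # row 1 total
  n_ <- n01 + n00 # row 2 total
  k <- n11 + n01 # col 1 total
  lo <- max(0, k - n_)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  p_obs <- dhyper(n11, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# expression matrix with planted orthogonal modules (genes x samples)
planted_module_expr <- function(n_mod = 3, size = 50, n_bg = 50,
                                n_samp = 20, noise = 0.3, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n_mod * n_samp), n_mod)
  n_genes <- n_mod * size + n_bg
  expr <- matrix(rnorm(n_genes * n_samp, sd = noise), n_genes)
  truth <- integer(n_genes)
  for (m in seq_len(n_mod)) {
    idx <- ((m - 1) * size + 1):(m * size)
    expr[idx, ] <- expr[idx, ] + rep(z[m, ], each = size)
    truth[idx] <- m
  }
  rownames(expr) <- sprintf("g%03d", seq_len(n_genes))
  colnames(expr) <- sprintf("s%02d", seq_len(n_samp))
  list(expr = expr, truth = truth)
}
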