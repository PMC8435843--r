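# Read-count simulator: negative-binomial counts with planted differential
# expression (downregulation-biased in the crop), a crop-wide expression-CV
# shrink with extra loss in the most differentiated genes, and planted
# co-expression modules driven by shared accession-level latent factors.

#' Create a stand-alone truth ledger
#'
#' Used when counts are simulated without a genotype simulation; per-gene
#' nucleotide-level truth columns are empty.
#'
#' @param params A [sim_params()] object.
#' @return A truth tibble with one row per gene.
#' @export
make_truth_ledger <- function(params) {
  tibble::tibble(
    gene_id = sprintf("gene_%04d", seq_len(params$n_genes)),
    is_swept = FALSE,
    true_pi_wild = NA_real_, true_pi_crop = NA_real_, true_fst = NA_real_,
    is_de = FALSE, true_lfc = 0, module_id = 0L, is_candidate = FALSE,
    is_expr_only = FALSE
  )
}

#' Simulate a gene x accession read-count matrix
#'
#' Counts are `NB(mean = lib_i * q_g * 2^(pool effect), dispersion phi)`.
#' DE genes receive a symmetric pool effect of magnitude `lfc_magnitude`
#' (sign convention log2(wild/crop): downregulated-in-crop genes have
#' positive true logFC); exactly `round(frac_down * n_de)` of them are
#' down in the crop. Genes sharing a planted module are driven by a common
#' accession-level lognormal latent factor. The crop pool's biological
#' dispersion is shrunk by `crop_cv_shrink^2` (so CV_crop < CV_wild), with
#' the additional `candidate_cv_loss` shrink applied to genes in the top
#' `candidate_top_frac` of true between-pool differentiation (from the
#' ledger's `true_fst`, falling back to swept status, then to a random draw).
#'
#' @param params A [sim_params()] object.
#' @param ledger Truth ledger from [simulate_genotypes()] (or
#'   [make_truth_ledger()]). Defaults to a stand-alone ledger.
#' @param seed_offset Added to `params$seed` so genotype and count draws are
#'   independent streams.
#' @return A list of class `counts_sim`: `counts` (tibble, gene_id +
#'   accession columns), `labels` (accession/pool tibble), `truth` (updated
#'   ledger) and `params`.
#' @examples
#' cs <- simulate_counts(sim_params(n_genes = 20, seed = 1))
#' cs$counts[1:3, 1:4]
#' @export
simulate_counts <- function(params, ledger = NULL, seed_offset = 1L) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  if (is.null(ledger)) ledger <- make_truth_ledger(params)
  stopifnot(nrow(ledger) == params$n_genes)
  set.seed(params$seed + seed_offset)

  n_genes <- params$n_genes
  acc <- c(
    sprintf("W%02d", seq_len(params$n_wild)),
    sprintf("C%02d", seq_len(params$n_crop))
  )
  pool <- rep(c("wild", "crop"), c(params$n_wild, params$n_crop))
  n_acc <- length(acc)

  # planted DE genes (exact counts). A fraction de_low_fst_frac of them is
  # placed on genes from the least-differentiated decile (expression-only
  # divergence); the rest are placed at random.
  n_de <- round(params$prop_de * n_genes)
  expr_only <- rep(FALSE, n_genes)
  if (n_de > 0) {
    n_low <- if (!all(is.na(ledger$true_fst))) {
      round(params$de_low_fst_frac * n_de)
    } else {
      0L
    }
    if (n_low > 0) {
      n_decile <- max(n_low, ceiling(0.1 * n_genes))
      low_pool <- order(ledger$true_fst, na.last = TRUE)[seq_len(n_decile)]
      low_idx <- sample(low_pool, n_low)
      rest <- sample(setdiff(seq_len(n_genes), low_idx), n_de - n_low)
      de_idx <- sample(c(low_idx, rest)) # shuffle so down/up is unbiased
      expr_only[low_idx] <- TRUE
    } else {
      de_idx <- sample.int(n_genes, n_de)
    }
  } else {
    de_idx <- integer(0)
  }
  n_down <- round(params$frac_down * n_de)
  down_idx <- if (n_down > 0) de_idx[seq_len(n_down)] else integer(0)
  up_idx <- setdiff(de_idx, down_idx)
  true_lfc <- numeric(n_genes)
  true_lfc[down_idx] <- params$lfc_magnitude
  true_lfc[up_idx] <- -params$lfc_magnitude

  # planted modules (exclusive of each other, independent of DE)
  module_id <- integer(n_genes)
  n_mod_genes <- params$n_modules * params$module_size
  if (params$n_modules > 0 && n_mod_genes <= n_genes) {
    mod_genes <- sample.int(n_genes, n_mod_genes)
    module_id[mod_genes] <- rep(seq_len(params$n_modules),
      each = params$module_size
    )
  }

  # candidate genes receiving extra crop CV loss: top differentiation
  n_cand <- round(params$candidate_top_frac * n_genes)
  cand <- rep(FALSE, n_genes)
  if (n_cand > 0) {
    if (!all(is.na(ledger$true_fst))) {
      ord <- order(ledger$true_fst, decreasing = TRUE, na.last = TRUE)
      cand[ord[seq_len(n_cand)]] <- TRUE
    } else if (any(ledger$is_swept)) {
      cand[ledger$is_swept] <- TRUE
    } else {
      cand[sample.int(n_genes, n_cand)] <- TRUE
    }
  }

  lib <- round(stats::runif(
    n_acc, params$lib_size_range[1], params$lib_size_range[2]
  ))
  q <- exp(stats::rnorm(n_genes, sd = 1.5))
  q <- q / sum(q)

  # per-gene, per-accession mean
  half <- true_lfc / 2
  pool_fac <- outer(half, ifelse(pool == "wild", 1, -1)) # log2 scale
  mu <- (q %o% lib) * 2^pool_fac

  # biological CV per gene x accession: wild phi; crop shrunk (plus the
  # candidate extra loss). phi is the squared biological CV.
  shrink <- params$crop_cv_shrink *
    ifelse(cand, 1 - params$candidate_cv_loss, 1)
  phi_mat <- matrix(params$nb_dispersion, n_genes, n_acc)
  crop_cols <- which(pool == "crop")
  phi_mat[, crop_cols] <- params$nb_dispersion *
    matrix(shrink^2, n_genes, length(crop_cols))

  counts <- matrix(0L, n_genes, n_acc)
  plain <- module_id == 0
  for (j in seq_len(n_acc)) {
    phi <- phi_mat[, j]
    counts[plain, j] <- ifelse(
      phi[plain] > 0,
      stats::rnbinom(sum(plain), mu = mu[plain, j], size = 1 / phi[plain]),
      stats::rpois(sum(plain), mu[plain, j])
    )
  }
  # module genes: lognormal biological effect split into a shared
  # accession-level factor (fraction module_cor of the log-scale variance)
  # and a private part, Poisson sampling on top; total variance matches the
  # NB genes, so module membership does not change the CV.
  if (any(!plain)) {
    rho <- params$module_cor
    z <- matrix(stats::rnorm(params$n_modules * n_acc), params$n_modules)
    for (g in which(!plain)) {
      sig2 <- log(1 + phi_mat[g, ]) # log-scale biological variance
      eff <- sqrt(rho * sig2) * z[module_id[g], ] +
        sqrt((1 - rho) * sig2) * stats::rnorm(n_acc) -
        sig2 / 2
      counts[g, ] <- stats::rpois(n_acc, mu[g, ] * exp(eff))
    }
  }
  dimnames(counts) <- list(ledger$gene_id, acc)

  ledger$is_de <- seq_len(n_genes) %in% de_idx
  ledger$true_lfc <- true_lfc
  ledger$module_id <- module_id
  ledger$is_candidate <- cand
  ledger$is_expr_only <- expr_only

  structure(
    list(
      counts = tibble::as_tibble(counts, rownames = "gene_id"),
      labels = tibble::tibble(accession = acc, pool = pool),
      truth = ledger,
      params = params
    ),
    class = "counts_sim"
  )
}

#' Simulate a full dataset (genotypes + counts)
#'
#' @param params A [sim_params()] object.
#' @return A list of class `wildcrop_sim` combining [simulate_genotypes()]
#'   and [simulate_counts()] with a shared truth ledger.
#' @export
simulate_dataset <- function(params) {
  geno <- simulate_genotypes(params)
  cnt <- simulate_counts(params, ledger = geno$truth)
  structure(
    list(
      genes = geno$genes, counts = cnt$counts, labels = cnt$labels,
      truth = cnt$truth, params = params
    ),
    class = c("wildcrop_sim", "genotype_sim")
  )
}

#' @export
print.counts_sim <- function(x, ...) {
  cat(sprintf(
    "<counts_sim> %d genes x %d accessions\n",
    nrow(x$counts), nrow(x$labels)
  ))
  invisible(x)
}

#' @export
print.wildcrop_sim <- function(x, ...) {
  cat(sprintf(
    "<wildcrop_sim> %d genes, %d wild + %d crop accessions (seed %d)\n",
    nrow(x$genes), x$params$n_wild, x$params$n_crop, x$params$seed
  ))
  invisible(x)
}
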