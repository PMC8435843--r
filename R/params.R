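#' Simulation parameters for a wild/domesticated transcriptome study design
#'
#' Bundles all knobs of the synthetic-data generator. Defaults emulate a
#' selfing cereal domestication design: 9 wild and 11 domesticated
#' accessions, wild per-site diversity of 1.6e-3, a bottleneck scaling
#' domesticated diversity to 65% of wild, near-complete selfing in the crop
#' (F = 0.99) and partial selfing in the wild (F = 0.42), a small fraction of
#' swept genes that are monomorphic in the crop, negative-binomial read
#' counts with differential expression biased toward downregulation in the
#' crop (82% of DE genes), a crop-wide expression-variability shrink to 84%
#' of the wild coefficient of variation with extra loss in the most
#' differentiated genes, and planted co-expression modules.
#'
#' @param n_wild,n_crop Number of diploid accessions per pool.
#' @param n_genes Number of genes to simulate.
#' @param gene_length_codons Coding length of each gene, in codons.
#' @param theta_wild Expected observed per-site nucleotide diversity (pi) in
#'   the wild pool. Must be in (0, 0.75]; 0 is allowed and yields
#'   monomorphic data.
#' @param bottleneck_ratio Target expected per-gene ratio
#'   pi_crop / pi_wild in non-swept genes.
#' @param f_wild,f_crop Target inbreeding coefficients (probability that the
#'   two haplotypes of an individual are identical by descent), in [0, 1].
#' @param pin_pis_ratio Target genome-wide ratio of nonsynonymous to
#'   synonymous diversity (piN/piS) planted by down-weighting nonsynonymous
#'   mutations.
#' @param prop_swept Fraction of genes whose crop alignment is forced
#'   monomorphic (pi_crop = 0).
#' @param prop_de Fraction of genes that are differentially expressed.
#' @param frac_down Fraction of DE genes downregulated in the crop.
#' @param de_low_fst_frac Fraction of DE genes planted on genes from the
#'   least-differentiated decile (expression-only divergence: regulation
#'   changes without coding-sequence differentiation).
#' @param lfc_magnitude Absolute log2 fold change planted in DE genes.
#' @param nb_dispersion Negative-binomial dispersion of counts in the wild
#'   pool (squared biological coefficient of variation).
#' @param crop_cv_shrink Multiplier applied to the crop biological CV so that
#'   CV_crop < CV_wild genome wide.
#' @param candidate_cv_loss Extra fractional CV loss applied to the crop for
#'   genes in the top `candidate_top_frac` of true between-pool
#'   differentiation (emulates selection-driven expression-diversity loss).
#' @param candidate_top_frac Fraction of genes (by true differentiation)
#'   receiving the extra CV loss.
#' @param lib_size_range Length-2 numeric, min and max library size.
#' @param n_modules,module_size Number and size of planted co-expression
#'   modules.
#' @param module_cor Target within-module expression correlation: the
#'   fraction of a module gene's biological (log-scale) variance carried by
#'   the shared accession-level latent factor. Total variance (hence CV) is
#'   unchanged by module membership.
#' @param missing_rate Per-genotype (individual x site) missingness
#'   probability, emulating coverage-based genotype filtering.
#' @param seed Integer RNG seed; all generator randomness derives from it.
#'
#' @return A list of class `sim_params`.
#' @examples
#' p <- sim_params(n_genes = 50, seed = 1)
#' p$bottleneck_ratio
#' @export
sim_params <- function(n_wild = 9L,
                       n_crop = 11L,
                       n_genes = 2000L,
                       gene_length_codons = 500L,
                       theta_wild = 0.0016,
                       bottleneck_ratio = 0.65,
                       f_wild = 0.42,
                       f_crop = 0.99,
                       pin_pis_ratio = 0.16,
                       prop_swept = 0.05,
                       prop_de = 0.04,
                       frac_down = 0.82,
                       de_low_fst_frac = 0.2,
                       lfc_magnitude = 2,
                       nb_dispersion = 0.55,
                       crop_cv_shrink = 0.84,
                       candidate_cv_loss = 0.19,
                       candidate_top_frac = 0.10,
                       lib_size_range = c(5e5, 2e6),
                       n_modules = 3L,
                       module_size = 50L,
                       module_cor = 0.85,
                       missing_rate = 0.05,
                       seed = 1L) {
  p <- list(
    n_wild = as.integer(n_wild), n_crop = as.integer(n_crop),
    n_genes = as.integer(n_genes),
    gene_length_codons = as.integer(gene_length_codons),
    theta_wild = theta_wild, bottleneck_ratio = bottleneck_ratio,
    f_wild = f_wild, f_crop = f_crop, pin_pis_ratio = pin_pis_ratio,
    prop_swept = prop_swept, prop_de = prop_de, frac_down = frac_down,
    de_low_fst_frac = de_low_fst_frac,
    lfc_magnitude = lfc_magnitude, nb_dispersion = nb_dispersion,
    crop_cv_shrink = crop_cv_shrink,
    candidate_cv_loss = candidate_cv_loss,
    candidate_top_frac = candidate_top_frac,
    lib_size_range = as.numeric(lib_size_range),
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    module_cor = module_cor,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(p$n_wild >= 1L, p$n_crop >= 1L)
  if (p$n_wild + p$n_crop < 4L) {
    stop("need at least 4 accessions in total", call. = FALSE)
  }
  if (p$n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  if (p$gene_length_codons < 1L) {
    stop("gene_length_codons must be a positive codon count", call. = FALSE)
  }
  props <- c(
    prop_swept = p$prop_swept, prop_de = p$prop_de, frac_down = p$frac_down,
    f_wild = p$f_wild, f_crop = p$f_crop, missing_rate = p$missing_rate,
    bottleneck_ratio = p$bottleneck_ratio,
    candidate_cv_loss = p$candidate_cv_loss,
    candidate_top_frac = p$candidate_top_frac,
    de_low_fst_frac = p$de_low_fst_frac
  )
  bad <- names(props)[props < 0 | props > 1]
  # bottleneck_ratio may legitimately exceed 1 (diversity gain); re-allow it
  bad <- setdiff(bad, if (p$bottleneck_ratio >= 0) "bottleneck_ratio")
  if (length(bad) > 0) {
    stop("parameters out of [0, 1]: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (p$theta_wild < 0 || p$theta_wild > 0.75) {
    stop("theta_wild implies per-site diversity outside [0, 0.75]",
      call. = FALSE
    )
  }
  if (length(p$lib_size_range) != 2L || any(p$lib_size_range <= 0) ||
    diff(p$lib_size_range) < 0) {
    stop("lib_size_range must be two positive increasing values",
      call. = FALSE
    )
  }
  if (p$nb_dispersion < 0 || p$crop_cv_shrink < 0) {
    stop("dispersion and CV shrink must be >= 0", call. = FALSE)
  }
  if (p$module_cor < 0 || p$module_cor >= 1) {
    stop("module_cor must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(p$seed) && abs(p$seed) > 2^31 - 100) {
    stop("seed must be a 32-bit integer", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf(
    "  %d wild + %d crop accessions, %d genes x %d codons\n",
    x$n_wild, x$n_crop, x$n_genes, x$gene_length_codons
  ))
  cat(sprintf(
    "  theta_wild=%.2g bottleneck=%.2f F=(%.2f, %.2f) piN/piS=%.2f\n",
    x$theta_wild, x$bottleneck_ratio, x$f_wild, x$f_crop, x$pin_pis_ratio
  ))
  cat(sprintf(
    "  prop_de=%.2f frac_down=%.2f lfc=%.1f phi=%.2f cv_shrink=%.2f\n",
    x$prop_de, x$frac_down, x$lfc_magnitude, x$nb_dispersion,
    x$crop_cv_shrink
  ))
  cat(sprintf("  seed=%d\n", x$seed))
  invisible(x)
}
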