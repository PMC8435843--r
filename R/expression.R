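# Count-matrix processing: CPM filter, TMM normalization, per-pool CV,
# two-group NB exact tests with BH-FDR, expression PCA. Normalization and
# the exact test are delegated to edgeR's classic pipeline (TMM +
# common-dispersion conditional ML + exact NB test).

table_to_matrix <- function(df) {
  stopifnot(is.data.frame(df), "gene_id" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

counts_to_matrix <- function(counts) {
  m <- table_to_matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  m
}

check_labels <- function(m, labels) {
  stopifnot(all(c("accession", "pool") %in% names(labels)))
  missing <- setdiff(colnames(m), labels$accession)
  if (length(missing) > 0) {
    stop(
      "accessions absent from labels: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  labels$pool[match(colnames(m), labels$accession)]
}

#' Counts per million
#'
#' @param counts Counts tibble (`gene_id` + accession columns).
#' @param lib_size Optional library sizes (default: column sums).
#' @return CPM tibble of the same shape.
#' @export
cpm_table <- function(counts, lib_size = NULL) {
  m <- counts_to_matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(m)
  cpmm <- t(t(m) / lib_size) * 1e6
  tibble::as_tibble(cpmm, rownames = "gene_id")
}

#' Filter genes by expression support
#'
#' Keeps genes with at least `min_cpm` counts per million (raw library
#' sizes) in at least `min_accessions` accessions. This is the permissive
#' reading of an "at least one CPM in at least five accessions" criterion;
#' the strict per-accession reading is available via
#' `min_accessions = ncol(counts) - 1`.
#'
#' @param counts Counts tibble (`gene_id` + accession columns).
#' @param labels Accession/pool tibble (checked for coverage).
#' @param min_accessions Minimum accessions meeting the CPM threshold.
#' @param min_cpm CPM threshold.
#' @return The filtered counts tibble; attribute `n_removed` records the
#'   number of dropped genes.
#' @export
filter_expressed <- function(counts, labels, min_accessions = 5L,
                             min_cpm = 1) {
  m <- counts_to_matrix(counts)
  check_labels(m, labels)
  cpmm <- t(t(m) / colSums(m)) * 1e6
  keep <- rowSums(cpmm >= min_cpm) >= min_accessions
  if (!any(keep)) {
    warning("no genes pass the expression filter", call. = FALSE)
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values (weighted, doubly trimmed by log-ratio then
#' absolute expression; reference = sample whose upper-quartile CPM is
#' closest to the mean upper quartile), rescaled to geometric mean 1.
#'
#' @param counts Counts tibble.
#' @param trim_m Trim fraction on log-ratios (default 0.30).
#' @param trim_a Trim fraction on absolute log expression (default 0.05).
#' @return Tibble with `accession`, `lib_size`, `tmm_factor`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- counts_to_matrix(counts)
  f <- edgeR::calcNormFactors(m,
    method = "TMM", logratioTrim = trim_m, sumTrim = trim_a
  )
  tibble::tibble(
    accession = colnames(m), lib_size = colSums(m), tmm_factor = unname(f)
  )
}

#' TMM-normalized CPM
#'
#' CPM on effective library sizes (library size x TMM factor).
#'
#' @inheritParams filter_expressed
#' @param log If `TRUE`, return `log2(CPM + 1)`.
#' @return CPM tibble.
#' @export
normalized_cpm <- function(counts, log = FALSE) {
  m <- counts_to_matrix(counts)
  f <- edgeR::calcNormFactors(m, method = "TMM")
  cpmm <- t(t(m) / (colSums(m) * f)) * 1e6
  if (log) cpmm <- log2(cpmm + 1)
  tibble::as_tibble(cpmm, rownames = "gene_id")
}

#' Two-group negative-binomial exact test
#'
#' Classic exact-test differential expression between the wild and crop
#' pools: TMM normalization, counts quantile-adjusted to a common effective
#' library size, common NB dispersion by conditional maximum likelihood, and
#' an exact test conditioning on per-gene group totals (two-sided p by
#' summing outcome probabilities at or below the observed one), followed by
#' Benjamini-Hochberg correction. The log2 fold change is log2(wild/crop),
#' so genes downregulated in the crop have positive logFC.
#'
#' @inheritParams filter_expressed
#' @param fdr FDR threshold for the `de` flag (default 0.01).
#' @return Tibble: `gene_id`, `logfc`, `log_cpm`, `p_value`, `q_value`,
#'   `de`, `direction` (`down_in_crop` / `up_in_crop`). Attribute
#'   `common_dispersion` records the estimated dispersion.
#' @examples
#' cs <- simulate_counts(sim_params(n_genes = 200, prop_de = 0.1, seed = 1))
#' de <- exact_test_de(cs$counts, cs$labels)
#' sum(de$de)
#' @export
exact_test_de <- function(counts, labels, fdr = 0.01) {
  m <- counts_to_matrix(counts)
  pool <- check_labels(m, labels)
  if (min(table(pool)) < 2) {
    stop("need at least 2 accessions per pool", call. = FALSE)
  }
  grp <- factor(pool, levels = c("crop", "wild"))
  y <- edgeR::DGEList(counts = m, group = grp)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y, pair = c("crop", "wild"))
  tab <- et$table
  q <- stats::p.adjust(tab$PValue, method = "BH")
  out <- tibble::tibble(
    gene_id = rownames(tab),
    logfc = tab$logFC,
    log_cpm = tab$logCPM,
    p_value = tab$PValue,
    q_value = q,
    de = q < fdr,
    direction = ifelse(tab$logFC > 0, "down_in_crop", "up_in_crop")
  )
  attr(out, "common_dispersion") <- y$common.dispersion
  attr(out, "fdr") <- fdr
  out
}

#' Per-pool expression coefficient of variation
#'
#' CV (sample sd / mean) of TMM-normalized CPM within each pool; `NA` for
#' zero-mean genes.
#'
#' @inheritParams filter_expressed
#' @return Tibble: `gene_id`, `mean_wild`, `mean_crop`, `cv_wild`,
#'   `cv_crop`.
#' @export
expression_cv <- function(counts, labels) {
  m <- counts_to_matrix(counts)
  pool <- check_labels(m, labels)
  f <- edgeR::calcNormFactors(m, method = "TMM")
  cpmm <- t(t(m) / (colSums(m) * f)) * 1e6
  cv_of <- function(x) {
    mu <- mean(x)
    if (mu == 0) NA_real_ else stats::sd(x) / mu
  }
  w <- cpmm[, pool == "wild", drop = FALSE]
  c_ <- cpmm[, pool == "crop", drop = FALSE]
  tibble::tibble(
    gene_id = rownames(cpmm),
    mean_wild = unname(rowMeans(w)),
    mean_crop = unname(rowMeans(c_)),
    cv_wild = unname(apply(w, 1, cv_of)),
    cv_crop = unname(apply(c_, 1, cv_of))
  )
}
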