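# Principal component analysis shared by the genotype and expression views,
# with a deterministic sign convention.

wildcrop_pca <- function(x, labels = NULL, scale. = FALSE) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  # mean-impute missing values per column
  if (anyNA(x)) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
    }
    x[is.na(x)] <- 0
  }
  keep <- apply(x, 2, stats::var) > 0
  x <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  # sign convention: the largest-|loading| element of each PC is positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(min(10, ncol(pc$x))),
    drop = FALSE
  ])
  scores <- dplyr::bind_cols(
    tibble::tibble(accession = rownames(x)), scores
  )
  if (!is.null(labels)) {
    scores <- dplyr::left_join(scores, labels, by = "accession")
  }
  structure(
    list(scores = scores, var_explained = ve),
    class = "wildcrop_pca"
  )
}

#' PCA of a genotype dosage matrix
#'
#' Centered PCA of the individuals-by-sites derived-allele dosage matrix
#' (missing genotypes mean-imputed), with a deterministic sign convention
#' (largest-|loading| element positive).
#'
#' @param geno Dosage matrix from [genotype_matrix()], or any samples x
#'   variables numeric matrix.
#' @param labels Optional accession/pool tibble joined onto the scores.
#' @return A `wildcrop_pca` object: `scores` tibble and `var_explained`.
#' @export
genotype_pca <- function(geno, labels = NULL) {
  wildcrop_pca(geno, labels = labels)
}

#' PCA of expression profiles
#'
#' Centered PCA of accessions on `log2(TMM-normalized CPM + 1)`.
#'
#' @inheritParams filter_expressed
#' @return A `wildcrop_pca` object.
#' @export
expression_pca <- function(counts, labels = NULL) {
  lcpm <- normalized_cpm(counts, log = TRUE)
  m <- t(table_to_matrix(lcpm))
  wildcrop_pca(m, labels = labels)
}

#' @export
print.wildcrop_pca <- function(x, ...) {
  cat(sprintf(
    "<wildcrop_pca> %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$scores), 100 * x$var_explained[1], 100 * x$var_explained[2]
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy wildcrop_pca
#' @export
tidy.wildcrop_pca <- function(x, ...) x$scores

#' @method glance wildcrop_pca
#' @export
glance.wildcrop_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    pc1_var = x$var_explained[1],
    pc2_var = x$var_explained[2]
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of the first two principal components
#'
#' @param object A `wildcrop_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wildcrop_pca
#' @export
autoplot.wildcrop_pca <- function(object, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  if ("pool" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$pool), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}
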