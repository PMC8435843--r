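# Signed weighted co-expression network: soft-power selection by scale-free
# fit, topological overlap, average-linkage module detection with a
# quantile static cut plus recursive gap splitting, eigengene merging, and
# module-level enrichment.

expr_matrix_genes <- function(counts, log = TRUE) {
  lcpm <- normalized_cpm(counts, log = log)
  table_to_matrix(lcpm)
}

#' Signed similarity and adjacency
#'
#' Signed similarity `s = (1 + cor) / 2` (Pearson, pairwise-complete) of
#' genes across accessions, raised to the soft power `beta`.
#'
#' @param expr Numeric matrix, genes x accessions (e.g. log2 CPM).
#' @param beta Soft-thresholding power.
#' @return Adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(expr, beta = 20) {
  s <- (1 + stats::cor(t(expr), use = "pairwise.complete.obs")) / 2
  s[is.na(s)] <- 0.5
  a <- s^beta
  diag(a) <- 1
  a
}

#' Pick the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power, computes the signed adjacency, the per-gene
#' connectivity `k`, and the scale-free fit index: the signed R^2
#' (`-sign(slope) * r^2`) of the regression of `log10 p(k)` on `log10 k`
#' over connectivity bins. Returns the smallest power whose fit reaches
#' `rsq_cut` (falling back, with a warning, to the best-fitting power).
#' Constant genes are removed first.
#'
#' @param expr Genes x accessions matrix.
#' @param powers Candidate powers.
#' @param rsq_cut Scale-free fit threshold (default 0.8).
#' @param n_bins Connectivity bins for the fit (default 10).
#' @param fixed_power If not `NULL`, bypass selection and return it as-is.
#' @return List with `power` and a `fit` tibble (power, rsq, slope,
#'   mean_k, median_k, max_k).
#' @export
pick_soft_power <- function(expr, powers = c(1:10, seq(12, 20, 2)),
                            rsq_cut = 0.8, n_bins = 10L,
                            fixed_power = NULL) {
  if (!is.null(fixed_power)) {
    return(list(power = fixed_power, fit = NULL))
  }
  keep <- apply(expr, 1, stats::var, na.rm = TRUE) > 0
  expr <- expr[keep, , drop = FALSE]
  if (ncol(expr) < 8) stop("need at least 8 samples", call. = FALSE)
  s <- (1 + stats::cor(t(expr), use = "pairwise.complete.obs")) / 2
  s[is.na(s)] <- 0.5
  fit <- purrr::map_dfr(powers, function(b) {
    a <- s^b
    diag(a) <- 0
    k <- colSums(a)
    tibble::tibble(
      power = b,
      rsq = scale_free_rsq(k, n_bins)["rsq"],
      slope = scale_free_rsq(k, n_bins)["slope"],
      mean_k = mean(k), median_k = stats::median(k), max_k = max(k)
    )
  })
  ok <- which(fit$rsq >= rsq_cut)
  if (length(ok) > 0) {
    power <- fit$power[ok[1]]
  } else {
    power <- fit$power[which.max(fit$rsq)]
    warning(
      "no candidate power reached the scale-free fit threshold; ",
      "using the best fit (power ", power, ")",
      call. = FALSE
    )
  }
  list(power = power, fit = fit)
}

scale_free_rsq <- function(k, n_bins = 10L) {
  if (stats::sd(k) == 0) {
    return(c(rsq = NA_real_, slope = NA_real_))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  p_k <- tapply(k, bin, length)
  k_mean <- tapply(k, bin, mean)
  ok <- !is.na(p_k) & p_k > 0 & k_mean > 0
  if (sum(ok) < 3) {
    return(c(rsq = NA_real_, slope = NA_real_))
  }
  lx <- log10(k_mean[ok])
  ly <- log10(p_k[ok] / sum(p_k[ok]))
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  c(rsq = -sign(slope) * r2, slope = slope)
}

#' Topological overlap dissimilarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k` excluding the diagonal; the diagonal of TOM is 1 and
#' `dissTOM = 1 - TOM`.
#'
#' @param adjacency Symmetric adjacency matrix in `[0, 1]`.
#' @return List with `tom` and `diss` matrices.
#' @export
build_tom <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (nrow(adjacency) < 2) stop("need at least 2 genes", call. = FALSE)
  a <- adjacency
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  list(tom = tom, diss = 1 - tom)
}

# Static cut height anchored to the dissimilarity of unrelated gene pairs:
# in a sparse co-expression network the vast majority of pairs share no
# signal, so the median off-diagonal dissTOM estimates the background level;
# the cut sits just below it (relative margin), with min_cut as a floor
# against degenerate all-correlated inputs.
background_cut <- function(diss, min_cut = 0.3, margin = 0.02) {
  bg <- stats::median(diss[upper.tri(diss)])
  max(min_cut, (1 - margin) * bg)
}

# Recursive refinement of a candidate cluster. A cluster whose internal
# median dissimilarity is clearly below the global background level is
# cohesive (a module) and is kept whole; a cluster whose internal median is
# still near the background must contain unrelated gene pairs, so it is
# re-cut just below its own local background and the pieces are refined
# recursively. Sub-minimum fragments are dropped (label 0); pieces of one
# true module that get separated are re-joined by the eigengene merging.
refine_cluster <- function(diss, idx, min_size, global_bg, margin,
                           cohesion_frac = 0.9) {
  if (length(idx) < 2 * min_size) {
    return(list(idx))
  }
  sub <- diss[idx, idx]
  local_bg <- stats::median(sub[upper.tri(sub)])
  if (local_bg < cohesion_frac * global_bg) {
    return(list(idx))
  }
  h <- (1 - margin) * local_bg
  hc <- stats::hclust(stats::as.dist(sub), method = "average")
  if (h >= max(hc$height)) {
    return(list(idx))
  }
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  if (max(sizes) == length(idx)) {
    return(list(idx))
  }
  out <- list()
  for (piece in names(sizes)[sizes >= min_size]) {
    sub_idx <- idx[cl == as.integer(piece)]
    # shrink the background reference so homogeneous pieces stop splitting
    out <- c(
      out,
      refine_cluster(diss, sub_idx, min_size, local_bg, margin,
        cohesion_frac
      )
    )
  }
  if (length(out) == 0) list(idx) else out
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `dissTOM`; an initial static
#' cut just below the background (median off-diagonal) dissimilarity,
#' followed by recursive re-cutting of each candidate cluster at its own
#' local background level until clusters are stable (a simplified dynamic
#' cut).
#' Clusters smaller than `min_module_size` become unassigned (label 0).
#' Module eigengenes (first principal component across accessions,
#' sign-oriented to correlate positively with the module mean) are computed,
#' and modules whose eigengene dissimilarity `1 - cor` is below
#' `merge_height` are merged iteratively. Modules are relabeled by
#' decreasing size (module 1 = largest) and given conventional color names.
#'
#' @param diss Dissimilarity matrix (`1 - TOM`), gene names as dimnames.
#' @param expr Genes x accessions expression matrix (for eigengenes).
#' @param min_module_size Minimum module size (default 30).
#' @param merge_height Eigengene-dissimilarity merge threshold (default
#'   0.25).
#' @param cut_height Static cut height; `NULL` (default) places the cut
#'   just below the median off-diagonal dissimilarity (the background level
#'   of unrelated gene pairs), so coherent modules stay intact while
#'   chance-level merges are cut away.
#' @param min_cut Floor for the automatic cut (default 0.3).
#' @param margin Relative margin below the background dissimilarity at
#'   which cuts are placed (default 0.02).
#' @return A `module_set` object: `labels` tibble (gene_id, module, color),
#'   `eigengenes` tibble (accession x module), `sizes`, `power` (filled by
#'   the caller), `merge_height`.
#' @export
detect_modules <- function(diss, expr, min_module_size = 30L,
                           merge_height = 0.25, cut_height = NULL,
                           min_cut = 0.3, margin = 0.02) {
  stopifnot(nrow(diss) == nrow(expr))
  gene_ids <- rownames(expr)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) {
    colnames(expr) <- sprintf("s%03d", seq_len(ncol(expr)))
  }
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  h_cut <- cut_height %||% background_cut(diss, min_cut, margin)
  base <- stats::cutree(hc, h = h_cut)

  labels <- integer(length(base))
  next_lab <- 1L
  for (cl in unique(base)) {
    leaves <- which(base == cl)
    if (length(leaves) < min_module_size) next
    pieces <- refine_cluster(
      diss, leaves, min_module_size,
      stats::median(diss[upper.tri(diss)]), margin
    )
    for (pc in pieces) {
      if (length(pc) < min_module_size) next
      labels[pc] <- next_lab
      next_lab <- next_lab + 1L
    }
  }

  if (all(labels == 0L)) {
    warning("no module reached the minimum size; all genes unassigned",
      call. = FALSE
    )
    return(new_module_set(gene_ids, labels, expr, merge_height))
  }

  # eigengene merging
  repeat {
    me <- module_eigengenes(expr, labels)
    if (ncol(me$scores) < 2) break
    d_me <- 1 - stats::cor(me$scores)
    hc_me <- stats::hclust(stats::as.dist(d_me), method = "average")
    grp <- stats::cutree(hc_me, h = merge_height)
    if (max(table(grp)) == 1) break
    mods <- as.integer(sub("^module_", "", colnames(me$scores)))
    for (gval in unique(grp)) {
      which_mods <- mods[grp == gval]
      if (length(which_mods) > 1) {
        labels[labels %in% which_mods] <- which_mods[1]
      }
    }
  }
  new_module_set(gene_ids, labels, expr, merge_height)
}

# conventional module color names, by size rank
module_colors <- function(n) {
  pal <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
  )
  rep_len(pal, n)
}

module_eigengenes <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0]))
  scores <- sapply(mods, function(mm) {
    sub <- expr[labels == mm, , drop = FALSE]
    sub_sc <- t(scale(t(sub)))
    sub_sc[!is.finite(sub_sc)] <- 0
    sv <- svd(sub_sc, nu = 0, nv = 1)
    eg <- sv$v[, 1]
    if (stats::cor(eg, colMeans(sub_sc)) < 0) eg <- -eg
    eg
  })
  scores <- matrix(scores, ncol = length(mods))
  colnames(scores) <- paste0("module_", mods)
  rownames(scores) <- colnames(expr)
  var_expl <- vapply(seq_along(mods), function(i) {
    sub <- t(scale(t(expr[labels == mods[i], , drop = FALSE])))
    sub[!is.finite(sub)] <- 0
    proj <- sub %*% scores[, i]
    sum(proj^2) / sum(sub^2)
  }, numeric(1))
  list(scores = scores, var_explained = var_expl, modules = mods)
}

new_module_set <- function(gene_ids, labels, expr, merge_height,
                           power = NA_real_) {
  # relabel by decreasing size
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) > 0) {
    sz <- vapply(mods, function(mm) sum(labels == mm), integer(1))
    ord <- mods[order(-sz)]
    relab <- integer(max(labels))
    relab[ord] <- seq_along(ord)
    labels[labels > 0] <- relab[labels[labels > 0]]
  }
  mods <- sort(unique(labels[labels > 0]))
  colors <- c("grey", module_colors(length(mods)))
  me <- if (length(mods) > 0) module_eigengenes(expr, labels) else NULL
  eg_tbl <- if (!is.null(me)) {
    dplyr::bind_cols(
      tibble::tibble(accession = colnames(expr)),
      tibble::as_tibble(me$scores)
    )
  } else {
    tibble::tibble(accession = colnames(expr))
  }
  structure(
    list(
      labels = tibble::tibble(
        gene_id = gene_ids, module = labels,
        color = colors[labels + 1L]
      ),
      eigengenes = eg_tbl,
      eigengene_var = if (!is.null(me)) me$var_explained else numeric(0),
      sizes = if (length(mods) > 0) {
        tibble::tibble(
          module = mods,
          size = vapply(mods, function(mm) sum(labels == mm), integer(1)),
          color = module_colors(length(mods))
        )
      } else {
        tibble::tibble(module = integer(0), size = integer(0), color = character(0))
      },
      merge_height = merge_height, power = power
    ),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf(
    "<module_set> %d modules over %d genes (%d unassigned)\n",
    nrow(x$sizes), nrow(x$labels), sum(x$labels$module == 0)
  ))
  if (nrow(x$sizes) > 0) print(x$sizes, n = 10)
  invisible(x)
}

#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) x$labels

#' @method glance module_set
#' @export
glance.module_set <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x$sizes),
    n_assigned = sum(x$labels$module > 0),
    n_unassigned = sum(x$labels$module == 0),
    largest = if (nrow(x$sizes) > 0) max(x$sizes$size) else 0L
  )
}

#' Module sizes bar chart
#'
#' @param object A `module_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot module_set
#' @export
autoplot.module_set <- function(object, ...) {
  df <- object$sizes
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$module),
    .data$size,
    fill = .data$color
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = "module", y = "genes") +
    ggplot2::theme_minimal()
}

#' Build a signed co-expression network and detect modules
#'
#' Convenience wrapper: log2 normalized CPM, soft power (fixed or picked by
#' scale-free fit), signed adjacency, TOM, module detection.
#'
#' @inheritParams filter_expressed
#' @param power Soft power (default 20); `NULL` to select automatically.
#' @param min_module_size,merge_height Module detection parameters.
#' @return A `module_set` (with `power` filled in).
#' @export
coexpression_modules <- function(counts, labels = NULL, power = 20,
                                 min_module_size = 30L,
                                 merge_height = 0.25) {
  expr <- expr_matrix_genes(counts)
  keep <- apply(expr, 1, stats::var) > 0
  expr <- expr[keep, , drop = FALSE]
  if (is.null(power)) {
    power <- pick_soft_power(expr)$power
  }
  adj <- signed_adjacency(expr, beta = power)
  tm <- build_tom(adj)
  ms <- detect_modules(tm$diss, expr,
    min_module_size = min_module_size, merge_height = merge_height
  )
  ms$power <- power
  ms
}

#' Module enrichment in a binary gene flag
#'
#' Fisher 2x2 test of each module against the rest of the genes, BH-adjusted
#' across modules; when expression and labels are supplied the mean module
#' expression direction in the crop is reported.
#'
#' @param modules A `module_set`.
#' @param flags Tibble with `gene_id` and a logical `flag` column (e.g. DE
#'   status).
#' @param expr Optional genes x accessions matrix for the direction report.
#' @param labels Optional accession/pool tibble.
#' @return Tibble: module, size, overlap, odds ratio, p, q (+ direction).
#' @export
module_enrichment <- function(modules, flags, expr = NULL, labels = NULL) {
  stopifnot(inherits(modules, "module_set"))
  df <- dplyr::left_join(modules$labels, flags, by = "gene_id")
  mods <- modules$sizes$module
  if (length(mods) == 0) {
    return(tibble::tibble(
      module = integer(0), size = integer(0), n_flagged = integer(0),
      odds_ratio = numeric(0), p_value = numeric(0), q_value = numeric(0)
    ))
  }
  out <- purrr::map_dfr(mods, function(mm) {
    inmod <- df$module == mm
    e <- enrichment_2x2(inmod, df$flag)
    tibble::tibble(
      module = mm, size = sum(inmod), n_flagged = sum(inmod & df$flag,
        na.rm = TRUE
      ),
      odds_ratio = e$odds_ratio, p_value = e$p_value
    )
  })
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  if (!is.null(expr) && !is.null(labels)) {
    pool <- labels$pool[match(colnames(expr), labels$accession)]
    out$direction <- vapply(out$module, function(mm) {
      sub <- expr[df$module == mm, , drop = FALSE]
      d <- mean(sub[, pool == "crop", drop = FALSE]) -
        mean(sub[, pool == "wild", drop = FALSE])
      if (d < 0) "down_in_crop" else "up_in_crop"
    }, character(1))
  }
  out
}

#' Per-accession module eigengene outlier report
#'
#' Eigengene score of every accession in every module, with a z-score within
#' the accession's pool; accessions with |z| > `z_cut` in a module are
#' flagged (useful to spot accessions whose expression behaves unlike their
#' pool).
#'
#' @param modules A `module_set`.
#' @param labels Accession/pool tibble.
#' @param z_cut Flag threshold (default 2.5).
#' @return Tibble: accession, pool, module, eigengene, z, flagged.
#' @export
outlier_accession_report <- function(modules, labels, z_cut = 2.5) {
  eg <- modules$eigengenes
  if (ncol(eg) < 2) {
    return(tibble::tibble(
      accession = character(0), module = integer(0),
      eigengene = numeric(0), pool = character(0), z = numeric(0),
      flagged = logical(0)
    ))
  }
  long <- tidyr::pivot_longer(eg, -"accession",
    names_to = "module", values_to = "eigengene"
  )
  long$module <- as.integer(sub("^module_", "", long$module))
  long <- dplyr::left_join(long, labels, by = "accession")
  long <- long %>%
    dplyr::group_by(.data$module, .data$pool) %>%
    dplyr::mutate(
      z = if (dplyr::n() > 1 && stats::sd(.data$eigengene) > 0) {
        (.data$eigengene - mean(.data$eigengene)) / stats::sd(.data$eigengene)
      } else {
        0
      }
    ) %>%
    dplyr::ungroup()
  long$flagged <- abs(long$z) > z_cut
  long
}
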