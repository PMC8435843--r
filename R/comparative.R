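# Joint polymorphism-expression inference: the diversity-matched resampling
# test for expression-diversity loss in selection candidates, DE vs non-DE
# distribution comparisons, enrichment and direction-bias tests, and
# polymorphism ~ expression regressions.

local_seed <- function(seed) {
  if (is.null(seed)) {
    return(invisible(NULL))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  invisible(old)
}

#' Diversity-matched resampling test for CV loss in F_ST outliers
#'
#' Tests whether the wild-to-crop loss of expression diversity
#' (`CV_wild - CV_crop`) in highly differentiated genes exceeds what is
#' expected from their (lower) nucleotide diversity alone. Outliers are the
#' genes at or above the given F_ST percentile. Each of `n_resamples` null
#' draws picks, for every outlier, one non-outlier gene uniformly among
#' those with equal or lower diversity (pi at most the outlier's pi); the
#' null distribution of the mean CV difference yields the empirical p-value
#' `(1 + #{null >= observed}) / (n_resamples + 1)`. An outlier with no
#' eligible match is relaxed to the nearest-pi donor with a warning.
#'
#' @param master Tibble with columns `gene_id`, `cv_wild`, `cv_crop`, `pi`
#'   (matching diversity; conventionally the wild-pool pi) and `fst`.
#' @param percentile F_ST percentile defining outliers (e.g. 90, 95, 99).
#' @param n_resamples Number of null resamples (default 1000).
#' @param seed Optional RNG seed for reproducible draws.
#' @return An `outlier_scan` object: observed mean CV difference in outliers
#'   and in non-outliers, null draws, empirical p, outlier gene ids.
#' @examples
#' df <- tibble::tibble(
#'   gene_id = paste0("g", 1:200), cv_wild = runif(200, 0.5, 1),
#'   cv_crop = runif(200, 0.4, 0.9), pi = rexp(200, 500),
#'   fst = runif(200)
#' )
#' scan <- matched_resampling_test(df, percentile = 95, n_resamples = 99, seed = 1)
#' glance(scan)
#' @export
matched_resampling_test <- function(master, percentile = 95,
                                    n_resamples = 1000L, seed = NULL) {
  need <- c("gene_id", "cv_wild", "cv_crop", "pi", "fst")
  stopifnot(all(need %in% names(master)))
  df <- dplyr::filter(
    master,
    !is.na(.data$cv_wild), !is.na(.data$cv_crop),
    !is.na(.data$pi), !is.na(.data$fst)
  )
  if (nrow(df) < 10) stop("too few genes with complete statistics", call. = FALSE)
  cutoff <- stats::quantile(df$fst, percentile / 100)
  out <- df$fst >= cutoff
  if (sum(out) == 0 || sum(!out) == 0) {
    stop("degenerate outlier split at percentile ", percentile, call. = FALSE)
  }
  dcv <- df$cv_wild - df$cv_crop
  obs <- mean(dcv[out])
  background <- mean(dcv[!out])

  non <- df[!out, ]
  ord <- order(non$pi)
  pi_sorted <- non$pi[ord]
  dcv_sorted <- (non$cv_wild - non$cv_crop)[ord]
  k <- findInterval(df$pi[out], pi_sorted)
  relaxed <- k == 0
  if (any(relaxed)) {
    warning(
      sum(relaxed), " outlier(s) had no equal-or-lower-diversity match; ",
      "relaxed to the nearest-pi donor",
      call. = FALSE
    )
    k[relaxed] <- 1L
  }
  local_seed(seed)
  n_out <- sum(out)
  null_mat <- matrix(0, n_resamples, n_out)
  for (i in seq_len(n_out)) {
    idx <- ceiling(stats::runif(n_resamples) * k[i])
    null_mat[, i] <- dcv_sorted[idx]
  }
  null_dcv <- rowMeans(null_mat)
  p <- (1 + sum(null_dcv >= obs)) / (n_resamples + 1)

  structure(
    list(
      percentile = percentile, fst_cutoff = unname(cutoff),
      n_outliers = n_out, outlier_genes = df$gene_id[out],
      observed_dcv = obs, background_dcv = background,
      cv_loss = obs / mean(df$cv_wild[out]),
      null_dcv = null_dcv, n_resamples = n_resamples,
      n_relaxed = sum(relaxed), p_value = p, seed = seed
    ),
    class = "outlier_scan"
  )
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf(
    "<outlier_scan> F_ST >= %.3f (%sth pct): %d outliers, dCV = %.3f (null %.3f), p = %.4g\n",
    x$fst_cutoff, x$percentile, x$n_outliers, x$observed_dcv,
    mean(x$null_dcv), x$p_value
  ))
  invisible(x)
}

#' @method tidy outlier_scan
#' @export
tidy.outlier_scan <- function(x, ...) {
  tibble::tibble(
    percentile = x$percentile, fst_cutoff = x$fst_cutoff,
    n_outliers = x$n_outliers, observed_dcv = x$observed_dcv,
    null_dcv_mean = mean(x$null_dcv), cv_loss = x$cv_loss,
    p_value = x$p_value
  )
}

#' @method glance outlier_scan
#' @export
glance.outlier_scan <- function(x, ...) tidy(x)

#' Histogram of the matched-resampling null with the observed value
#'
#' @param object An `outlier_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot outlier_scan
#' @export
autoplot.outlier_scan <- function(object, ...) {
  df <- tibble::tibble(null_dcv = object$null_dcv)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_dcv)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(
      xintercept = object$observed_dcv,
      colour = "firebrick", linewidth = 1
    ) +
    ggplot2::labs(
      x = "null mean CV_wild - CV_crop", y = "resamples",
      title = sprintf(
        "F_ST %sth percentile outliers: p = %.4g",
        object$percentile, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Compare polymorphism statistics between DE and non-DE genes
#'
#' Summaries (mean, median, 2.5/97.5% quantiles) of per-gene statistics by
#' group (DE up / DE down in crop / non-DE), and two-sample
#' Kolmogorov-Smirnov tests of DE vs non-DE for each statistic. Tests are
#' suppressed (NA) for groups with fewer than 5 genes.
#'
#' @param master Tibble with per-gene columns; `de` (logical) and
#'   `direction` are required, statistics are taken from `stats_cols`.
#' @param stats_cols Character vector of statistic columns to compare.
#' @return List with `summary` and `tests` tibbles.
#' @export
de_vs_nonde_distributions <- function(master,
                                      stats_cols = c(
                                        "pi_s_wild", "pi_n_wild",
                                        "pin_pis_wild", "tajima_d_wild",
                                        "pi_s_crop", "pi_n_crop",
                                        "pin_pis_crop", "tajima_d_crop",
                                        "ratio", "fst"
                                      )) {
  stopifnot("de" %in% names(master))
  stats_cols <- intersect(stats_cols, names(master))
  grp <- dplyr::case_when(
    !master$de ~ "non_de",
    master$direction == "down_in_crop" ~ "de_down",
    TRUE ~ "de_up"
  )
  df <- dplyr::mutate(master, group = grp)
  summary <- purrr::map_dfr(stats_cols, function(cn) {
    df %>%
      dplyr::group_by(.data$group) %>%
      dplyr::summarise(
        statistic = cn,
        n = sum(is.finite(.data[[cn]])),
        mean = mean(.data[[cn]][is.finite(.data[[cn]])]),
        median = stats::median(.data[[cn]][is.finite(.data[[cn]])]),
        q025 = stats::quantile(.data[[cn]][is.finite(.data[[cn]])], 0.025,
          na.rm = TRUE
        ),
        q975 = stats::quantile(.data[[cn]][is.finite(.data[[cn]])], 0.975,
          na.rm = TRUE
        ),
        .groups = "drop"
      )
  })
  tests <- purrr::map_dfr(stats_cols, function(cn) {
    x <- master[[cn]][master$de]
    y <- master[[cn]][!master$de]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    p <- if (length(x) >= 5 && length(y) >= 5) {
      suppressWarnings(stats::ks.test(x, y)$p.value)
    } else {
      NA_real_
    }
    tibble::tibble(
      statistic = cn, n_de = length(x), n_nonde = length(y), ks_p = p
    )
  })
  list(summary = summary, tests = tests)
}

#' Fisher 2x2 enrichment test
#'
#' Exact hypergeometric test (two-sided by the point-probability method) of
#' association between two binary gene flags, with the sample odds ratio
#' (Haldane 0.5 correction for zero cells) and the conditional-MLE odds
#' ratio.
#'
#' @param flag_a,flag_b Logical vectors over the same genes.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return One-row tibble with the 2x2 cells, odds ratios and p-value.
#' @export
enrichment_2x2 <- function(flag_a, flag_b, alternative = "two.sided") {
  stopifnot(length(flag_a) == length(flag_b))
  ok <- !is.na(flag_a) & !is.na(flag_b)
  a <- flag_a[ok]
  b <- flag_b[ok]
  tab <- matrix(
    c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
    nrow = 2, byrow = TRUE
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    p <- 1
    or_cmle <- NA_real_
  } else {
    ft <- stats::fisher.test(tab, alternative = alternative)
    p <- ft$p.value
    or_cmle <- unname(ft$estimate)
  }
  or_sample <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
    ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  tibble::tibble(
    n11 = tab[1, 1], n10 = tab[1, 2], n01 = tab[2, 1], n00 = tab[2, 2],
    odds_ratio = or_sample, odds_ratio_cmle = or_cmle, p_value = p
  )
}

#' Test for directional bias among DE genes
#'
#' Compares the fraction of crop-downregulated genes among DE genes with the
#' background fraction in the whole gene set, via a chi-square test on the
#' 2x2 DE-status x direction table (exact binomial fallback when fewer than
#' 10 DE genes).
#'
#' @param de Logical DE flags.
#' @param logfc log2(wild/crop) fold changes (positive = down in crop).
#' @return One-row tibble with fractions and the p-value.
#' @export
direction_bias_test <- function(de, logfc) {
  stopifnot(length(de) == length(logfc))
  ok <- !is.na(de) & !is.na(logfc)
  de <- de[ok]
  down <- logfc[ok] > 0
  n_de <- sum(de)
  frac_de_down <- mean(down[de])
  frac_all_down <- mean(down)
  if (n_de == 0) stop("no DE genes", call. = FALSE)
  if (n_de < 10) {
    p <- stats::binom.test(sum(down & de), n_de, p = frac_all_down)$p.value
    method <- "exact binomial"
  } else {
    tab <- table(
      factor(de, levels = c(FALSE, TRUE)),
      factor(down, levels = c(FALSE, TRUE))
    )
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    method <- "chi-squared"
  }
  tibble::tibble(
    n_de = n_de, frac_de_down = frac_de_down,
    frac_all_down = frac_all_down, method = method, p_value = p
  )
}

#' Polymorphism ~ expression regressions
#'
#' Per-pool ordinary least squares of log10(polymorphism) on log10(mean
#' normalized expression) for each diversity statistic, plus a pooled model
#' with pool, expression and their interaction (ANOVA F-test for the
#' interaction). Genes with non-positive polymorphism or expression are
#' excluded (log-transform domain).
#'
#' @param master Tibble with per-gene `mean_wild`/`mean_crop` expression and
#'   per-pool polymorphism columns named `<stat>_wild` / `<stat>_crop`.
#' @param stats_cols Base names of the polymorphism statistics.
#' @return A `px_regression` object; see [tidy()] and [glance()] methods.
#' @export
polymorphism_expression_regression <- function(master,
                                               stats_cols = c(
                                                 "pi_s", "pi_n", "pin_pis"
                                               )) {
  fits <- list()
  rows <- list()
  inter <- list()
  for (st in stats_cols) {
    long <- dplyr::bind_rows(
      tibble::tibble(
        pool = "wild",
        y = master[[paste0(st, "_wild")]], x = master$mean_wild
      ),
      tibble::tibble(
        pool = "crop",
        y = master[[paste0(st, "_crop")]], x = master$mean_crop
      )
    )
    long <- dplyr::filter(
      long, is.finite(.data$y), is.finite(.data$x),
      .data$y > 0, .data$x > 0
    )
    if (nrow(long) < 10) {
      warning("fewer than 10 usable genes for ", st, call. = FALSE)
      next
    }
    long$ly <- log10(long$y)
    long$lx <- log10(long$x)
    for (pl in c("wild", "crop")) {
      sub <- long[long$pool == pl, ]
      if (nrow(sub) < 10) next
      fit <- stats::lm(ly ~ lx, data = sub)
      sm <- summary(fit)
      rows[[paste(st, pl)]] <- tibble::tibble(
        statistic = st, pool = pl, n = nrow(sub),
        slope = unname(stats::coef(fit)[2]),
        adj_r_squared = sm$adj.r.squared,
        p_value = sm$coefficients[2, 4]
      )
    }
    full <- stats::lm(ly ~ lx * pool, data = long)
    av <- stats::anova(full)
    inter[[st]] <- tibble::tibble(
      statistic = st,
      interaction_f = av["lx:pool", "F value"],
      interaction_p = av["lx:pool", "Pr(>F)"]
    )
    fits[[st]] <- full
  }
  structure(
    list(
      slopes = dplyr::bind_rows(rows),
      interaction = dplyr::bind_rows(inter),
      fits = fits
    ),
    class = "px_regression"
  )
}

#' @export
print.px_regression <- function(x, ...) {
  cat("<px_regression>\n")
  print(x$slopes)
  print(x$interaction)
  invisible(x)
}

#' @method tidy px_regression
#' @export
tidy.px_regression <- function(x, ...) x$slopes

#' @method glance px_regression
#' @export
glance.px_regression <- function(x, ...) x$interaction

#' Regulatory-only domestication candidates
#'
#' DE genes with zero (or negative) between-pool F_ST: expression divergence
#' without detectable coding-sequence differentiation.
#'
#' @param master Tibble with `gene_id`, `de` and `fst`.
#' @return Tibble of candidate genes annotated `regulatory-only candidate`.
#' @export
zero_fst_candidates <- function(master) {
  stopifnot(all(c("gene_id", "de", "fst") %in% names(master)))
  out <- dplyr::filter(master, .data$de, !is.na(.data$fst), .data$fst <= 0)
  dplyr::mutate(
    dplyr::select(out, "gene_id", "fst"),
    annotation = "regulatory-only candidate"
  )
}
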