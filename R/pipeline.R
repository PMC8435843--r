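# End-to-end orchestration: simulate (or read) -> popgen -> expression ->
# comparative -> network, with a joined master table, summary JSON and
# byte-stable outputs for a fixed seed.

#' Pipeline configuration
#'
#' All thresholds of the analysis in one serializable list. Either
#' `simulation` (a [sim_params()] object) or input paths (`counts_path`,
#' `labels_path`, `fasta_dir`) must be supplied.
#'
#' @param simulation A [sim_params()] object, or `NULL` when reading files.
#' @param counts_path,labels_path,fasta_dir Input files for a real-data run.
#' @param min_called Site filter: called individuals per pool (default 5).
#' @param min_cpm,min_accessions Expression filter thresholds.
#' @param fdr FDR threshold declaring DE genes (default 0.01).
#' @param baseline_ratio Neutral crop/wild diversity ratio (default 0.65).
#' @param fst_percentiles Percentiles for the matched-resampling scan.
#' @param n_resamples Resamples for the matched null (default 1000).
#' @param power,merge_height,min_module_size Network parameters.
#' @param network_max_genes Cap on genes entering the network stage (most
#'   variable genes are kept).
#' @param seed Seed for every stochastic step of the run.
#' @param outdir Output directory (`NULL` = no files written).
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = sim_params(),
                       counts_path = NULL, labels_path = NULL,
                       fasta_dir = NULL,
                       min_called = 5L, min_cpm = 1, min_accessions = 5L,
                       fdr = 0.01, baseline_ratio = 0.65,
                       fst_percentiles = c(90, 95, 99),
                       n_resamples = 1000L,
                       power = 20, merge_height = 0.25,
                       min_module_size = 30L,
                       network_max_genes = 2000L,
                       seed = 1L, outdir = NULL) {
  cfg <- list(
    simulation = simulation, counts_path = counts_path,
    labels_path = labels_path, fasta_dir = fasta_dir,
    min_called = min_called, min_cpm = min_cpm,
    min_accessions = min_accessions, fdr = fdr,
    baseline_ratio = baseline_ratio, fst_percentiles = fst_percentiles,
    n_resamples = n_resamples, power = power,
    merge_height = merge_height, min_module_size = min_module_size,
    network_max_genes = network_max_genes,
    seed = as.integer(seed), outdir = outdir
  )
  structure(cfg, class = "run_config")
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$simulation)) out$simulation <- unclass(out$simulation)
  out
}

#' Run the full wild-vs-crop analysis pipeline
#'
#' Executes simulate (or load) -> per-gene popgen statistics -> expression
#' filtering/DE/CV/PCA -> comparative tests (matched-resampling CV scan at
#' each F_ST percentile, DE vs non-DE distributions, direction bias,
#' polymorphism~expression regressions, zero-F_ST candidates) -> signed
#' co-expression modules with DE enrichment. Results are joined on gene_id
#' into a master table; when `outdir` is set, tables, a summary JSON and the
#' resolved configuration are written (byte-stable for a fixed seed).
#'
#' @param config A [run_config()] object.
#' @return A `wildcrop_run` list: `master` (per-gene table), `popgen`,
#'   `de`, `cv`, `pca_genotype`, `pca_expression`, `scans`, `de_vs_nonde`,
#'   `direction_bias`, `regressions`, `zero_fst`, `modules`,
#'   `module_enrichment`, `summary`, `truth` (when simulated), `config`.
#' @examples
#' \donttest{
#' cfg <- run_config(simulation = sim_params(n_genes = 120, seed = 1),
#'                   n_resamples = 99, min_module_size = 10)
#' res <- run_pipeline(cfg)
#' res$summary$de_genes
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  # ---- data stage ----
  if (!is.null(config$simulation)) {
    params <- config$simulation
    sim <- simulate_dataset(params)
    genes <- sim$genes
    counts <- sim$counts
    labels <- sim$labels
    truth <- sim$truth
  } else {
    if (is.null(config$counts_path) || is.null(config$labels_path)) {
      stop("either a simulation or counts/labels paths are required",
        call. = FALSE
      )
    }
    counts <- read_counts_tsv(config$counts_path)
    labels <- read_labels_tsv(config$labels_path)
    genes <- if (!is.null(config$fasta_dir)) {
      read_gene_alignments(config$fasta_dir, labels)
    } else {
      NULL
    }
    truth <- NULL
  }

  # ---- popgen stage ----
  popgen <- pairwise <- NULL
  if (!is.null(genes)) {
    popgen <- popgen_stats(genes, min_called = config$min_called)
    pairwise <- pairwise_stats(genes,
      min_called = config$min_called, baseline = config$baseline_ratio
    )
    f_tbl <- dplyr::bind_rows(
      fixation_index(genes, "wild"),
      fixation_index(genes, "crop")
    )
    pca_g <- genotype_pca(genotype_matrix(genes), labels = labels)
  } else {
    f_tbl <- NULL
    pca_g <- NULL
  }

  # ---- expression stage ----
  counts_f <- filter_expressed(counts, labels,
    min_accessions = config$min_accessions, min_cpm = config$min_cpm
  )
  de <- exact_test_de(counts_f, labels, fdr = config$fdr)
  cv <- expression_cv(counts_f, labels)
  pca_e <- expression_pca(counts_f, labels = labels)

  # ---- join ----
  master <- dplyr::left_join(de, cv, by = "gene_id")
  if (!is.null(popgen)) {
    wide <- tidyr::pivot_wider(
      dplyr::select(
        popgen, "gene_id", "pool", "pi", "pi_s", "pi_n",
        "pin_pis", "tajima_d", "s_seg"
      ),
      names_from = "pool",
      values_from = c("pi", "pi_s", "pi_n", "pin_pis", "tajima_d", "s_seg")
    )
    master <- master %>%
      dplyr::left_join(wide, by = "gene_id") %>%
      dplyr::left_join(
        dplyr::select(pairwise, -"pi_wild", -"pi_crop"),
        by = "gene_id"
      )
  }

  # ---- comparative stage ----
  scans <- list()
  de_vs <- NULL
  bias <- NULL
  reg <- NULL
  zerofst <- NULL
  if (!is.null(popgen)) {
    scan_in <- master %>%
      dplyr::transmute(
        gene_id = .data$gene_id, cv_wild = .data$cv_wild,
        cv_crop = .data$cv_crop, pi = .data$pi_wild, fst = .data$fst
      )
    for (pct in config$fst_percentiles) {
      scans[[as.character(pct)]] <- matched_resampling_test(
        scan_in,
        percentile = pct, n_resamples = config$n_resamples,
        seed = config$seed + pct
      )
    }
    de_vs <- de_vs_nonde_distributions(master)
    reg <- polymorphism_expression_regression(master)
    zerofst <- zero_fst_candidates(master)
  }
  bias <- direction_bias_test(master$de, master$logfc)

  # ---- network stage ----
  net_counts <- counts_f
  if (nrow(net_counts) > config$network_max_genes) {
    vars <- apply(table_to_matrix(normalized_cpm(net_counts, log = TRUE)), 1, stats::var)
    keep <- rank(-vars, ties.method = "first") <= config$network_max_genes
    net_counts <- net_counts[keep, , drop = FALSE]
  }
  modules <- coexpression_modules(
    net_counts, labels,
    power = config$power,
    min_module_size = config$min_module_size,
    merge_height = config$merge_height
  )
  expr_net <- expr_matrix_genes(net_counts)
  mod_enr <- module_enrichment(
    modules,
    flags = dplyr::transmute(de, gene_id = .data$gene_id, flag = .data$de),
    expr = expr_net, labels = labels
  )
  outliers <- outlier_accession_report(modules, labels)

  # ---- summaries ----
  summary <- list(
    n_genes_expression = nrow(counts_f),
    de_genes = sum(de$de),
    frac_down_in_crop = if (sum(de$de) > 0) {
      mean(de$direction[de$de] == "down_in_crop")
    } else {
      NA_real_
    },
    mean_cv_wild = mean(cv$cv_wild, na.rm = TRUE),
    mean_cv_crop = mean(cv$cv_crop, na.rm = TRUE),
    direction_bias_p = bias$p_value,
    n_modules = nrow(modules$sizes),
    seed = config$seed
  )
  if (!is.null(popgen)) {
    w <- popgen[popgen$pool == "wild", ]
    cr <- popgen[popgen$pool == "crop", ]
    r <- master$ratio
    summary <- c(summary, list(
      mean_pi_wild = mean(w$pi, na.rm = TRUE),
      mean_pi_crop = mean(cr$pi, na.rm = TRUE),
      mean_ratio = mean(r[is.finite(r)], na.rm = TRUE),
      frac_ratio_zero = mean(r[is.finite(r)] == 0, na.rm = TRUE),
      frac_ratio_gt1 = mean(r[is.finite(r)] > 1, na.rm = TRUE),
      f_wild = f_tbl$f_hat[f_tbl$pool == "wild"],
      f_crop = f_tbl$f_hat[f_tbl$pool == "crop"],
      mean_fst = mean(master$fst, na.rm = TRUE),
      n_zero_fst_candidates = nrow(zerofst),
      scan_p = purrr::map_dbl(scans, "p_value")
    ))
  }

  res <- structure(
    list(
      master = master, popgen = popgen, pairwise = pairwise,
      fixation = f_tbl, de = de, cv = cv,
      pca_genotype = pca_g, pca_expression = pca_e,
      scans = scans, de_vs_nonde = de_vs, direction_bias = bias,
      regressions = reg, zero_fst = zerofst,
      modules = modules, module_enrichment = mod_enr,
      accession_outliers = outliers,
      summary = summary, truth = truth, config = config
    ),
    class = "wildcrop_run"
  )

  if (!is.null(config$outdir)) write_run(res, config$outdir)
  res
}

write_run <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_tsv(df, file.path(outdir, paste0(name, ".tsv")))
  }
  wr(res$master, "master_table")
  if (!is.null(res$popgen)) wr(res$popgen, "popgen_stats")
  wr(res$de, "differential_expression")
  if (!is.null(res$de_vs_nonde)) {
    wr(res$de_vs_nonde$summary, "de_vs_nonde_summary")
    wr(res$de_vs_nonde$tests, "de_vs_nonde_tests")
  }
  if (!is.null(res$regressions)) wr(res$regressions$slopes, "regressions")
  if (length(res$scans) > 0) {
    wr(purrr::map_dfr(res$scans, tidy), "cv_outlier_scans")
  }
  if (!is.null(res$zero_fst)) wr(res$zero_fst, "zero_fst_candidates")
  wr(res$modules$labels, "modules")
  wr(res$modules$eigengenes, "eigengenes")
  wr(res$module_enrichment, "module_enrichment")
  wr(
    dplyr::select(res$de, "gene_id", "q_value"),
    "qvalue_table"
  )
  jsonlite::write_json(
    res$summary,
    file.path(outdir, "summary.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE
  )
  cfg_out <- config_as_list(res$config)
  cfg_out$outdir <- NULL # location-independent, keeps reruns byte-identical
  cfg_out$wildcrop_version <- as.character(utils::packageVersion("wildcrop"))
  yaml::write_yaml(cfg_out, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' @export
print.wildcrop_run <- function(x, ...) {
  s <- x$summary
  cat("<wildcrop_run>\n")
  cat(sprintf(
    "  %d genes analyzed; %d DE (%.0f%% down in crop)\n",
    s$n_genes_expression, s$de_genes, 100 * s$frac_down_in_crop
  ))
  if (!is.null(s$mean_ratio)) {
    cat(sprintf(
      "  mean pi ratio %.2f; F wild/crop %.2f/%.2f; %d modules\n",
      s$mean_ratio, s$f_wild, s$f_crop, s$n_modules
    ))
  }
  invisible(x)
}

#' Manhattan-style plot of DE q-values
#'
#' Genes in input order against -log10(q), with the FDR threshold line.
#'
#' @param de DE results tibble from [exact_test_de()].
#' @param fdr Threshold line (default the attribute stored on `de`).
#' @return A ggplot.
#' @export
plot_qvalues <- function(de, fdr = NULL) {
  if (is.null(fdr)) fdr <- attr(de, "fdr") %||% 0.01
  df <- dplyr::mutate(de, index = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(
    .data$index, -log10(.data$q_value),
    colour = .data$de
  )) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "black")) +
    ggplot2::geom_hline(
      yintercept = -log10(fdr), colour = "firebrick",
      linetype = 2
    ) +
    ggplot2::labs(x = "gene index", y = "-log10(q)") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline input files
#'
#' Checks FASTA alignments (codon frame, equal lengths), the counts table
#' (integrality, non-negativity, duplicate gene ids) and label coverage.
#' Problems are split into hard failures and warnings.
#'
#' @param counts_path,labels_path,fasta_dir Input paths (any may be `NULL`).
#' @return Tibble with columns `level` (`fail`/`warn`) and `message`;
#'   zero rows means all checks passed.
#' @export
validate_inputs <- function(counts_path = NULL, labels_path = NULL,
                            fasta_dir = NULL) {
  probs <- list()
  add <- function(level, msg) {
    probs[[length(probs) + 1]] <<- tibble::tibble(level = level, message = msg)
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path)) {
      add("fail", paste("labels file not found:", labels_path))
    } else {
      labels <- readr::read_tsv(labels_path, show_col_types = FALSE)
      if (!all(c("accession", "pool") %in% names(labels))) {
        add("fail", "labels must have columns accession, pool")
        labels <- NULL
      } else if (!all(labels$pool %in% c("wild", "crop"))) {
        add("fail", "pool labels must be 'wild' or 'crop'")
      }
    }
  }
  if (!is.null(counts_path)) {
    if (!file.exists(counts_path)) {
      add("fail", paste("counts file not found:", counts_path))
    } else {
      counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
      if (!"gene_id" %in% names(counts)) {
        add("fail", "counts must have a gene_id column")
      } else {
        if (anyDuplicated(counts$gene_id) > 0) {
          add("fail", "duplicate gene ids in counts")
        }
        m <- as.matrix(counts[, -1])
        if (any(m < 0, na.rm = TRUE)) add("fail", "negative counts")
        if (any(m != round(m), na.rm = TRUE)) {
          add("fail", "non-integer counts")
        }
        if (!is.null(labels)) {
          missing <- setdiff(colnames(counts)[-1], labels$accession)
          if (length(missing) > 0) {
            add("fail", paste(
              "accessions missing from labels:",
              paste(missing, collapse = ", ")
            ))
          }
        }
      }
    }
  }
  if (!is.null(fasta_dir)) {
    files <- list.files(fasta_dir,
      pattern = "\\.(fa|fasta)$",
      full.names = TRUE
    )
    if (length(files) == 0) {
      add("fail", paste("no FASTA files in", fasta_dir))
    }
    for (fp in files) {
      dss <- Biostrings::readDNAStringSet(fp)
      w <- Biostrings::width(dss)
      if (length(unique(w)) > 1) {
        add("fail", paste(basename(fp), ": unequal sequence lengths"))
      } else if (w[1] %% 3 != 0) {
        add("fail", paste(basename(fp), ": length not multiple of 3"))
      }
      if (length(dss) %% 2 != 0) {
        add("warn", paste(basename(fp), ": odd haplotype count"))
      }
    }
  }
  if (length(probs) == 0) {
    return(tibble::tibble(level = character(0), message = character(0)))
  }
  dplyr::bind_rows(probs)
}
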