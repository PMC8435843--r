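# Plain-text fixture writing and reading: per-gene FASTA haplotype
# alignments, a VCF-like site table, counts/labels/truth TSVs.

#' Write a simulated dataset to plain-text files
#'
#' Emits, under `outdir`: one FASTA haplotype alignment per gene
#' (`fasta/<gene_id>.fa`, two records per diploid accession named
#' `<accession>_1/_2`), a VCF-like site table (`sites.tsv`: CHROM = gene,
#' 1-based POS, REF/ALT, per-accession GT with `./.` for missing), the raw
#' counts matrix (`counts.tsv`), pool labels (`labels.tsv`) and the truth
#' ledger (`truth.tsv`). Output is byte-stable for a fixed seed.
#'
#' @param sim A `wildcrop_sim` (or `genotype_sim`) object.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a character vector of written paths.
#' @export
write_fixtures <- function(sim, outdir) {
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  fasta_dir <- file.path(outdir, "fasta")
  dir.create(fasta_dir, showWarnings = FALSE)
  paths <- character(0)

  gl <- gene_list(sim)
  site_rows <- list()
  for (g in gl) {
    m <- as_alignment_matrix(g, "both")
    seqs <- apply(m, 1, paste, collapse = "")
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- rownames(m)
    fp <- file.path(fasta_dir, paste0(g$gene_id, ".fa"))
    Biostrings::writeXStringSet(dss, fp, width = 80L)
    paths <- c(paths, fp)
    if (length(g$pos) > 0) {
      anc_chars <- strsplit(g$anc, "")[[1]]
      hap <- rbind(g$wild_hap, g$crop_hap)
      n_ind <- nrow(hap) / 2L
      acc <- sub("_[12]$", "", rownames(hap)[2 * seq_len(n_ind)])
      gts <- matrix("", length(g$pos), n_ind, dimnames = list(NULL, acc))
      alt <- character(length(g$pos))
      for (s in seq_along(g$pos)) {
        ref <- anc_chars[g$pos[s]]
        col <- hap[, s]
        alleles <- setdiff(unique(col), c(ref, "N"))
        alt[s] <- if (length(alleles) == 0) "." else paste(alleles, collapse = ",")
        code <- function(a) {
          if (a == "N") {
            "."
          } else if (a == ref) {
            "0"
          } else {
            as.character(match(a, alleles))
          }
        }
        a1 <- col[2 * seq_len(n_ind) - 1]
        a2 <- col[2 * seq_len(n_ind)]
        gts[s, ] <- paste0(
          vapply(a1, code, character(1)), "/",
          vapply(a2, code, character(1))
        )
      }
      site_rows[[g$gene_id]] <- tibble::tibble(
        CHROM = g$gene_id, POS = g$pos,
        REF = anc_chars[g$pos], ALT = alt,
        tibble::as_tibble(gts)
      )
    }
  }
  sites <- dplyr::bind_rows(site_rows)
  fp_sites <- file.path(outdir, "sites.tsv")
  readr::write_tsv(sites, fp_sites)
  paths <- c(paths, fp_sites)

  if (!is.null(sim$counts)) {
    fp <- file.path(outdir, "counts.tsv")
    readr::write_tsv(sim$counts, fp)
    paths <- c(paths, fp)
    fp <- file.path(outdir, "labels.tsv")
    readr::write_tsv(sim$labels, fp)
    paths <- c(paths, fp)
  }
  if (!is.null(sim$truth)) {
    fp <- file.path(outdir, "truth.tsv")
    readr::write_tsv(sim$truth, fp)
    paths <- c(paths, fp)
  }
  invisible(paths)
}

#' Read per-gene FASTA haplotype alignments
#'
#' Reads every `*.fa`/`*.fasta` file in a directory into `gene_geno` objects.
#' Record names must be `<accession>_1` / `<accession>_2`; pool membership
#' comes from the labels table.
#'
#' @param fasta_dir Directory of per-gene FASTA alignments.
#' @param labels Tibble with columns `accession` and `pool`
#'   (`wild`/`crop`).
#' @return A tibble with columns `gene_id` and `geno` (list-column).
#' @export
read_gene_alignments <- function(fasta_dir, labels) {
  files <- list.files(fasta_dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (length(files) == 0) stop("no FASTA files in ", fasta_dir, call. = FALSE)
  stopifnot(all(c("accession", "pool") %in% names(labels)))
  genes <- purrr::map(files, function(fp) {
    dss <- Biostrings::readDNAStringSet(fp)
    m <- t(vapply(
      seq_along(dss),
      function(i) strsplit(as.character(dss[[i]]), "")[[1]],
      character(Biostrings::width(dss)[1])
    ))
    rownames(m) <- names(dss)
    acc <- sub("_[12]$", "", rownames(m))
    pool <- labels$pool[match(acc, labels$accession)]
    if (anyNA(pool)) {
      stop("accessions missing from labels in ", fp, call. = FALSE)
    }
    ord <- order(match(acc, labels$accession), rownames(m))
    m <- m[ord, , drop = FALSE]
    pool <- pool[ord]
    gene_geno_from_alignment(
      gene_id = sub("\\.(fa|fasta)$", "", basename(fp)),
      wild = m[pool == "wild", , drop = FALSE],
      crop = m[pool == "crop", , drop = FALSE]
    )
  })
  tibble::tibble(
    gene_id = vapply(genes, function(g) g$gene_id, character(1)),
    geno = genes
  )
}

#' Read a counts TSV (genes x accessions)
#'
#' @param path TSV with a `gene_id` first column and one integer column per
#'   accession.
#' @return A tibble.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a pool-label TSV
#'
#' @param path TSV with columns `accession` and `pool`.
#' @return A tibble.
#' @export
read_labels_tsv <- function(path) {
  labels <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("accession", "pool") %in% names(labels)))
  labels
}
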