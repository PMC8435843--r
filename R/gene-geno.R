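# Per-gene genotype container: haplotype alignments (2 per diploid
# accession) of both pools, stored compactly as ancestral sequence +
# segregating-site allele matrices + per-site called-individual counts.

new_gene_geno <- function(gene_id, L, anc, pos, wild_hap, crop_hap,
                          wild_called, crop_called, n_wild, n_crop,
                          frame = 0L) {
  structure(
    list(
      gene_id = gene_id, L = as.integer(L), frame = as.integer(frame),
      anc = anc, pos = as.integer(pos),
      wild_hap = wild_hap, crop_hap = crop_hap,
      wild_called = as.integer(wild_called),
      crop_called = as.integer(crop_called),
      n_wild = as.integer(n_wild), n_crop = as.integer(n_crop)
    ),
    class = "gene_geno"
  )
}

#' @export
print.gene_geno <- function(x, ...) {
  cat(sprintf(
    "<gene_geno> %s: %d bp, %d segregating sites, %d wild + %d crop accessions\n",
    x$gene_id, x$L, length(x$pos), x$n_wild, x$n_crop
  ))
  invisible(x)
}

pool_hap <- function(gene, pool) {
  switch(pool,
    wild = gene$wild_hap,
    crop = gene$crop_hap,
    stop("pool must be 'wild' or 'crop'", call. = FALSE)
  )
}

pool_called <- function(gene, pool) {
  switch(pool,
    wild = gene$wild_called,
    crop = gene$crop_called,
    stop("pool must be 'wild' or 'crop'", call. = FALSE)
  )
}

#' Expand a gene's haplotypes to a full alignment matrix
#'
#' Reconstructs the complete haplotype-by-site character matrix (bases
#' A/C/G/T, `N` for missing genotypes) from the compact representation.
#' Missingness at invariant sites is not individually tracked, so invariant
#' columns are the ancestral base for all haplotypes.
#'
#' @param gene A `gene_geno` object.
#' @param pool `"wild"`, `"crop"` or `"both"`.
#' @return Character matrix with one row per haplotype.
#' @export
as_alignment_matrix <- function(gene, pool = "both") {
  stopifnot(inherits(gene, "gene_geno"))
  hap <- if (pool == "both") {
    rbind(gene$wild_hap, gene$crop_hap)
  } else {
    pool_hap(gene, pool)
  }
  anc_chars <- strsplit(gene$anc, "")[[1]]
  full <- matrix(rep(anc_chars, each = nrow(hap)), nrow = nrow(hap))
  if (length(gene$pos) > 0) full[, gene$pos] <- hap
  rownames(full) <- rownames(hap)
  full
}

#' Build a gene_geno object from full haplotype alignments
#'
#' Entry point for real data: takes one character matrix per pool (two rows
#' per diploid accession, aligned coding sequence, `N` for missing calls) and
#' compresses it to the internal representation. The ancestral state is taken
#' as the majority allele across all haplotypes (ties broken alphabetically).
#'
#' @param gene_id Gene identifier.
#' @param wild,crop Character matrices (haplotypes x sites) with rownames
#'   `<accession>_1` / `<accession>_2`.
#' @param frame Codon frame offset (bases to trim from the start).
#' @return A `gene_geno` object.
#' @export
gene_geno_from_alignment <- function(gene_id, wild, crop, frame = 0L) {
  if (ncol(wild) != ncol(crop)) {
    stop("wild and crop alignments must have equal length", call. = FALSE)
  }
  if (frame > 0) {
    wild <- wild[, -seq_len(frame), drop = FALSE]
    crop <- crop[, -seq_len(frame), drop = FALSE]
  }
  L <- ncol(wild)
  trim <- L %% 3L
  if (trim > 0) {
    wild <- wild[, seq_len(L - trim), drop = FALSE]
    crop <- crop[, seq_len(L - trim), drop = FALSE]
    L <- L - trim
  }
  all_hap <- rbind(wild, crop)
  # majority (consensus) base per site
  anc_chars <- apply(all_hap, 2, function(col) {
    col <- col[col %in% BASES]
    if (length(col) == 0) {
      return("A")
    }
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1]
  })
  n_alleles <- apply(all_hap, 2, function(col) {
    length(unique(col[col %in% BASES]))
  })
  pos <- which(n_alleles >= 2)
  called_ind <- function(m, n_ind) {
    ok <- matrix(TRUE, n_ind, ncol(m))
    for (k in seq_len(n_ind)) {
      ok[k, ] <- m[2 * k - 1, ] != "N" & m[2 * k, ] != "N"
    }
    as.integer(colSums(ok))
  }
  new_gene_geno(
    gene_id = gene_id, L = L, frame = 0L,
    anc = paste(anc_chars, collapse = ""), pos = pos,
    wild_hap = wild[, pos, drop = FALSE],
    crop_hap = crop[, pos, drop = FALSE],
    wild_called = called_ind(wild, nrow(wild) / 2L),
    crop_called = called_ind(crop, nrow(crop) / 2L),
    n_wild = nrow(wild) / 2L, n_crop = nrow(crop) / 2L
  )
}

#' Remove sites called in too few individuals
#'
#' Drops every site called in fewer than `min_called` individuals in either
#' pool. To keep a consistent reading frame for synonymous/nonsynonymous
#' analysis, the whole codon containing a removed position is dropped, and
#' codon bookkeeping (gene length, segregating-site coordinates) is
#' recomputed. A gene with zero surviving sites is flagged
#' (`attr(, "empty")`), not an error.
#'
#' @param gene A `gene_geno` object.
#' @param min_called Minimum called individuals per pool (default 5).
#' @return A filtered `gene_geno`; attribute `n_codons_removed` records the
#'   number of dropped codons.
#' @export
filter_sites <- function(gene, min_called = 5L) {
  stopifnot(inherits(gene, "gene_geno"))
  bad_site <- which(
    gene$wild_called < min_called | gene$crop_called < min_called
  )
  if (length(bad_site) == 0) {
    attr(gene, "n_codons_removed") <- 0L
    return(gene)
  }
  bad_codon <- unique((bad_site - 1L) %/% 3L + 1L)
  keep_codon <- setdiff(seq_len(gene$L %/% 3L), bad_codon)
  keep_site <- as.vector(outer(-2:0, 3L * keep_codon, `+`))
  keep_site <- sort(keep_site)
  new_L <- length(keep_site)
  # remap positions
  new_index <- integer(gene$L)
  new_index[keep_site] <- seq_len(new_L)
  keep_seg <- gene$pos %in% keep_site
  anc_chars <- strsplit(gene$anc, "")[[1]]
  out <- new_gene_geno(
    gene_id = gene$gene_id, L = new_L,
    anc = paste(anc_chars[keep_site], collapse = ""),
    pos = new_index[gene$pos[keep_seg]],
    wild_hap = gene$wild_hap[, keep_seg, drop = FALSE],
    crop_hap = gene$crop_hap[, keep_seg, drop = FALSE],
    wild_called = gene$wild_called[keep_site],
    crop_called = gene$crop_called[keep_site],
    n_wild = gene$n_wild, n_crop = gene$n_crop
  )
  attr(out, "n_codons_removed") <- length(bad_codon)
  attr(out, "empty") <- new_L == 0L
  out
}
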