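# Codon-level machinery for Nei-Gojobori (NG86) synonymous/nonsynonymous
# site counting and pairwise difference decomposition.

BASES <- c("A", "C", "G", "T")

genetic_code <- function() Biostrings::GENETIC_CODE

codon_aa <- function(codon) unname(genetic_code()[codon])

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

is_stop <- function(codon) {
  aa <- genetic_code()[codon]
  !is.na(aa) & aa == "*"
}

# cache environment for per-codon and per-pair lookups
.codon_cache <- new.env(parent = emptyenv())

#' Nei-Gojobori synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position, the synonymous site fraction is the proportion of
#' the three possible single-base changes that leave the amino acid unchanged
#' (changes to stop codons count as nonsynonymous, so the two counts always
#' sum to exactly 3). Codons containing characters other than A/C/G/T (e.g.
#' missing data) return `NA`.
#'
#' @param codon A single 3-letter codon string.
#' @return Named numeric vector `c(syn = , nonsyn = )`.
#' @examples
#' ng86_site_counts("TTT") # 1/3 synonymous, 8/3 nonsynonymous
#' @export
ng86_site_counts <- function(codon) {
  key <- paste0("S:", codon)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  gc <- genetic_code()
  if (is.na(gc[codon])) {
    out <- c(syn = NA_real_, nonsyn = NA_real_)
    .codon_cache[[key]] <- out
    return(out)
  }
  aa <- gc[[codon]]
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- b
      if (gc[[paste(mut, collapse = "")]] == aa) syn <- syn + 1 / 3
    }
  }
  out <- c(syn = syn, nonsyn = 3 - syn)
  .codon_cache[[key]] <- out
  out
}

# All orderings of the differing positions between two codons; each pathway
# step is classified synonymous/nonsynonymous; pathways passing through stop
# codons are excluded (if every pathway hits a stop, all are used).
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) {
    return(c(syn = 0, nonsyn = 0))
  }
  key <- if (c1 < c2) paste0("P:", c1, c2) else paste0("P:", c2, c1)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  gc <- genetic_code()
  if (is.na(gc[c1]) || is.na(gc[c2])) {
    out <- c(syn = NA_real_, nonsyn = NA_real_)
    .codon_cache[[key]] <- out
    return(out)
  }
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  dpos <- which(a != b)
  perms <- switch(as.character(length(dpos)),
    "1" = list(dpos),
    "2" = list(dpos, rev(dpos)),
    "3" = {
      o <- list(
        c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
        c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
      )
      lapply(o, function(i) dpos[i])
    }
  )
  eval_path <- function(order) {
    cur <- a
    syn <- 0
    nonsyn <- 0
    ok <- TRUE
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      cod1 <- paste(cur, collapse = "")
      cod2 <- paste(nxt, collapse = "")
      if (gc[[cod2]] == "*" && cod2 != c2) ok <- FALSE
      if (gc[[cod1]] == gc[[cod2]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn, nonsyn, as.numeric(ok))
  }
  res <- vapply(perms, eval_path, numeric(3))
  valid <- res[3, ] == 1
  if (!any(valid)) valid <- rep(TRUE, ncol(res))
  out <- c(
    syn = mean(res[1, valid]),
    nonsyn = mean(res[2, valid])
  )
  .codon_cache[[key]] <- out
  out
}

# Weight table used by the generator: for every sense codon and position,
# which alternative bases are synonymous / nonsynonymous / stop-creating.
# Returns a list keyed by codon with a 3x3 character classification.
codon_mutation_table <- function() {
  hit <- .codon_cache[["MUT_TABLE"]]
  if (!is.null(hit)) {
    return(hit)
  }
  gc <- genetic_code()
  tab <- lapply(sense_codons(), function(cod) {
    chars <- strsplit(cod, "")[[1]]
    aa <- gc[[cod]]
    m <- matrix(NA_character_, 3, 3)
    for (pos in 1:3) {
      alts <- setdiff(BASES, chars[pos])
      cls <- vapply(alts, function(bb) {
        mut <- chars
        mut[pos] <- bb
        aa2 <- gc[[paste(mut, collapse = "")]]
        if (aa2 == "*") "stop" else if (aa2 == aa) "syn" else "nonsyn"
      }, character(1))
      m[pos, ] <- cls
      rownames(m) <- NULL
    }
    alts <- t(vapply(1:3, function(pos) setdiff(BASES, chars[pos]),
      character(3)
    ))
    list(alts = alts, class = m)
  })
  names(tab) <- sense_codons()
  .codon_cache[["MUT_TABLE"]] <- tab
  tab
}

# Fraction of NG86 nonsynonymous mutational opportunity that does not create
# a stop codon, under a uniform distribution over sense codons. Used to
# rescale the generator's nonsynonymous acceptance weight so the *measured*
# piN/piS (with stops counted as nonsynonymous sites) matches the target.
nonstop_nonsyn_fraction <- function() {
  hit <- .codon_cache[["NONSTOP_FRAC"]]
  if (!is.null(hit)) {
    return(hit)
  }
  tab <- codon_mutation_table()
  n_nonsyn <- 0
  n_nonstop <- 0
  for (cod in names(tab)) {
    cls <- tab[[cod]]$class
    n_nonsyn <- n_nonsyn + sum(cls != "syn")
    n_nonstop <- n_nonstop + sum(cls == "nonsyn")
  }
  out <- n_nonstop / n_nonsyn
  .codon_cache[["NONSTOP_FRAC"]] <- out
  out
}
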