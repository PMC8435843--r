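# co-expression network: signed similarity endpoints, TOM against the
# O(n^3) oracle, module detection/merging, enrichment, outlier accessions.

test_that("signed similarity maps correlation endpoints exactly", {
  x <- seq_len(10)
  expr <- rbind(x, -x, rev(x) * 2)
  s <- (1 + cor(t(expr))) / 2
  expect_equal(s[1, 2], 0)
  expect_equal(s[1, 1], 1)
  expect_equal(s[1, 3], 0)
  a <- signed_adjacency(expr, beta = 6)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(diag(a), rep(1, 3), ignore_attr = TRUE)
})

test_that("TOM matches closed-form values and the brute-force oracle", {
  # two perfectly correlated genes: a = 1, TOM = 1, dissTOM = 0
  x <- seq_len(12)
  expr2 <- rbind(g1 = x, g2 = 2 * x + 3)
  a2 <- signed_adjacency(expr2, beta = 20)
  tm2 <- build_tom(a2)
  expect_equal(tm2$tom[1, 2], 1, tolerance = 1e-12)
  expect_equal(tm2$diss[1, 2], 0, tolerance = 1e-12)

  # uncorrelated pair with no shared neighbours: TOM = a = 0.5^beta
  a0 <- matrix(c(1, 0.5^20, 0.5^20, 1), 2)
  tm0 <- build_tom(a0)
  expect_equal(tm0$tom[1, 2], 0.5^20 / (0.5^20 + 1 - 0.5^20), tolerance = 1e-15)

  # random 15-gene adjacencies agree with the O(n^3) oracle to 1e-12
  set.seed(61)
  for (rep in 1:5) {
    expr <- matrix(rnorm(15 * 20), 15)
    adj <- signed_adjacency(expr, beta = sample(c(6, 12, 20), 1))
    tm <- build_tom(adj)
    expect_equal(tm$tom, oracle_tom(adj), tolerance = 1e-12)
    # invariants: symmetry, unit diagonal, entries in [0, 1]
    expect_equal(tm$tom, t(tm$tom), tolerance = 1e-12)
    expect_equal(diag(tm$tom), rep(1, 15), ignore_attr = TRUE)
    expect_true(all(tm$tom >= -1e-12 & tm$tom <= 1 + 1e-12))
  }
})

test_that("soft power selection returns sane fits and honours the bypass", {
  pm <- planted_module_expr(n_mod = 3, size = 30, n_bg = 30, seed = 3)
  ps <- pick_soft_power(pm$expr, powers = c(2, 6, 12, 20))
  expect_true(ps$power %in% c(2, 6, 12, 20))
  expect_true(all(ps$fit$rsq >= -1 & ps$fit$rsq <= 1, na.rm = TRUE))
  expect_true(all(ps$fit$mean_k > 0))
  # connectivity decreases with power
  expect_true(all(diff(ps$fit$mean_k) < 0))
  # fixed power bypass
  expect_equal(pick_soft_power(pm$expr, fixed_power = 20)$power, 20)
})

test_that("planted orthogonal modules are recovered with high ARI", {
  pm <- planted_module_expr(n_mod = 3, size = 50, n_bg = 60, noise = 0.4, seed = 5)
  adj <- signed_adjacency(pm$expr, beta = 20)
  tm <- build_tom(adj)
  ms <- detect_modules(tm$diss, pm$expr, min_module_size = 20)
  expect_equal(nrow(ms$sizes), 3)
  planted <- pm$truth > 0
  expect_gt(ari(ms$labels$module[planted], pm$truth[planted]), 0.95)
  # background stays unassigned
  expect_gt(mean(ms$labels$module[!planted] == 0), 0.8)
})

test_that("tiny or degenerate inputs behave as documented", {
  pm <- planted_module_expr(n_mod = 2, size = 10, n_bg = 5, seed = 6)
  adj <- signed_adjacency(pm$expr, beta = 6)
  tm <- build_tom(adj)
  # min_module_size larger than the gene count: everything unassigned
  expect_warning(
    ms <- detect_modules(tm$diss, pm$expr, min_module_size = 1000),
    "unassigned"
  )
  expect_true(all(ms$labels$module == 0))
})

test_that("module merging follows the eigengene dissimilarity threshold", {
  set.seed(8)
  n_samp <- 30
  z1 <- rnorm(n_samp)
  z2 <- 0.9 * z1 + sqrt(1 - 0.9^2) * rnorm(n_samp) # eigengene diss ~ 0.1
  z3 <- 0.5 * z1 + sqrt(1 - 0.5^2) * rnorm(n_samp) # eigengene diss ~ 0.5
  mk <- function(z, size) {
    t(sapply(seq_len(size), function(i) z + rnorm(n_samp, sd = 0.3)))
  }
  expr <- rbind(mk(z1, 40), mk(z2, 40), mk(z3, 40))
  rownames(expr) <- sprintf("g%03d", 1:120)
  adj <- signed_adjacency(expr, beta = 12)
  tm <- build_tom(adj)
  merged <- detect_modules(tm$diss, expr,
    min_module_size = 20,
    merge_height = 0.25
  )
  # the 0.9-correlated pair collapses (diss 0.1 < 0.25); the 0.5-correlated
  # module stays separate (diss ~0.5 > 0.25)
  expect_equal(nrow(merged$sizes), 2)
  m_of <- function(gene) merged$labels$module[merged$labels$gene_id == gene]
  expect_equal(m_of("g001"), m_of("g041")) # z1 and z2 genes together
  expect_false(m_of("g001") == m_of("g081")) # z3 genes apart
})

test_that("eigengenes are unit-norm first PCs explaining the most variance", {
  pm <- planted_module_expr(n_mod = 2, size = 40, n_bg = 20, seed = 9)
  adj <- signed_adjacency(pm$expr, beta = 12)
  tm <- build_tom(adj)
  ms <- detect_modules(tm$diss, pm$expr, min_module_size = 20)
  eg <- as.matrix(ms$eigengenes[, -1])
  for (j in seq_len(ncol(eg))) {
    expect_equal(sum(eg[, j]^2), 1, tolerance = 1e-8)
  }
  # first-PC optimality: the eigengene explains at least the average
  # per-gene share of its module's variance
  for (i in seq_along(ms$eigengene_var)) {
    mod <- ms$sizes$module[i]
    size <- ms$sizes$size[i]
    expect_gte(ms$eigengene_var[i], 1 / size)
  }
})

test_that("module enrichment flags a fully DE module with direction", {
  pm <- planted_module_expr(n_mod = 3, size = 40, n_bg = 40, seed = 10)
  adj <- signed_adjacency(pm$expr, beta = 12)
  tm <- build_tom(adj)
  ms <- detect_modules(tm$diss, pm$expr, min_module_size = 20)
  # flag exactly the genes of (detected) module 1
  flags <- tibble::tibble(
    gene_id = ms$labels$gene_id,
    flag = ms$labels$module == 1
  )
  labels <- tibble::tibble(
    accession = colnames(pm$expr),
    pool = rep(c("wild", "crop"), each = ncol(pm$expr) / 2)
  )
  enr <- module_enrichment(ms, flags, expr = pm$expr, labels = labels)
  expect_lt(enr$q_value[enr$module == 1], 1e-6)
  expect_gt(enr$odds_ratio[enr$module == 1], 1)
  # the remaining modules can only be depleted, never enriched
  expect_true(all(enr$odds_ratio[enr$module != 1] < 1))
  expect_true(all(enr$direction %in% c("down_in_crop", "up_in_crop")))

  # independent flags: no module should be strongly enriched
  set.seed(11)
  flags_null <- tibble::tibble(
    gene_id = ms$labels$gene_id,
    flag = runif(nrow(ms$labels)) < 0.3
  )
  enr_null <- module_enrichment(ms, flags_null)
  expect_gt(min(enr_null$q_value), 0.001)
})

test_that("aberrant accessions are flagged by module eigengene z-scores", {
  # pools of 20 accessions: the within-pool z of a single accession is
  # bounded by (n-1)/sqrt(n), so pools must be large enough for z > 2.5
  pm <- planted_module_expr(n_mod = 2, size = 40, n_bg = 20, n_samp = 40, seed = 12)
  expr <- pm$expr
  # one accession grossly shifted in module 1 genes only
  expr[pm$truth == 1, 3] <- expr[pm$truth == 1, 3] + 6
  adj <- signed_adjacency(expr, beta = 12)
  tm <- build_tom(adj)
  ms <- detect_modules(tm$diss, expr, min_module_size = 20)
  labels <- tibble::tibble(
    accession = colnames(expr),
    pool = rep(c("wild", "crop"), each = 20)
  )
  rep_tbl <- outlier_accession_report(ms, labels, z_cut = 2.5)
  flagged_acc <- unique(rep_tbl$accession[rep_tbl$flagged])
  expect_true(colnames(expr)[3] %in% flagged_acc)

  # an accession sitting at its pool mean has z = 0; construct directly
  eg_z <- rep_tbl$z[rep_tbl$accession == colnames(expr)[3]]
  expect_true(any(abs(eg_z) > 2.5))
})
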