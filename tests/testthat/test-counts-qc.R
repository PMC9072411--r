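test_that("log fold change follows the CPM + 1 pseudo-count formula exactly", {
  d <- tiny_design(seed = 2, n_genes = 1, guides_per_gene = 1,
                   n_cutting = 1, n_noncutting = 0)
  cons <- enumerate_constructs(d)  # 2x2 = 4 constructs
  counts <- matrix(c(100, 50, 999900 - 100, 999950 - 50,
                     100, 100, 999900 - 100, 999900 - 100),
                   nrow = 4, byrow = FALSE,
                   dimnames = list(cons$construct_id, c("d15_b1", "pDNA_b1")))
  counts <- counts[, c("pDNA_b1", "d15_b1")]
  counts[, "pDNA_b1"] <- c(50, 100, 999950 - 50, 999900 - 100)
  counts[, "d15_b1"] <- c(100, 0, 999900 - 100, 1e6)
  meta <- data.frame(sample_id = c("pDNA_b1", "d15_b1"),
                     condition = c("pDNA", "glucose"), batch = 1,
                     timepoint = c("pDNA", "d15"))
  lfc <- compute_lfc(counts, meta, cons)
  tot_p <- sum(counts[, "pDNA_b1"]); tot_e <- sum(counts[, "d15_b1"])
  # construct 1: endpoint 100, pDNA 50 (totals ~1e6 each)
  expect_equal(lfc$lfc[1],
               log2(100 / tot_e * 1e6 + 1) - log2(50 / tot_p * 1e6 + 1))
  expect_equal(lfc$lfc[1], log2(100 / tot_e * 1e6 + 1) -
                 log2(50 / tot_p * 1e6 + 1), tolerance = 1e-12)
  # zero endpoint count stays finite: -log2(pDNA CPM + 1)
  expect_equal(lfc$lfc[2], -log2(100 / tot_p * 1e6 + 1))
  expect_true(all(is.finite(lfc$lfc)))

  # identical CPM in endpoint and pDNA -> LFC exactly 0
  counts2 <- counts; counts2[, "d15_b1"] <- counts[, "pDNA_b1"] * 3L
  lfc2 <- compute_lfc(counts2, meta, cons)
  expect_equal(lfc2$lfc, rep(0, 4))

  # scaling a whole sample leaves all LFCs unchanged (CPM property)
  counts3 <- counts; counts3[, "d15_b1"] <- counts[, "d15_b1"] * 7L
  expect_equal(compute_lfc(counts3, meta, cons)$lfc, lfc$lfc)
})

test_that("low-pDNA filtering matches a brute-force evaluation of the rule", {
  s <- small_screen(design = tiny_design(seed = 5, n_genes = 4), seed = 21)
  counts <- s$screen$counts; meta <- s$screen$sample_meta
  res <- filter_low_pdna(s$lfc, counts, meta,
                         cutoff_rule = list(type = "quantile", q = 0.05))
  # oracle: recompute the removed set with plain loops
  pdna_col <- meta$sample_id[meta$timepoint == "pDNA"]
  pc <- counts[, pdna_col]
  cutoff <- unname(quantile(pc, 0.05))
  cons <- unique(as.data.frame(s$lfc)[, c("construct_id", "sp_guide_id",
                                          "sa_guide_id")])
  removed <- cons$construct_id[pc[cons$construct_id] < cutoff]
  for (col in c("sp_guide_id", "sa_guide_id")) {
    for (g in unique(cons[[col]])) {
      ids <- cons$construct_id[cons[[col]] == g]
      if (median(pc[ids]) < cutoff) removed <- union(removed, ids)
    }
  }
  expect_setequal(res$report$removed_constructs, removed)

  # all pDNA counts equal -> nothing removed
  counts_eq <- counts; counts_eq[, pdna_col] <- 100L
  lfc_eq <- compute_lfc(counts_eq, meta, s$screen$constructs)
  res_eq <- filter_low_pdna(lfc_eq, counts_eq, meta)
  expect_equal(res_eq$report$n_removed, 0L)

  # a guide with pDNA count 0 everywhere loses every pair containing it
  g0 <- s$screen$design$sp_guides$guide_id[1]
  counts0 <- counts
  hit <- s$screen$constructs$construct_id[
    s$screen$constructs$sp_guide_id == g0]
  counts0[hit, pdna_col] <- 0L
  lfc0 <- compute_lfc(counts0, meta, s$screen$constructs)
  res0 <- filter_low_pdna(lfc0, counts0, meta,
                          cutoff_rule = list(type = "absolute", value = 10))
  expect_true(all(hit %in% res0$report$removed_constructs))
})

test_that("non-cutting filter obeys the inclusion-exclusion identity", {
  for (nn in c(0, 2, 5)) {
    d <- tiny_design(seed = 7, n_genes = 3, n_noncutting = nn, n_cutting = 4)
    s <- small_screen(design = d, scenario = "null", seed = 2)
    res <- filter_noncutting(s$lfc)
    n_sp <- nrow(d$sp_guides); n_sa <- nrow(d$sa_guides)
    expect_equal(res$report$n_removed, nn * n_sa + n_sp * nn - nn * nn)
    # brute-force set union
    cons <- s$screen$constructs
    brute <- union(
      cons$construct_id[cons$sp_category == "noncutting_ctrl"],
      cons$construct_id[cons$sa_category == "noncutting_ctrl"])
    expect_setequal(res$report$removed_constructs, brute)
  }
})

test_that("lethal cutting controls are flagged exactly as injected", {
  d <- tiny_design(seed = 9, n_genes = 4, n_cutting = 10)
  p <- sim_params(n_batches = 1, conditions = c("glucose", "galactose"),
                  pdna_depth = 400, endpoint_depth = 400,
                  lethal_cutting_fraction = 0.15)
  s <- small_screen(design = d, scenario = "paper_like", seed = 3, params = p)
  res <- filter_lethal_cutting_controls(s$lfc)
  expect_setequal(res$report$details$flagged_guides, s$truth$lethal_guides)

  # brute-force oracle for the removal set
  flagged <- res$report$details$flagged_guides
  cons <- s$screen$constructs
  brute <- cons$construct_id[cons$sp_guide_id %in% flagged |
                               cons$sa_guide_id %in% flagged]
  expect_setequal(res$report$removed_constructs, brute)

  # neutral controls: nothing flagged
  s0 <- small_screen(design = d, scenario = "null", seed = 4)
  res0 <- filter_lethal_cutting_controls(s0$lfc)
  expect_equal(res0$report$n_removed, 0L)
})

test_that("guide-concordance filter flags sign-inverted guides and matches the oracle", {
  d <- tiny_design(seed = 11, n_genes = 3, guides_per_gene = 3,
                   n_cutting = 8, n_noncutting = 0)
  p <- sim_params(n_batches = 1,
                  conditions = c("glucose", "galactose", "oxphos_inhibition"),
                  pdna_depth = 2000, endpoint_depth = 2000, dispersion = 0.01)
  tr <- make_truth(d, "custom", seed = 5, params = p)
  # strong condition-dependent fitness so guide profiles correlate
  tr$phi[] <- matrix(rnorm(length(tr$phi), -0.5, 0.6), nrow(tr$phi))
  bad_guide <- d$sp_guides$guide_id[d$sp_guides$target_gene == "SLC25A2"][1]
  tr$guide_efficacy[bad_guide] <- -1  # doctored: inverted sign
  s <- small_screen(design = d, truth = tr, params = p, seed = 6)
  res <- filter_uncorrelated_guides(s$lfc)
  expect_true(bad_guide %in% res$report$details$poor_guides)
  expect_setequal(res$report$details$poor_guides,
                  brute_force_poor_guides(s$lfc))

  # noiseless, perfectly correlated guides: none flagged
  p0 <- sim_params(n_batches = 1, conditions = c("glucose", "galactose"),
                   pdna_depth = 5e4, endpoint_depth = 5e4, dispersion = 0,
                   abundance_sigma = 0)
  tr0 <- make_truth(d, "custom", seed = 7, params = p0)
  # condition-dependent but noise-free: guides of a gene track each other
  tr0$phi[] <- matrix(c(-0.3, -1, -0.1, -1.2, -0.2, -0.8), nrow = 3)
  s0 <- small_screen(design = d, truth = tr0, params = p0, seed = 8)
  res0 <- filter_uncorrelated_guides(s0$lfc)
  expect_equal(res0$report$n_removed, 0L)
})

test_that("filter cascade is idempotent and guards representation", {
  d <- tiny_design(seed = 5, n_genes = 4)
  p <- sim_params(n_batches = 1,
                  conditions = c("glucose", "galactose", "oxphos_inhibition"),
                  pdna_depth = 500, endpoint_depth = 500)
  s <- small_screen(design = d, scenario = "paper_like", seed = 12, params = p)
  qc <- apply_qc_filters(s$lfc, s$screen$counts, s$screen$sample_meta,
                         check_representation = FALSE)
  qc2 <- apply_qc_filters(qc$lfc, s$screen$counts, s$screen$sample_meta,
                          check_representation = FALSE)
  expect_equal(qc2$reports$noncutting$n_removed, 0L)
  expect_equal(qc2$reports$lethal_cutting$n_removed, 0L)
  expect_equal(nrow(qc2$lfc), nrow(qc$lfc))

  # wiping a gene out of the pDNA pool must raise a representation error
  counts_bad <- s$screen$counts
  gene_cons <- s$screen$constructs$construct_id[
    s$screen$constructs$sp_gene == "SLC25A1" |
      s$screen$constructs$sa_gene == "SLC25A1"]
  pdna_col <- s$screen$sample_meta$sample_id[
    s$screen$sample_meta$timepoint == "pDNA"]
  counts_bad[gene_cons, pdna_col] <- 0L
  lfc_bad <- compute_lfc(counts_bad, s$screen$sample_meta,
                         s$screen$constructs)
  expect_error(
    apply_qc_filters(lfc_bad, counts_bad, s$screen$sample_meta,
                     cutoff_rule = list(type = "absolute", value = 10)),
    "unrepresented")
})

test_that("orientation pooling: per-pair medians pool both construct orders", {
  phi <- c(A_g1 = -0.5, A_g2 = -0.4, B_g1 = 0.2, B_g2 = 0.1)
  psi <- c(A_h1 = -0.6, A_h2 = -0.3, B_h1 = 0.3, B_h2 = 0.0)
  tab <- toy_lfc_table(phi, psi, sp_gene = c("A", "A", "B", "B"),
                       sa_gene = c("A", "A", "B", "B"))
  comb <- combine_and_symmetrize(tab)
  ab <- comb[comb$gene_pair == "A|B"]
  # brute force: pool A x B and B x A orientations, then take the median
  vals <- c()
  df <- as.data.frame(tab)
  for (r in seq_len(nrow(df)))
    if ((df$sp_gene[r] == "A" && df$sa_gene[r] == "B") ||
        (df$sp_gene[r] == "B" && df$sa_gene[r] == "A"))
      vals <- c(vals, df$lfc[r])
  expect_equal(median(ab$lfc), median(vals))
  expect_equal(nrow(ab), 8L)  # 2x2 constructs in each orientation

  # stacking two identical batches leaves per-pair medians unchanged
  tab2 <- data.table::copy(tab); tab2$batch <- 2L
  comb2 <- combine_and_symmetrize(list(tab, tab2))
  ab2 <- comb2[comb2$gene_pair == "A|B"]
  expect_equal(median(ab2$lfc), median(vals))
})
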