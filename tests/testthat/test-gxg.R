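test_that("noiseless additive data is fitted exactly, up to the control gauge", {
  phi <- c(G1_g1 = -0.9, G1_g2 = -0.7, G2_g1 = 0.3, sp_c1 = 0.15,
           sp_c2 = -0.15)
  psi <- c(H1_h1 = -0.4, H1_h2 = -0.2, H2_h1 = 0.5, sa_c1 = 0.1,
           sa_c2 = -0.1)
  tab <- toy_lfc_table(
    phi, psi, alpha = 0.25,
    sp_category = c("target", "target", "target", "cutting_ctrl",
                    "cutting_ctrl"),
    sa_category = c("target", "target", "target", "cutting_ctrl",
                    "cutting_ctrl"),
    sp_gene = c("G1", "G1", "G2", "C1", "C2"),
    sa_gene = c("H1", "H1", "H2", "C1", "C2"))
  fit <- fit_additive_model(tab, "glucose")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$residuals)), 1e-6)
  # control guides average zero in each position (the gauge constraint)
  expect_equal(mean(fit$phi[c("sp_c1", "sp_c2")]), 0, tolerance = 1e-8)
  expect_equal(mean(fit$psi[c("sa_c1", "sa_c2")]), 0, tolerance = 1e-8)
  # parameters recovered after expressing truth in the same gauge
  expect_equal(unname(fit$phi["G1_g1"] - fit$phi["G1_g2"]),
               unname(phi["G1_g1"] - phi["G1_g2"]), tolerance = 1e-6)
  expect_equal(unname(fit$alpha),
               0.25 + mean(phi[c("sp_c1", "sp_c2")]) +
                 mean(psi[c("sa_c1", "sa_c2")]), tolerance = 1e-6)

  # gauge invariance: shifting every LFC by a constant moves only alpha
  tab2 <- data.table::copy(tab); tab2$lfc <- tab2$lfc + 1.3
  fit2 <- fit_additive_model(tab2, "glucose")
  expect_equal(fit2$phi, fit$phi, tolerance = 1e-6)
  expect_equal(fit2$psi, fit$psi, tolerance = 1e-6)
  expect_equal(unname(fit2$alpha - fit$alpha), 1.3, tolerance = 1e-6)
  expect_equal(fit2$residuals, fit$residuals, tolerance = 1e-6)
})

test_that("the L1 fit shrugs off a single outlier where least squares shifts", {
  phi <- c(G1_g1 = -0.6, G1_g2 = -0.5, G2_g1 = 0.2, G2_g2 = 0.1,
           sp_c1 = 0, sp_c2 = 0, sp_c3 = 0)
  psi <- c(H1_h1 = -0.3, H1_h2 = -0.1, H2_h1 = 0.4, H2_h2 = 0.2,
           sa_c1 = 0, sa_c2 = 0, sa_c3 = 0)
  cats_sp <- c(rep("target", 4), rep("cutting_ctrl", 3))
  cats_sa <- c(rep("target", 4), rep("cutting_ctrl", 3))
  tab <- toy_lfc_table(phi, psi,
                       sp_category = cats_sp, sa_category = cats_sa,
                       sp_gene = c("G1", "G1", "G2", "G2", "C1", "C2", "C3"),
                       sa_gene = c("H1", "H1", "H2", "H2", "C1", "C2", "C3"))
  # noiseless additive data: the exact L1 optimum interpolates every clean
  # construct and a lone outlier cannot move it
  fit_clean <- fit_additive_model(tab, "glucose")
  tab_out <- data.table::copy(tab)
  tab_out$lfc[1] <- tab_out$lfc[1] - 8  # one wild construct
  fit_out <- fit_additive_model(tab_out, "glucose")
  expect_lt(max(abs(fit_out$phi - fit_clean$phi)), 1e-3)
  expect_lt(max(abs(fit_out$psi - fit_clean$psi)), 1e-3)

  # a least-squares fit of the same model moves visibly
  ls_phi <- function(t) {
    df <- as.data.frame(t)
    coef(lm(lfc ~ sp_guide_id + sa_guide_id, data = df))
  }
  shift_ls <- max(abs(ls_phi(tab_out) - ls_phi(tab)), na.rm = TRUE)
  expect_gt(shift_ls, 0.05)
})

test_that("IRLS reaches the exact LP optimum on small instances", {
  for (seed in c(13, 27)) {
    d <- tiny_design(seed = seed, n_genes = 4, guides_per_gene = 2,
                     n_cutting = 4, n_noncutting = 0)
    p <- sim_params(n_batches = 1, conditions = "glucose",
                    pdna_depth = 300, endpoint_depth = 300)
    s <- small_screen(design = d, scenario = "paper_like", seed = seed,
                      params = p)
    fit <- fit_additive_model(s$lfc, "glucose")
    lp_obj <- lp_l1_objective(s$lfc[s$lfc$condition == "glucose"])
    expect_lt(abs(fit$objective - lp_obj), 1e-6)
    expect_gte(fit$objective, lp_obj - 1e-9)  # LP is the true optimum
  }
})

test_that("pi is the median residual per unordered pair; self-pairs are zero", {
  d <- tiny_design(seed = 17, n_genes = 4, guides_per_gene = 2,
                   n_cutting = 5, n_noncutting = 0)
  p <- sim_params(n_batches = 2, conditions = "glucose",
                  pdna_depth = 500, endpoint_depth = 500)
  s <- small_screen(design = d, scenario = "paper_like", seed = 3, params = p)
  fit <- fit_additive_model(s$lfc, "glucose")
  tab <- compute_pi_scores(fit)
  # brute-force check on one pair
  dat <- as.data.frame(fit$data)
  resid <- fit$residuals
  gp <- tab$gene_pair[!tab$self_pair][1]
  expect_equal(tab$pi[tab$gene_pair == gp],
               median(resid[dat$pair_class == "gene_gene" &
                              dat$gene_pair == gp]))
  expect_true(all(tab$pi[tab$self_pair] == 0))
  # symmetric by construction: single row per unordered pair
  expect_false(anyDuplicated(tab$gene_pair) > 0)
  # missing pairs recorded as NA, never silently dropped or zeroed
  tab2 <- compute_pi_scores(fit, all_pairs = c(tab$gene_pair, "ZZ1|ZZ2"))
  expect_true(is.na(tab2$pi[tab2$gene_pair == "ZZ1|ZZ2"]))
})

test_that("median-based pi tolerates any single guide-pair outlier", {
  d <- tiny_design(seed = 19, n_genes = 3, guides_per_gene = 3,
                   n_cutting = 4, n_noncutting = 0)
  p <- sim_params(n_batches = 1, conditions = "glucose",
                  pdna_depth = 800, endpoint_depth = 800)
  s <- small_screen(design = d, scenario = "null", seed = 5, params = p)
  fit <- fit_additive_model(s$lfc, "glucose")
  tab <- compute_pi_scores(fit)
  gp <- tab$gene_pair[!tab$self_pair & tab$n_guide_pairs >= 5][1]
  # corrupt one construct of that pair and refit nothing: pi barely moves
  lfc2 <- data.table::copy(s$lfc)
  row <- which(lfc2$gene_pair == gp & lfc2$pair_class == "gene_gene")[1]
  lfc2$lfc[row] <- lfc2$lfc[row] + 50
  fit2 <- fit_additive_model(lfc2, "glucose")
  tab2 <- compute_pi_scores(fit2)
  expect_lt(abs(tab2$pi[tab2$gene_pair == gp] -
                  tab$pi[tab$gene_pair == gp]), 0.2)
})

test_that("disabling shrinkage reduces the moderated test to a plain t-test", {
  set.seed(8)
  groups <- replicate(12, rnorm(5, 0.1, 0.3), simplify = FALSE)
  names(groups) <- sprintf("G%02d|H%02d", 1:12, 1:12)
  res <- moderated_significance(groups, shrink = FALSE)
  for (i in seq_along(groups)) {
    tt <- t.test(groups[[i]])
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(res$q, p.adjust(res$p, "BH"))

  # with shrinkage, variances move toward the pooled prior
  res_shrunk <- moderated_significance(groups, shrink = TRUE)
  expect_true(all(is.finite(res_shrunk$p)))
  # tiny groups are not testable
  res_na <- moderated_significance(c(groups, list(`A|B` = c(0.1, 0.2))))
  expect_true(is.na(res_na$p[res_na$gene_pair == "A|B"]))
})

test_that("an all-zero-residual pair ranks below noisy pairs in |moderated t|", {
  set.seed(9)
  groups <- replicate(10, rnorm(6, 0.5, 0.2), simplify = FALSE)
  names(groups) <- sprintf("N%02d|M%02d", 1:10, 1:10)
  groups[["Z1|Z2"]] <- rep(0, 6)
  # limma offsets the zero sample variance; that is the point of shrinkage
  res <- suppressWarnings(moderated_significance(groups, shrink = TRUE))
  t_zero <- abs(res$t[res$gene_pair == "Z1|Z2"])
  t_noisy <- abs(res$t[res$gene_pair != "Z1|Z2"])
  expect_lt(t_zero, median(t_noisy))
})
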