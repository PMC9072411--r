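#' Fit the constrained robust additive model for one condition
#'
#' Models the construct-level LFC as `C = alpha + phi[sp guide] +
#' psi[sa guide] + error` and estimates the parameters by minimizing the L1
#' norm of the residuals, subject to the identifiability constraint that the
#' cutting-control guide effects average zero in each position (controls are
#' the neutral reference). Minimization uses iteratively reweighted least
#' squares with weights `1 / max(|r|, eps)`; after each weighted solve the
#' control means are subtracted from phi and psi and absorbed into alpha, so
#' the constraint holds exactly at every iterate. Zero initialization makes
#' the fit deterministic. Batches enter as replicate observations.
#'
#' @param lfc A filtered, symmetrized `guide_lfc` table.
#' @param condition Condition to fit.
#' @param eps Weight regularizer (default 1e-4).
#' @param tol Convergence threshold on the max parameter change (default
#'   1e-6).
#' @param max_iter Iteration cap (default 200).
#' @param ridge Tiny ridge stabilizing the (gauge-fixed) normal equations.
#' @return List of class `additive_fit`: `alpha`, `phi` (named per Sp guide),
#'   `psi` (named per Sa guide), `residuals` + the fitted rows (`data`),
#'   `converged`, `iterations`, `objective` (final L1 objective),
#'   `objective_trace`.
#' @export
fit_additive_model <- function(lfc, condition, eps = 1e-4, tol = 1e-6,
                               max_iter = 200L, ridge = 1e-8) {
  in_cond <- lfc$condition == condition
  dat <- lfc[in_cond]
  if (nrow(dat) == 0) stop("condition not present: ", condition)
  y <- dat$lfc
  sp_lev <- sort(unique(dat$sp_guide_id))
  sa_lev <- sort(unique(dat$sa_guide_id))
  i_sp <- match(dat$sp_guide_id, sp_lev)
  i_sa <- match(dat$sa_guide_id, sa_lev)
  n <- length(y); P <- length(sp_lev); Q <- length(sa_lev)
  X <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 3),
    j = c(rep(1L, n), 1L + i_sp, 1L + P + i_sa),
    x = 1, dims = c(n, 1L + P + Q))
  sp_ctrl <- which(sp_lev %in% dat$sp_guide_id[dat$sp_category == "cutting_ctrl"])
  sa_ctrl <- which(sa_lev %in% dat$sa_guide_id[dat$sa_category == "cutting_ctrl"])
  if (length(sp_ctrl) == 0) sp_ctrl <- seq_len(P)  # fall back: centre over all
  if (length(sa_ctrl) == 0) sa_ctrl <- seq_len(Q)

  recenter <- function(beta) {
    m_sp <- mean(beta[1L + sp_ctrl]); m_sa <- mean(beta[1L + P + sa_ctrl])
    beta[2:(1L + P)] <- beta[2:(1L + P)] - m_sp
    beta[(2L + P):(1L + P + Q)] <- beta[(2L + P):(1L + P + Q)] - m_sa
    beta[1] <- beta[1] + m_sp + m_sa
    beta
  }

  beta <- numeric(1L + P + Q)
  obj <- sum(abs(y))
  trace <- obj
  converged <- FALSE
  iter <- 0L
  I_ridge <- ridge * Matrix::Diagonal(1L + P + Q)
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - as.vector(X %*% beta)
    w <- 1 / pmax(abs(r), eps)
    A <- Matrix::crossprod(X, Matrix::Diagonal(x = w) %*% X) + I_ridge
    b <- Matrix::crossprod(X, w * y)
    beta_new <- recenter(as.vector(Matrix::solve(A, b)))
    obj_new <- sum(abs(y - as.vector(X %*% beta_new)))
    if (obj_new > obj + 1e-12) {
      # keep the better iterate; an essentially flat objective is a plateau
      # of the L1 surface, i.e. convergence
      converged <- obj_new - obj < 1e-8 * (1 + abs(obj))
      break
    }
    delta <- max(abs(beta_new - beta))
    improve <- obj - obj_new
    beta <- beta_new; obj <- obj_new; trace <- c(trace, obj)
    if (delta < tol || improve < 1e-10 * (1 + abs(obj))) {
      converged <- TRUE; break
    }
  }
  if (!converged)
    warning("additive model did not converge in ", iter, " iterations")
  resid <- y - as.vector(X %*% beta)
  structure(list(alpha = beta[1],
                 phi = setNames(beta[2:(1L + P)], sp_lev),
                 psi = setNames(beta[(2L + P):(1L + P + Q)], sa_lev),
                 residuals = resid, data = dat, condition = condition,
                 converged = converged, iterations = iter,
                 objective = obj, objective_trace = trace),
            class = "additive_fit")
}

#' @export
print.additive_fit <- function(x, ...) {
  cat(sprintf("additive_fit (%s): %d obs, %d+%d guide effects, L1 objective %.4g, %s in %d iter\n",
              x$condition, length(x$residuals), length(x$phi), length(x$psi),
              x$objective, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Pairwise interaction pi-scores from an additive fit
#'
#' For every unordered pair of distinct scored genes, pi is the median over
#' all guide pairs (both orientations, all batches) of the residual
#' `C - alpha - phi - psi`. Self-pairs are set to 0 by definition. Pairs with
#' no surviving guide pairs are recorded with `pi = NA` (missing, not 0) when
#' the full pair universe is supplied.
#'
#' @param fit An `additive_fit`.
#' @param all_pairs Optional character vector of expected pair keys
#'   (`"A|B"`); defaults to the pairs present in the fitted data.
#' @return A `data.table` of class `pi_table`: gene_pair, condition, pi,
#'   n_guide_pairs, self_pair.
#' @export
compute_pi_scores <- function(fit, all_pairs = NULL) {
  dat <- fit$data
  scored <- dat$pair_class == "gene_gene"
  dd <- dat[scored]
  res <- fit$residuals[scored]
  selfp <- dd$sp_gene == dd$sa_gene
  grp <- data.table::data.table(gene_pair = dd$gene_pair, resid = res,
                                self_pair = selfp)
  tab <- grp[, list(pi = median(resid), n_guide_pairs = .N,
                    self_pair = self_pair[1]),
             by = "gene_pair"]
  tab$pi[tab$self_pair] <- 0
  if (!is.null(all_pairs)) {
    miss <- setdiff(all_pairs, tab$gene_pair)
    if (length(miss))
      tab <- rbind(tab, data.table::data.table(
        gene_pair = miss, pi = NA_real_, n_guide_pairs = 0L,
        self_pair = vapply(strsplit(miss, "|", fixed = TRUE),
                           function(x) x[1] == x[2], logical(1))))
  }
  tab$condition <- fit$condition
  tab <- tab[order(tab$gene_pair)]
  data.table::setattr(tab, "class", c("pi_table", class(tab)))
  res_groups <- split(res[!selfp], grp$gene_pair[!selfp])
  data.table::setattr(tab, "residual_groups", res_groups)
  tab[]
}

#' Moderated guide-level significance for pi-scores
#'
#' One-sample test of mean residual != 0 per gene pair, using
#' empirical-Bayes variance moderation across pairs (prior df and scale
#' estimated from the distribution of sample variances; `limma`'s shrinkage)
#' and Benjamini-Hochberg correction across the pairs of a condition. Pairs
#' with fewer than 3 guide-level residuals get `p = NA`.
#'
#' @param residual_groups Named list of per-pair guide-level residual
#'   vectors.
#' @param shrink With `FALSE`, no shrinkage (prior df 0): an ordinary
#'   one-sample t-test.
#' @return data.table gene_pair, n, mean_resid, t, df, p, q.
#' @export
moderated_significance <- function(residual_groups, shrink = TRUE) {
  n <- vapply(residual_groups, length, integer(1))
  m <- vapply(residual_groups, mean, numeric(1))
  v <- vapply(residual_groups, function(x) if (length(x) >= 2) var(x) else NA_real_,
              numeric(1))
  ok <- n >= 3L
  t_stat <- df_tot <- p <- rep(NA_real_, length(n))
  if (any(ok)) {
    if (shrink) {
      sq <- limma::squeezeVar(v[ok], df = n[ok] - 1L)
      s2 <- sq$var.post
      df_prior <- sq$df.prior
    } else {
      s2 <- v[ok]
      df_prior <- 0
    }
    t_stat[ok] <- m[ok] / sqrt(s2 / n[ok])
    df_tot[ok] <- pmin(n[ok] - 1L + df_prior, 1e6)
    p[ok] <- 2 * pt(-abs(t_stat[ok]), df_tot[ok])
  }
  out <- data.table::data.table(gene_pair = names(residual_groups), n = n,
                                mean_resid = m, t = t_stat, df = df_tot, p = p)
  out$q <- NA_real_
  out$q[!is.na(out$p)] <- p.adjust(out$p[!is.na(out$p)], method = "BH")
  out[]
}

#' Score pairwise genetic interactions for one or more conditions
#'
#' Convenience wrapper: fits the additive model per condition, computes
#' pi-scores and attaches moderated p/q-values and single-knockout LFC
#' summaries for both genes of each pair.
#'
#' @param lfc A filtered, symmetrized `guide_lfc` table.
#' @param conditions Conditions to score (default: all present).
#' @param all_pairs Optional expected pair universe (`"A|B"` keys).
#' @param shrink Variance moderation toggle; see
#'   [moderated_significance()].
#' @param ... Passed to [fit_additive_model()].
#' @return List: `pi` (a `pi_table` with p and q columns, all conditions
#'   stacked), `fits` (per-condition `additive_fit`s).
#' @export
score_interactions <- function(lfc, conditions = NULL, all_pairs = NULL,
                               shrink = TRUE, ...) {
  if (is.null(conditions)) conditions <- sort(unique(lfc$condition))
  single_ko <- single_ko_summary(lfc)
  fits <- list(); tabs <- list()
  for (cc in conditions) {
    fit <- fit_additive_model(lfc, cc, ...)
    tab <- compute_pi_scores(fit, all_pairs)
    sig <- moderated_significance(attr(tab, "residual_groups"), shrink = shrink)
    tab <- merge(tab, sig[, c("gene_pair", "n", "t", "p", "q")],
                 by = "gene_pair", all.x = TRUE, sort = TRUE)
    g <- strsplit(tab$gene_pair, "|", fixed = TRUE)
    sk <- setNames(single_ko$median_lfc,
                   paste(single_ko$gene, single_ko$condition, sep = "."))
    tab$lfc_gene_a <- unname(sk[paste(vapply(g, `[`, "", 1), cc, sep = ".")])
    tab$lfc_gene_b <- unname(sk[paste(vapply(g, `[`, "", 2), cc, sep = ".")])
    fits[[cc]] <- fit
    tabs[[cc]] <- tab
  }
  pi_all <- data.table::rbindlist(tabs)
  data.table::setattr(pi_all, "class", c("pi_table", class(pi_all)))
  list(pi = pi_all[], fits = fits)
}

#' Per-gene single-knockout LFC summaries
#'
#' Median LFC of a gene's guide x cutting-control constructs (both
#' orientations pooled) per condition — the gene's single-knockout effect
#' size used by the interaction curation rules.
#'
#' @param lfc A `guide_lfc` table.
#' @return data.table gene, condition, median_lfc, n.
#' @export
single_ko_summary <- function(lfc) {
  scored <- c("target", "positive_ctrl")
  sp_sel <- lfc$sp_category %in% scored & lfc$sa_category == "cutting_ctrl"
  sa_sel <- lfc$sa_category %in% scored & lfc$sp_category == "cutting_ctrl"
  sp <- lfc[sp_sel, c("sp_gene", "condition", "lfc")]
  data.table::setnames(sp, "sp_gene", "gene")
  sa <- lfc[sa_sel, c("sa_gene", "condition", "lfc")]
  data.table::setnames(sa, "sa_gene", "gene")
  both <- rbind(sp, sa)
  both[, list(median_lfc = median(lfc), n = .N), by = c("gene", "condition")]
}
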