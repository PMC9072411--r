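#' Single-knockout z-scores against the control-control null
#'
#' Restricts to constructs where exactly one position carries a scored gene
#' and the other a cutting control (single knockouts), plus the cutting
#' control-control constructs themselves (the null). Within each condition
#' and batch, z = (LFC - mean of ctrl-ctrl LFC) / sd of ctrl-ctrl LFC, so the
#' null has mean 0 and sd 1 by construction; this corrects for growth-rate
#' differences between conditions.
#'
#' @param lfc A filtered, symmetrized `guide_lfc` table.
#' @param robust Use median/MAD instead of mean/sd for the null location and
#'   scale.
#' @param min_ctrl Minimum ctrl-ctrl constructs required per condition
#'   (default 10).
#' @return A `data.table` of class `single_ko` with columns gene, guide_id,
#'   position (`sp`/`sa`), condition, batch, lfc, z and `is_ctrl`
#'   (ctrl-ctrl null rows, gene `NA`).
#' @export
zscore_vs_ctrl <- function(lfc, robust = FALSE, min_ctrl = 10L) {
  scored <- c("target", "positive_ctrl")
  sp_single <- lfc$sp_category %in% scored & lfc$sa_category == "cutting_ctrl"
  sa_single <- lfc$sa_category %in% scored & lfc$sp_category == "cutting_ctrl"
  cc <- lfc$sp_category == "cutting_ctrl" & lfc$sa_category == "cutting_ctrl"

  rows <- data.table::rbindlist(list(
    data.table::data.table(
      gene = lfc$sp_gene[sp_single], guide_id = lfc$sp_guide_id[sp_single],
      position = "sp", condition = lfc$condition[sp_single],
      batch = lfc$batch[sp_single], lfc = lfc$lfc[sp_single], is_ctrl = FALSE),
    data.table::data.table(
      gene = lfc$sa_gene[sa_single], guide_id = lfc$sa_guide_id[sa_single],
      position = "sa", condition = lfc$condition[sa_single],
      batch = lfc$batch[sa_single], lfc = lfc$lfc[sa_single], is_ctrl = FALSE),
    data.table::data.table(
      gene = NA_character_, guide_id = NA_character_, position = "cc",
      condition = lfc$condition[cc], batch = lfc$batch[cc],
      lfc = lfc$lfc[cc], is_ctrl = TRUE)))

  loc <- if (robust) median else mean
  scl <- if (robust) stats::mad else sd
  null_stats <- rows[rows$is_ctrl == TRUE,
                     list(mu = loc(lfc), sigma = scl(lfc), n_ctrl = .N),
                     by = c("condition", "batch")]
  if (any(null_stats$n_ctrl < min_ctrl))
    stop("fewer than ", min_ctrl, " ctrl-ctrl constructs in some condition")
  if (any(null_stats$sigma == 0))
    stop("ctrl-ctrl LFC sd is zero in some condition")
  res <- merge(rows, null_stats, by = c("condition", "batch"), sort = FALSE)
  res$z <- (res$lfc - res$mu) / res$sigma
  res[, c("mu", "sigma", "n_ctrl") := NULL]
  data.table::setattr(res, "class", c("single_ko", class(res)))
  res[]
}

#' Gene-by-environment regression on single-knockout z-scores
#'
#' Fits the linear model `z ~ gene + gene:condition` on the single-knockout
#' rows: per-gene main effects (fitness in the reference condition) and
#' per-gene, per-non-reference-condition interaction coefficients. Wald
#' p-values on the interaction terms are corrected across all gene x
#' condition terms with Benjamini-Hochberg.
#'
#' @param table A `single_ko` table from [zscore_vs_ctrl()].
#' @param reference_condition Condition used as regression baseline; default
#'   the first condition alphabetically unless given.
#' @return List of class `gxe_result`: `interactions` (data.table gene,
#'   condition, estimate, se, p, q), `main_effects` (gene, estimate),
#'   `reference_condition`, `model` (the `lm` fit).
#' @export
fit_gxe <- function(table, reference_condition = NULL) {
  dat <- table[table$is_ctrl == FALSE]
  conds <- sort(unique(dat$condition))
  if (length(conds) < 2)
    stop("gene-by-environment regression needs at least 2 conditions")
  obs <- unique(dat[, c("gene", "condition")])
  under <- names(which(table(obs$gene) < 2))
  if (length(under))
    stop("genes observed in fewer than 2 conditions: ",
         paste(under, collapse = ", "))
  if (is.null(reference_condition)) reference_condition <- conds[1]
  stopifnot(reference_condition %in% conds)
  dat$gene <- factor(dat$gene)
  dat$condition <- stats::relevel(factor(dat$condition), reference_condition)
  fit <- lm(z ~ 0 + gene + gene:condition, data = dat)
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient gene-by-environment design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  is_int <- grepl(":condition", rownames(cf))
  ints <- data.table::data.table(
    gene = sub("^gene([^:]*):.*$", "\\1", rownames(cf)[is_int]),
    condition = sub("^.*:condition", "", rownames(cf)[is_int]),
    estimate = cf[is_int, 1], se = cf[is_int, 2], p = cf[is_int, 4])
  ints$q <- p.adjust(ints$p, method = "BH")
  mains <- data.table::data.table(
    gene = sub("^gene", "", rownames(cf)[!is_int]),
    estimate = cf[!is_int, 1])
  structure(list(interactions = ints[], main_effects = mains[],
                 reference_condition = reference_condition, model = fit),
            class = "gxe_result")
}

#' Call gene-by-environment hits
#'
#' Interaction terms with q below `q_max` and an absolute coefficient of at
#' least `min_delta_z` (z-score units), ordered by q then absolute effect.
#'
#' @param result A `gxe_result`.
#' @param q_max BH q-value ceiling (default 0.05).
#' @param min_delta_z Minimum |interaction coefficient| (default 1).
#' @return data.table of hits (possibly empty), deterministic ordering.
#' @export
call_gxe_hits <- function(result, q_max = 0.05, min_delta_z = 1) {
  ints <- result$interactions
  hits <- ints[ints$q <= q_max & abs(ints$estimate) >= min_delta_z]
  hits[order(hits$q, -abs(hits$estimate), hits$gene, hits$condition)]
}
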