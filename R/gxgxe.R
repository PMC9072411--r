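#' Z-transform pi-scores within each condition
#'
#' Standardizes pi across all tested pairs within a condition, z = (pi -
#' mean(pi)) / sd(pi), correcting for growth-rate differences between
#' conditions that blunt pi-scores in slow-growing media. Reporting-only; the
#' curation rules below always act on raw pi.
#'
#' @param pi_table A `pi_table` (stacked conditions).
#' @return The table with a `pi_z` column added.
#' @export
z_transform_pi <- function(pi_table) {
  out <- data.table::copy(pi_table)
  out$pi_z <- NA_real_
  for (cc in unique(out$condition)) {
    idx <- out$condition == cc & !is.na(out$pi)
    if (sum(idx) < 2) stop("need at least 2 pi values in condition ", cc)
    s <- sd(out$pi[idx])
    if (s == 0) stop("pi-scores are degenerate (sd = 0) in condition ", cc)
    out$pi_z[idx] <- (out$pi[idx] - mean(out$pi[idx])) / s
  }
  out[]
}

#' Curate condition-dependent genetic interactions
#'
#' Candidate pairs are those significant (q < `fdr_max`) in at least one
#' condition. Candidates are then disqualified, in order, when they match:
#' \describe{
#'   \item{small_effect}{|pi| < `pi_min` in every condition.}
#'   \item{ceiling}{in some condition where the pair is significant, both
#'     genes have positive single-knockout effect sizes and pi is negative —
#'     the double knockout likely hit a growth ceiling.}
#'   \item{deader_than_dead}{both genes have strongly negative
#'     single-knockout effect sizes (LFC < `dead_lfc`) and pi is positive
#'     across all conditions — fitness cannot drop below dead.}
#' }
#' The first matching rule is the recorded reason; every candidate is
#' returned with its verdict. Verdicts are a pure function of (pi, q,
#' single-knockout LFC, params).
#'
#' @param pi_table A `pi_table` with q-values and `lfc_gene_a`/`lfc_gene_b`
#'   single-knockout summaries (as produced by [score_interactions()]).
#' @param params List: `fdr_max` (default 0.02), `pi_min` (0.25), `dead_lfc`
#'   (-0.75).
#' @return data.table of class `gxgxe_hits`: gene_pair, verdict
#'   (`retained`/`disqualified`), reason, flags, per-condition pi and q in
#'   list columns `pi_by_cond`, `q_by_cond`.
#' @export
filter_interactions <- function(pi_table,
                                params = list(fdr_max = 0.02, pi_min = 0.25,
                                              dead_lfc = -0.75)) {
  fdr_max <- params$fdr_max %||% 0.02
  pi_min <- params$pi_min %||% 0.25
  dead_lfc <- params$dead_lfc %||% -0.75
  tab <- pi_table[pi_table$self_pair == FALSE & !is.na(pi_table$pi)]
  if (any(is.na(tab$lfc_gene_a) | is.na(tab$lfc_gene_b)))
    stop("missing single-knockout summary for a gene in the pi table")
  out <- list()
  for (gp in sort(unique(tab$gene_pair))) {
    rows <- tab[tab$gene_pair == gp]
    sig <- !is.na(rows$q) & rows$q < fdr_max
    if (!any(sig)) next
    small <- all(abs(rows$pi) < pi_min)
    ceiling_flag <- any(sig & rows$lfc_gene_a > 0 & rows$lfc_gene_b > 0 &
                          rows$pi < 0)
    deader <- all(rows$lfc_gene_a < dead_lfc & rows$lfc_gene_b < dead_lfc &
                    rows$pi > 0)
    reason <- if (small) "small_effect"
              else if (ceiling_flag) "ceiling"
              else if (deader) "deader_than_dead"
              else NA_character_
    out[[gp]] <- data.table::data.table(
      gene_pair = gp,
      verdict = if (is.na(reason)) "retained" else "disqualified",
      reason = reason,
      small_effect = small, ceiling = ceiling_flag,
      deader_than_dead = deader,
      min_q = min(rows$q, na.rm = TRUE),
      pi_by_cond = list(setNames(rows$pi, rows$condition)),
      q_by_cond = list(setNames(rows$q, rows$condition)))
  }
  res <- if (length(out)) data.table::rbindlist(out)
         else data.table::data.table(
           gene_pair = character(0), verdict = character(0),
           reason = character(0), small_effect = logical(0),
           ceiling = logical(0), deader_than_dead = logical(0),
           min_q = numeric(0), pi_by_cond = list(), q_by_cond = list())
  data.table::setattr(res, "class", c("gxgxe_hits", class(res)))
  res[]
}
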