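#' Construct-level log2 fold changes versus the plasmid baseline
#'
#' For every endpoint sample, LFC = log2(freq_condition * 1e6 + 1) -
#' log2(freq_pDNA * 1e6 + 1), where freq is the construct's count divided by
#' the sample's column total and the pDNA reference is the same batch's
#' plasmid sample. The +1 pseudo-count keeps zero counts finite.
#'
#' @param counts Integer matrix constructs x samples.
#' @param sample_meta data.frame sample_id, condition, batch, timepoint
#'   (timepoint `"pDNA"` marks the baseline; exactly one per batch).
#' @param constructs Construct annotations from [enumerate_constructs()].
#' @return A `data.table` of class `guide_lfc` in long form: construct_id,
#'   sp_guide_id, sa_guide_id, sp_gene, sa_gene, sp_category, sa_category,
#'   gene_pair, pair_class, condition, batch, lfc.
#' @export
compute_lfc <- function(counts, sample_meta, constructs) {
  stopifnot(all(colSums(counts) > 0))
  stopifnot(all(sample_meta$sample_id %in% colnames(counts)))
  pdna <- sample_meta[sample_meta$timepoint == "pDNA", ]
  if (anyDuplicated(pdna$batch) || !all(sample_meta$batch %in% pdna$batch))
    stop("each batch needs exactly one pDNA sample")
  cpm1 <- function(x) log2(x / sum(x) * 1e6 + 1)
  ends <- sample_meta[sample_meta$timepoint != "pDNA", ]
  out <- lapply(seq_len(nrow(ends)), function(s) {
    ref <- pdna$sample_id[match(ends$batch[s], pdna$batch)]
    lfc <- cpm1(counts[, ends$sample_id[s]]) - cpm1(counts[, ref])
    dt <- data.table::as.data.table(
      constructs[match(rownames(counts), constructs$construct_id), ])
    dt[, `:=`(condition = ends$condition[s], batch = ends$batch[s],
              lfc = unname(lfc))]
    dt
  })
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "class", c("guide_lfc", class(res)))
  res[]
}

filter_report <- function(step, lfc, removed_constructs, details = list()) {
  structure(list(step = step,
                 removed_constructs = sort(unique(removed_constructs)),
                 n_removed = length(unique(removed_constructs)),
                 n_surviving = length(setdiff(unique(lfc$construct_id),
                                             removed_constructs)),
                 details = details),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter '%s': removed %d constructs, %d surviving\n",
              x$step, x$n_removed, x$n_surviving))
  invisible(x)
}

apply_removal <- function(lfc, removed) {
  keep <- !lfc$construct_id %in% removed
  lfc[keep]
}

#' QC step 1: filter constructs poorly represented in the plasmid pool
#'
#' Removes guide-guide pairs whose pDNA read count falls below an empirical
#' cutoff in any batch, and additionally removes every pair containing an
#' individual guide whose median pDNA read count is below the cutoff.
#'
#' @param lfc A `guide_lfc` table.
#' @param counts The count matrix the LFCs came from.
#' @param sample_meta Its sample metadata.
#' @param cutoff_rule Either `list(type = "quantile", q = 0.01)` (cutoff =
#'   that quantile of each batch's pDNA counts) or
#'   `list(type = "absolute", value = <count>)`.
#' @return List: `lfc` (filtered), `report` (a `filter_report`; details carry
#'   the cutoffs and the low-median guides).
#' @export
filter_low_pdna <- function(lfc, counts, sample_meta,
                            cutoff_rule = list(type = "quantile", q = 0.01)) {
  pdna <- sample_meta[sample_meta$timepoint == "pDNA", ]
  cons_ids <- unique(lfc$construct_id)
  removed <- character(0); low_guides <- character(0); cutoffs <- numeric(0)
  for (b in seq_len(nrow(pdna))) {
    pc <- counts[, pdna$sample_id[b]]
    cutoff <- switch(cutoff_rule$type,
      quantile = unname(quantile(pc, cutoff_rule$q)),
      absolute = cutoff_rule$value,
      stop("unknown cutoff rule type: ", cutoff_rule$type))
    cutoffs[pdna$sample_id[b]] <- cutoff
    low_pair <- names(pc)[pc < cutoff]
    removed <- union(removed, intersect(low_pair, cons_ids))
    # per-guide median over that guide's constructs, each position separately
    first <- !duplicated(lfc$construct_id)
    ann <- lfc[first, c("construct_id", "sp_guide_id", "sa_guide_id")]
    pck <- pc[ann$construct_id]
    for (col in c("sp_guide_id", "sa_guide_id")) {
      med <- tapply(pck, ann[[col]], median)
      bad <- names(med)[med < cutoff]
      low_guides <- union(low_guides, bad)
      removed <- union(removed,
                       ann$construct_id[ann[[col]] %in% bad])
    }
  }
  list(lfc = apply_removal(lfc, removed),
       report = filter_report("low_pdna", lfc, removed,
                              list(cutoffs = cutoffs,
                                   low_median_guides = low_guides)))
}

#' QC step 2: drop constructs carrying a non-cutting control guide
#'
#' Cells with non-cutting controls escape double-strand-break burden and grow
#' better than the population mean, biasing them as a neutral reference; every
#' construct with a non-cutting guide in either position is removed. On the
#' default design this removes 8x273 + 273x8 - 8x8 = 4,304 constructs.
#'
#' @param lfc A `guide_lfc` table.
#' @return List: `lfc`, `report`.
#' @export
filter_noncutting <- function(lfc) {
  bad <- lfc$sp_category == "noncutting_ctrl" |
         lfc$sa_category == "noncutting_ctrl"
  removed <- unique(lfc$construct_id[bad])
  list(lfc = apply_removal(lfc, removed),
       report = filter_report("noncutting", lfc, removed))
}

#' QC step 3: drop cutting-control guides with lethal single-gene phenotypes
#'
#' A cutting control should be neutral; a control guide whose control-control
#' constructs have a median LFC more than `z_threshold` robust standard
#' deviations below the centre of the control-control LFC distribution
#' (median/MAD, pooled over conditions and batches; robust so the lethal
#' constructs cannot mask themselves by inflating the scale) is treated as
#' lethal, and every pair containing it is removed.
#'
#' @param lfc A `guide_lfc` table.
#' @param z_threshold Flagging threshold in robust SD units (default -3).
#' @return List: `lfc`, `report` (details carry the flagged guide ids).
#' @export
filter_lethal_cutting_controls <- function(lfc, z_threshold = -3) {
  is_cc <- lfc$pair_class == "ctrl_ctrl" &
    lfc$sp_category == "cutting_ctrl" &
    lfc$sa_category == "cutting_ctrl"
  cc <- lfc[is_cc]
  if (nrow(cc) == 0)
    return(list(lfc = lfc, report = filter_report("lethal_cutting", lfc,
                                                  character(0))))
  mu <- median(cc$lfc); sdv <- stats::mad(cc$lfc)
  flagged <- character(0)
  if (sdv > 0) for (col in c("sp_guide_id", "sa_guide_id")) {
    med <- tapply(cc$lfc, cc[[col]], median)
    flagged <- union(flagged, names(med)[(med - mu) / sdv < z_threshold])
  }
  removed <- unique(lfc$construct_id[lfc$sp_guide_id %in% flagged |
                                     lfc$sa_guide_id %in% flagged])
  list(lfc = apply_removal(lfc, removed),
       report = filter_report("lethal_cutting", lfc, removed,
                              list(flagged_guides = flagged)))
}

#' QC step 4: drop guides that do not correlate with their gene's guides
#'
#' For each scored gene in each batch, every guide of the gene (both Cas9
#' positions) gets a profile: its LFCs paired with cutting controls, indexed
#' by (condition, control slot) so profiles are comparable across positions.
#' The Pearson correlation matrix among the gene's guides is computed; a
#' guide whose row sum (self term excluded) is negative is marked poor, and
#' every pair containing a guide marked poor in any batch is removed.
#'
#' @param lfc A `guide_lfc` table (after the control filters).
#' @param profile One of `"cutting_ctrl"` (default; single-knockout-style
#'   profile against cutting-control partners) or `"all"` (profile over all
#'   partner guides).
#' @return List: `lfc`, `report` (details: poor guides per batch and union).
#' @export
filter_uncorrelated_guides <- function(lfc, profile = c("cutting_ctrl", "all")) {
  profile <- match.arg(profile)
  genes <- sort(unique(c(lfc$sp_gene[lfc$sp_category %in% c("target", "positive_ctrl")],
                         lfc$sa_gene[lfc$sa_category %in% c("target", "positive_ctrl")])))
  poor_by_batch <- list()
  for (b in sort(unique(lfc$batch))) {
    in_b <- lfc$batch == b
    lb <- lfc[in_b]
    poor <- character(0)
    for (g in genes) {
      prof <- guide_profiles(lb, g, profile)
      if (ncol(prof) < 2) {
        warning("gene ", g, " has fewer than 2 guides with profiles; skipped")
        next
      }
      cm <- suppressWarnings(cor(prof, use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      rowsum_excl <- rowSums(cm) - diag(cm)
      poor <- union(poor, colnames(prof)[rowsum_excl < 0])
    }
    poor_by_batch[[as.character(b)]] <- poor
  }
  poor_all <- unique(unlist(poor_by_batch))
  removed <- unique(lfc$construct_id[lfc$sp_guide_id %in% poor_all |
                                     lfc$sa_guide_id %in% poor_all])
  list(lfc = apply_removal(lfc, removed),
       report = filter_report("uncorrelated_guides", lfc, removed,
                              list(poor_by_batch = poor_by_batch,
                                   poor_guides = poor_all)))
}

# Profile matrix for gene g: rows = (condition, partner slot), one column per
# guide of the gene in either position. Partner slots align cutting controls
# across positions by their within-position order.
guide_profiles <- function(lb, g, profile) {
  take_sp <- lb[lb$sp_gene == g &
                (if (profile == "cutting_ctrl") lb$sa_category == "cutting_ctrl"
                 else lb$sa_gene != g)]
  take_sa <- lb[lb$sa_gene == g &
                (if (profile == "cutting_ctrl") lb$sp_category == "cutting_ctrl"
                 else lb$sp_gene != g)]
  slot <- function(ids) as.integer(factor(ids, levels = sort(unique(ids))))
  cols <- list()
  if (nrow(take_sp) > 0) {
    take_sp$slot <- slot(take_sp$sa_guide_id)
    for (gid in unique(take_sp$sp_guide_id)) {
      x <- take_sp[take_sp$sp_guide_id == gid]
      cols[[gid]] <- setNames(x$lfc, paste(x$condition, x$slot, sep = "."))
    }
  }
  if (nrow(take_sa) > 0) {
    take_sa$slot <- slot(take_sa$sp_guide_id)
    for (gid in unique(take_sa$sa_guide_id)) {
      x <- take_sa[take_sa$sa_guide_id == gid]
      cols[[gid]] <- setNames(x$lfc, paste(x$condition, x$slot, sep = "."))
    }
  }
  keys <- sort(unique(unlist(lapply(cols, names))))
  prof <- vapply(cols, function(v) unname(v[keys]), numeric(length(keys)))
  if (is.null(dim(prof))) prof <- matrix(prof, ncol = length(cols),
                                         dimnames = list(NULL, names(cols)))
  prof
}

#' Run the four-step QC filter cascade in order
#'
#' Steps: low pDNA representation, non-cutting controls, lethal cutting
#' controls, uncorrelated guides. Removals are disjointly attributed to the
#' first applicable step. After filtering, it is confirmed that no scored
#' gene or scored gene pair became unrepresented (error otherwise, unless
#' `check_representation = FALSE`).
#'
#' @param lfc A `guide_lfc` table.
#' @param counts,sample_meta The count matrix and metadata for step 1.
#' @param cutoff_rule Step-1 cutoff rule; see [filter_low_pdna()].
#' @param z_threshold Step-3 threshold.
#' @param profile Step-4 profile definition.
#' @param check_representation Verify gene/pair coverage after filtering.
#' @return List: `lfc` (filtered), `reports` (list of `filter_report`s).
#' @export
apply_qc_filters <- function(lfc, counts, sample_meta,
                             cutoff_rule = list(type = "quantile", q = 0.01),
                             z_threshold = -3,
                             profile = "cutting_ctrl",
                             check_representation = TRUE) {
  s1 <- filter_low_pdna(lfc, counts, sample_meta, cutoff_rule)
  s2 <- filter_noncutting(s1$lfc)
  s3 <- filter_lethal_cutting_controls(s2$lfc, z_threshold)
  s4 <- filter_uncorrelated_guides(s3$lfc, profile)
  out <- s4$lfc
  if (check_representation) {
    genes <- sort(unique(c(out$sp_gene[out$sp_category %in% c("target", "positive_ctrl")],
                           out$sa_gene[out$sa_category %in% c("target", "positive_ctrl")])))
    before <- sort(unique(c(lfc$sp_gene[lfc$sp_category %in% c("target", "positive_ctrl")],
                            lfc$sa_gene[lfc$sa_category %in% c("target", "positive_ctrl")])))
    lost_genes <- setdiff(before, genes)
    # self-pairs are excluded: their interaction score is 0 by definition
    pairs_before <- unique(lfc$gene_pair[lfc$pair_class == "gene_gene" &
                                           lfc$sp_gene != lfc$sa_gene])
    pairs_after <- unique(out$gene_pair[out$pair_class == "gene_gene" &
                                          out$sp_gene != out$sa_gene])
    lost_pairs <- setdiff(pairs_before, pairs_after)
    if (length(lost_genes) || length(lost_pairs))
      stop("filtering left genes/pairs unrepresented: ",
           paste(c(lost_genes, head(lost_pairs, 5)), collapse = ", "))
  }
  list(lfc = out, reports = list(low_pdna = s1$report, noncutting = s2$report,
                                 lethal_cutting = s3$report,
                                 uncorrelated = s4$report))
}

#' Stack batches and attach the unordered gene-pair key
#'
#' Batches are retained as replicate observations (never averaged) and each
#' construct carries its unordered `gene_pair` key, so downstream medians
#' pool the GeneA x GeneB and GeneB x GeneA orientations.
#'
#' @param lfc_batches A single `guide_lfc` table or a list of per-batch
#'   tables sharing the construct universe.
#' @return A combined `guide_lfc` table.
#' @export
combine_and_symmetrize <- function(lfc_batches) {
  if (inherits(lfc_batches, "guide_lfc")) lfc_batches <- list(lfc_batches)
  universe <- Reduce(intersect, lapply(lfc_batches,
                                       function(x) unique(x$construct_id)))
  if (length(universe) == 0) stop("batches share no constructs")
  res <- data.table::rbindlist(lfc_batches)
  res$gene_pair <- pair_key(res$sp_gene, res$sa_gene)
  data.table::setattr(res, "class", c("guide_lfc", class(res)))
  res[]
}
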