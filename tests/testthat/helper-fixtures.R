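# Shared fixtures, all generated in code at test time.

tiny_design <- function(seed = 5, n_genes = 4, guides_per_gene = 2,
                        n_cutting = 4, n_noncutting = 2,
                        positive_genes = character(0)) {
  build_design(n_target_genes = n_genes, guides_per_gene = guides_per_gene,
               positive_genes = positive_genes,
               guides_per_positive = if (length(positive_genes)) 2L else 0L,
               n_noncutting = n_noncutting, n_cutting = n_cutting,
               seed = seed)
}

# Simulate a small screen and return everything downstream tests need.
small_screen <- function(design = tiny_design(), scenario = "paper_like",
                         seed = 1, params = sim_params(n_batches = 1,
                           conditions = c("glucose", "galactose"),
                           pdna_depth = 300, endpoint_depth = 300),
                         truth = NULL) {
  if (is.null(truth)) truth <- make_truth(design, scenario, seed = seed,
                                          params = params)
  scr <- simulate_counts(design, truth, params, seed = seed + 1000)
  lfc <- compute_lfc(scr$counts, scr$sample_meta, scr$constructs)
  list(design = design, truth = truth, screen = scr, lfc = lfc,
       params = params)
}

# Hand-built guide-level LFC table for exact-arithmetic tests: full factorial
# of the given per-guide effects, C = alpha + phi + psi (+ extra).
toy_lfc_table <- function(phi, psi, alpha = 0, condition = "glucose",
                          batch = 1L, sp_category = NULL, sa_category = NULL,
                          sp_gene = NULL, sa_gene = NULL) {
  sp_ids <- names(phi); sa_ids <- names(psi)
  if (is.null(sp_category)) sp_category <- rep("target", length(phi))
  if (is.null(sa_category)) sa_category <- rep("target", length(psi))
  if (is.null(sp_gene)) sp_gene <- sub("_g[0-9]+$", "", sp_ids)
  if (is.null(sa_gene)) sa_gene <- sub("_g[0-9]+$", "", sa_ids)
  i <- rep(seq_along(sp_ids), times = length(sa_ids))
  k <- rep(seq_along(sa_ids), each = length(sp_ids))
  sp_ctrl <- sp_category[i] %in% c("cutting_ctrl", "noncutting_ctrl")
  sa_ctrl <- sa_category[k] %in% c("cutting_ctrl", "noncutting_ctrl")
  dt <- data.table::data.table(
    construct_id = paste(sp_ids[i], sa_ids[k], sep = "|"),
    sp_guide_id = sp_ids[i], sa_guide_id = sa_ids[k],
    sp_gene = sp_gene[i], sa_gene = sa_gene[k],
    sp_category = sp_category[i], sa_category = sa_category[k],
    gene_pair = duoscreen:::pair_key(sp_gene[i], sa_gene[k]),
    pair_class = ifelse(sp_ctrl & sa_ctrl, "ctrl_ctrl",
                 ifelse(!sp_ctrl & !sa_ctrl, "gene_gene", "gene_ctrl")),
    condition = condition, batch = batch,
    lfc = alpha + unname(phi)[i] + unname(psi)[k])
  data.table::setattr(dt, "class", c("guide_lfc", class(dt)))
  dt[]
}

# Exact L1 linear-programming oracle (scipy linprog via python); returns the
# optimal objective for the additive model on the given rows.
lp_l1_objective <- function(dat) {
  sp_lev <- sort(unique(dat$sp_guide_id))
  sa_lev <- sort(unique(dat$sa_guide_id))
  sp_ctrl <- which(sp_lev %in% dat$sp_guide_id[dat$sp_category == "cutting_ctrl"])
  sa_ctrl <- which(sa_lev %in% dat$sa_guide_id[dat$sa_category == "cutting_ctrl"])
  if (length(sp_ctrl) == 0) sp_ctrl <- seq_along(sp_lev)
  if (length(sa_ctrl) == 0) sa_ctrl <- seq_along(sa_lev)
  inp <- list(y = dat$lfc,
              i_sp = match(dat$sp_guide_id, sp_lev),
              i_sa = match(dat$sa_guide_id, sa_lev),
              P = length(sp_lev), Q = length(sa_lev),
              sp_ctrl = sp_ctrl, sa_ctrl = sa_ctrl)
  tf <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(inp, auto_unbox = TRUE, digits = NA), tf)
  script <- testthat::test_path("l1_lp.py")
  out <- system2("python", shQuote(script), stdout = TRUE, stdin = tf)
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  stopifnot(res$status == 0)
  res$objective
}

# Independent brute-force evaluation of the guide-concordance rule (QC step
# 4), written against the documented definition, loop-by-loop.
brute_force_poor_guides <- function(lfc, profile = "cutting_ctrl") {
  scored <- c("target", "positive_ctrl")
  genes <- sort(unique(c(lfc$sp_gene[lfc$sp_category %in% scored],
                         lfc$sa_gene[lfc$sa_category %in% scored])))
  poor <- list()
  lfc_df <- as.data.frame(lfc)
  for (b in sort(unique(lfc_df$batch))) {
    lb <- lfc_df[lfc_df$batch == b, ]
    flagged <- character(0)
    for (g in genes) {
      profs <- list()
      sp_rows <- lb[lb$sp_gene == g & lb$sa_category == "cutting_ctrl", ]
      for (gid in unique(sp_rows$sp_guide_id)) {
        x <- sp_rows[sp_rows$sp_guide_id == gid, ]
        slot <- match(x$sa_guide_id, sort(unique(sp_rows$sa_guide_id)))
        profs[[gid]] <- setNames(x$lfc, paste(x$condition, slot, sep = "."))
      }
      sa_rows <- lb[lb$sa_gene == g & lb$sp_category == "cutting_ctrl", ]
      for (gid in unique(sa_rows$sa_guide_id)) {
        x <- sa_rows[sa_rows$sa_guide_id == gid, ]
        slot <- match(x$sp_guide_id, sort(unique(sa_rows$sp_guide_id)))
        profs[[gid]] <- setNames(x$lfc, paste(x$condition, slot, sep = "."))
      }
      if (length(profs) < 2) next
      keys <- sort(unique(unlist(lapply(profs, names))))
      M <- sapply(profs, function(v) v[keys])
      cm <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      for (gid in colnames(cm))
        if (sum(cm[gid, ]) - cm[gid, gid] < 0) flagged <- c(flagged, gid)
    }
    poor[[as.character(b)]] <- flagged
  }
  sort(unique(unlist(poor)))
}
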