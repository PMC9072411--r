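#' Simulation parameters for a synthetic pooled screen
#'
#' @param pdna_depth Mean reads per construct in the plasmid-DNA baseline.
#' @param endpoint_depth Mean reads per construct in each endpoint sample.
#' @param dispersion Negative-binomial overdispersion d (variance
#'   mu + d * mu^2); 0 gives Poisson sampling.
#' @param n_batches Number of screening batches; each batch gets its own pDNA
#'   sample and its own plasmid-abundance draw.
#' @param conditions Condition labels for the endpoint samples.
#' @param abundance_sigma Log-normal sigma of per-construct plasmid abundance.
#' @param noncutting_bonus Fitness bonus (LFC units) for cells carrying a
#'   non-cutting control guide: these cells escape double-strand-break burden
#'   and grow slightly better than the population, which is why cutting
#'   controls are the preferred neutral reference.
#' @param lethal_cutting_fraction Fraction of cutting-control guides given a
#'   strong negative effect (off-target lethality), for testing the
#'   lethal-control filter.
#' @param lethal_effect LFC effect assigned to lethal cutting controls
#'   (default -4: near-complete dropout).
#' @param min_efficacy Lower bound of the uniform guide-efficacy draw for
#'   target/positive-control guides (efficacies in `[min_efficacy, 1]`).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(pdna_depth = 500, endpoint_depth = 500,
                       dispersion = 0.05, n_batches = 2L,
                       conditions = c("glucose", "galactose",
                                      "oxphos_inhibition", "no_pyruvate"),
                       abundance_sigma = 0.5, noncutting_bonus = 0.3,
                       lethal_cutting_fraction = 0, lethal_effect = -4,
                       min_efficacy = 0.8) {
  stopifnot(pdna_depth > 0, endpoint_depth > 0, dispersion >= 0,
            n_batches >= 1, length(conditions) >= 1,
            min_efficacy >= 0, min_efficacy <= 1)
  structure(as.list(environment()), class = "sim_params")
}

#' Generate a ground-truth table for a simulated screen
#'
#' The truth table holds the simulator's counterparts of the quantities the
#' analysis estimates: per-condition baseline drift (alpha), per-gene
#' per-condition fitness effects (phi), per-pair per-condition interaction
#' effects (pi), and per-guide efficacies. Self-pairs always have pi = 0.
#'
#' Scenarios: `"null"` sets every phi and pi to 0 (alpha still varies by
#' condition, emulating growth-rate differences between media); `"paper_like"`
#' draws gene effects and injects at least one synthetic-sick pair, one
#' buffering pair, one gene-by-environment gene and one condition-specific
#' interaction; `"custom"` starts from all-zero effects for the caller to
#' fill in.
#'
#' @param design A `dual_design`.
#' @param scenario One of `"null"`, `"paper_like"`, `"custom"`.
#' @param seed Integer seed.
#' @param params A [sim_params()]; supplies conditions, the non-cutting bonus
#'   and the lethal-control settings.
#' @return List of class `truth_table` with `conditions`, `alpha` (named per
#'   condition), `phi` (genes x conditions matrix), `pi` (pair-key x
#'   conditions matrix over all unordered distinct scored-gene pairs),
#'   `guide_efficacy` (named over all guide ids), `guide_effect` extras
#'   (`noncutting_bonus`, `lethal_guides`, `lethal_effect`).
#' @export
make_truth <- function(design, scenario = c("paper_like", "null", "custom"),
                       seed = 1L, params = sim_params()) {
  scenario <- match.arg(scenario)
  validate_design(design)
  conds <- params$conditions
  genes <- scored_genes(design)
  pairs <- if (length(genes) >= 2) {
    idx <- utils::combn(sort(genes), 2)
    paste(idx[1, ], idx[2, ], sep = "|")
  } else character(0)

  phi <- matrix(0, length(genes), length(conds),
                dimnames = list(genes, conds))
  pim <- matrix(0, length(pairs), length(conds),
                dimnames = list(pairs, conds))
  all_guides <- c(design$sp_guides$guide_id, design$sa_guides$guide_id)
  all_cat <- c(design$sp_guides$category, design$sa_guides$category)
  eff <- setNames(rep(1, length(all_guides)), all_guides)
  # growth-rate differences between media: a per-condition baseline shared by
  # every construct (absorbed by alpha / the control-based z-score downstream)
  alpha <- setNames(seq(0, -0.2 * (length(conds) - 1), length.out = length(conds)),
                    conds)

  cut_ids <- all_guides[all_cat == "cutting_ctrl"]
  lethal <- character(0)
  noncutting_bonus <- params$noncutting_bonus

  with_seed(derive_seed(seed, paste0("truth_", scenario)), {
    targ <- all_cat %in% c("target", "positive_ctrl")
    eff[targ] <- runif(sum(targ), params$min_efficacy, 1)
    if (scenario == "null") noncutting_bonus <- 0  # a truly null screen
    if (scenario != "null" &&
        params$lethal_cutting_fraction > 0 && length(cut_ids) > 0) {
      n_lethal <- max(1L, round(params$lethal_cutting_fraction * length(cut_ids)))
      lethal <- sample(cut_ids, n_lethal)
    }
    if (scenario == "paper_like") {
      # most knockouts mildly deleterious; a few strong fitness genes. Media
      # swaps change a metabolic gene's fitness substantially: restrictive
      # media amplify baseline effects (severity multiplier per condition)
      # and each gene gets its own per-condition component on top.
      base <- pmin(0, rnorm(length(genes), -0.2, 0.35))
      pos <- genes %in% design$gene_table$gene[design$gene_table$category ==
                                                "positive_ctrl"]
      base[pos] <- rnorm(sum(pos), -1.2, 0.2)  # positive controls drop out
      severity <- seq(1, 1.6, length.out = length(conds))
      phi[] <- outer(base, severity) +
        matrix(rnorm(length(phi), 0, 0.3), nrow(phi))
      if (all(c("BCL2L1", "MCL1") %in% genes))
        pim["BCL2L1|MCL1", ] <- -1  # the paralog synthetic-lethal pair
      if (length(genes) >= 4 && length(conds) >= 2) {
        gxe_gene <- genes[order(base)[ceiling(length(genes) / 2)]]
        phi[gxe_gene, conds[2]] <- phi[gxe_gene, conds[1]] - 1  # GxE gene
      }
      if (length(pairs) >= 3) {
        chosen <- sample(pairs, 3)
        pim[chosen[1], ] <- -1            # synthetic sick in all conditions
        pim[chosen[2], ] <- 0.6           # buffering
        if (length(conds) >= 2)
          pim[chosen[3], conds[2]] <- -0.8  # condition-specific interaction
      }
    }
  })

  structure(list(conditions = conds, alpha = alpha, phi = phi, pi = pim,
                 guide_efficacy = eff,
                 noncutting_bonus = noncutting_bonus,
                 lethal_guides = lethal, lethal_effect = params$lethal_effect,
                 scenario = scenario),
            class = "truth_table")
}

#' Ground truth for estimator-accuracy benchmarking
#'
#' A `custom` truth tailored to measuring pi-score recovery: all guides fully
#' active (so the estimand equals the injected pi rather than its
#' efficacy-attenuated version), gene fitness drawn with the paper_like
#' severity structure, and interactions injected at fixed levels on
#' `pairs_per_level` randomly chosen pairs each, constant across conditions.
#'
#' @param design A `dual_design`.
#' @param seed Integer seed.
#' @param params A [sim_params()]; `min_efficacy` is forced to 1.
#' @param pairs_per_level Pairs injected at each level (default 12).
#' @param levels Interaction levels (default -1, -0.5, +0.5; remaining pairs
#'   stay at 0).
#' @return A `truth_table`.
#' @export
make_recovery_truth <- function(design, seed = 1L,
                                params = sim_params(),
                                pairs_per_level = 12L,
                                levels = c(-1, -0.5, 0.5)) {
  params$min_efficacy <- 1
  truth <- make_truth(design, "custom", seed = seed, params = params)
  n_inject <- pairs_per_level * length(levels)
  stopifnot(nrow(truth$pi) >= n_inject)
  with_seed(derive_seed(seed, "recovery"), {
    chosen <- sample(rownames(truth$pi), n_inject)
    for (i in seq_along(levels)) {
      idx <- chosen[((i - 1) * pairs_per_level + 1):(i * pairs_per_level)]
      truth$pi[idx, ] <- levels[i]
    }
    base <- pmin(0, rnorm(nrow(truth$phi), -0.2, 0.35))
    severity <- seq(1, 1.6, length.out = ncol(truth$phi))
    truth$phi[] <- outer(base, severity) +
      matrix(rnorm(length(truth$phi), 0, 0.3), nrow(truth$phi))
  })
  truth
}

# Per-guide fitness contribution in a given condition (LFC units).
guide_effect <- function(guide_ids, categories, genes, truth, condition) {
  out <- numeric(length(guide_ids))
  targ <- categories %in% c("target", "positive_ctrl")
  out[targ] <- truth$phi[genes[targ], condition] *
    truth$guide_efficacy[guide_ids[targ]]
  out[categories == "noncutting_ctrl"] <- truth$noncutting_bonus
  out[guide_ids %in% truth$lethal_guides] <- truth$lethal_effect
  out
}

# Expected (infinite-depth) LFC of every construct in `condition`.
true_construct_lfc <- function(constructs, truth, condition) {
  eff <- truth$guide_efficacy
  lfc <- truth$alpha[condition] +
    guide_effect(constructs$sp_guide_id, constructs$sp_category,
                 constructs$sp_gene, truth, condition) +
    guide_effect(constructs$sa_guide_id, constructs$sa_category,
                 constructs$sa_gene, truth, condition)
  both_gene <- constructs$pair_class == "gene_gene" &
    constructs$sp_gene != constructs$sa_gene
  if (any(both_gene)) {
    key <- constructs$gene_pair[both_gene]
    lfc[both_gene] <- lfc[both_gene] +
      truth$pi[key, condition] *
      eff[constructs$sp_guide_id[both_gene]] *
      eff[constructs$sa_guide_id[both_gene]]
  }
  unname(lfc)
}

rnbinom_disp <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate a count matrix for a dual-guide screen
#'
#' Per batch, a log-normal plasmid abundance is drawn per construct and
#' sampled with negative-binomial noise at the pDNA depth. Endpoint samples
#' re-weight the abundance by `2^trueLFC` (additive single-gene effects times
#' guide efficacy, plus the pairwise interaction scaled by the efficacy
#' product), renormalize to the endpoint depth, and sample again. Fully
#' deterministic given the seed.
#'
#' @param design A `dual_design`.
#' @param truth A `truth_table` from [make_truth()].
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return List of class `sim_screen`: `counts` (integer matrix constructs x
#'   samples), `sample_meta` (sample_id, condition, batch, timepoint,
#'   barcode), `constructs`, `truth`, `design`.
#' @export
simulate_counts <- function(design, truth, params = sim_params(), seed = 1L) {
  validate_design(design)
  constructs <- enumerate_constructs(design)
  n <- nrow(constructs)
  conds <- truth$conditions
  lfc_true <- vapply(conds, function(cc) true_construct_lfc(constructs, truth, cc),
                     numeric(n))

  meta <- list(); cols <- list()
  with_seed(derive_seed(seed, "counts"), {
    for (b in seq_len(params$n_batches)) {
      abund <- exp(rnorm(n, 0, params$abundance_sigma))
      mu_p <- params$pdna_depth * abund / mean(abund)
      if (mean(mu_p < 1) > 0.5)
        warning("pDNA depth too low to represent the library (batch ", b, ")")
      sid <- sprintf("pDNA_b%d", b)
      cols[[sid]] <- rnbinom_disp(n, mu_p, params$dispersion)
      meta[[sid]] <- data.frame(sample_id = sid, condition = "pDNA",
                                batch = b, timepoint = "pDNA")
      for (cc in conds) {
        w <- abund * 2^lfc_true[, cc]
        mu_e <- params$endpoint_depth * n * w / sum(w)
        sid <- sprintf("%s_b%d", cc, b)
        cols[[sid]] <- rnbinom_disp(n, mu_e, params$dispersion)
        meta[[sid]] <- data.frame(sample_id = sid, condition = cc,
                                  batch = b, timepoint = "d15")
      }
    }
  })
  counts <- do.call(cbind, cols)
  rownames(counts) <- constructs$construct_id
  sample_meta <- do.call(rbind, meta)
  rownames(sample_meta) <- NULL
  sample_meta$barcode <- make_barcodes(nrow(sample_meta),
                                       design$context$barcode_length,
                                       design$context$sp_anchor,
                                       derive_seed(seed, "barcodes"))
  structure(list(counts = counts, sample_meta = sample_meta,
                 constructs = constructs, truth = truth, design = design),
            class = "sim_screen")
}

# Barcodes whose concatenation with the Sp anchor cannot create a spurious
# earlier anchor occurrence in the read prefix.
make_barcodes <- function(n, width, sp_anchor, seed) {
  with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      cand <- random_dna(n, width)
      ok <- !vapply(cand, function(b) {
        pre <- paste0(b, sp_anchor)
        regexpr(sp_anchor, pre, fixed = TRUE)[1] != width + 1
      }, logical(1))
      out <- unique(c(out, cand[ok]))
    }
    out[seq_len(n)]
  })
}

#' Emit synthetic FASTQ reads for a simulated screen
#'
#' Each read is `barcode + CACCG + SpCas9 guide + intervening vector sequence
#' (ending in the tracr anchor CTTAAAC, so the SaCas9 guide starts exactly
#' `sa_offset_nt` after the SpCas9 guide) + SaCas9 guide + suffix`. Reads per
#' construct are multinomial on the simulated count column; substitution
#' errors are injected uniformly at `error_rate`. An emission log (per sample
#' x construct read counts) is written so deconvolution can be checked
#' exactly.
#'
#' @param screen A `sim_screen` from [simulate_counts()].
#' @param out_dir Output directory (created if needed).
#' @param reads_per_sample Total reads emitted per sample.
#' @param error_rate Per-base substitution probability in `[0, 0.1]`.
#' @param seed Integer seed.
#' @return List with `fastq` (one file per sample), `sample_sheet`,
#'   `emission_log` paths.
#' @export
simulate_fastq <- function(screen, out_dir, reads_per_sample = 10000,
                           error_rate = 0, seed = 1L) {
  stopifnot(inherits(screen, "sim_screen"),
            error_rate >= 0, error_rate <= 0.1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ctx <- screen$design$context
  sp_seq <- setNames(screen$design$sp_guides$sequence,
                     screen$design$sp_guides$guide_id)
  sa_seq <- setNames(screen$design$sa_guides$sequence,
                     screen$design$sa_guides$guide_id)
  cons <- screen$constructs
  body <- paste0(ctx$sp_anchor, sp_seq[cons$sp_guide_id],
                 ctx$intervening_sequence, sa_seq[cons$sa_guide_id], "GTTTTAGT")

  fastq_paths <- character(0); log_rows <- list()
  with_seed(derive_seed(seed, "fastq"), {
    for (s in seq_len(nrow(screen$sample_meta))) {
      sid <- screen$sample_meta$sample_id[s]
      bc <- screen$sample_meta$barcode[s]
      p <- screen$counts[, sid]
      if (sum(p) == 0) p <- rep(1, length(p))
      nread <- as.vector(rmultinom(1, reads_per_sample, p))
      idx <- rep.int(seq_along(nread), nread)
      reads <- paste0(bc, body[idx])
      n_err_reads <- 0L
      if (error_rate > 0 && length(reads) > 0) {
        reads <- inject_errors(reads, error_rate)
        n_err_reads <- attr(reads, "n_mutated")
      }
      ids <- sprintf("@%s_read%06d", sid, seq_along(reads))
      fq <- file.path(out_dir, paste0(sid, ".fastq"))
      qual <- vapply(nchar(reads), function(w)
        paste(rep("F", w), collapse = ""), character(1))
      writeLines(as.vector(rbind(ids, reads, "+", qual)), fq)
      fastq_paths[sid] <- fq
      log_rows[[sid]] <- data.frame(sample_id = sid,
                                    construct_id = cons$construct_id,
                                    n_reads = nread)[nread > 0, ]
    }
  })
  sheet <- file.path(out_dir, "sample_sheet.tsv")
  write.table(screen$sample_meta[, c("sample_id", "condition", "batch",
                                     "timepoint", "barcode")],
              sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  log_path <- file.path(out_dir, "emission_log.tsv")
  emission <- do.call(rbind, log_rows)
  rownames(emission) <- NULL
  write.table(emission, log_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fastq = fastq_paths, sample_sheet = sheet, emission_log = log_path)
}

# Uniform substitution errors; returns reads with attribute n_mutated.
inject_errors <- function(reads, error_rate) {
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, error_rate)
  which_err <- which(n_err > 0)
  for (i in which_err) {
    pos <- sample.int(lens[i], n_err[i])
    chars <- strsplit(reads[i], "")[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  attr(reads, "n_mutated") <- length(which_err)
  reads
}
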