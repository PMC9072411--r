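#' Vector context for a dual-guide cassette
#'
#' Describes the fixed sequence landmarks of the dual-cassette vector that the
#' read parser relies on: the anchor immediately preceding the U6-driven
#' SpCas9 guide, the S. aureus tracr anchor immediately preceding the SaCas9
#' guide, and the offset (in nucleotides) from the end of the SpCas9 guide to
#' the start of the SaCas9 guide.
#'
#' @param sp_anchor Anchor preceding the SpCas9 guide (default `"CACCG"`).
#' @param sa_tracr_anchor Anchor preceding the SaCas9 guide (default
#'   `"CTTAAAC"`).
#' @param sa_offset_nt Distance in nt from the SpCas9 guide 3' end to the
#'   SaCas9 guide 5' start (default 194). The intervening vector sequence ends
#'   with `sa_tracr_anchor`.
#' @param barcode_length Length of the sample barcode (default 8).
#' @param intervening_sequence Optional explicit intervening sequence of
#'   length `sa_offset_nt` ending in `sa_tracr_anchor`; generated
#'   deterministically from `seed` when `NULL`.
#' @param seed Seed used to generate the intervening sequence.
#' @return A list of class `vector_context`.
#' @export
vector_context <- function(sp_anchor = "CACCG", sa_tracr_anchor = "CTTAAAC",
                           sa_offset_nt = 194L, barcode_length = 8L,
                           intervening_sequence = NULL, seed = 1L) {
  stopifnot(nzchar(sp_anchor), nzchar(sa_tracr_anchor), sa_offset_nt > 0)
  if (is.null(intervening_sequence)) {
    stopifnot(sa_offset_nt > nchar(sa_tracr_anchor))
    intervening_sequence <- with_seed(derive_seed(seed, "context"), {
      repeat {
        body <- random_dna(1, sa_offset_nt - nchar(sa_tracr_anchor))
        full <- paste0(body, sa_tracr_anchor)
        # exactly one tracr anchor (terminal) and no spurious Sp anchor, so
        # the offset window and the tracr window always agree on clean reads
        if (!grepl(sp_anchor, full, fixed = TRUE) &&
            length(gregexpr(sa_tracr_anchor, full, fixed = TRUE)[[1]]) == 1)
          break
      }
      full
    })
  }
  stopifnot(nchar(intervening_sequence) == sa_offset_nt,
            endsWith(intervening_sequence, sa_tracr_anchor))
  structure(list(sp_anchor = sp_anchor, sa_tracr_anchor = sa_tracr_anchor,
                 sa_offset_nt = as.integer(sa_offset_nt),
                 barcode_length = as.integer(barcode_length),
                 intervening_sequence = intervening_sequence),
            class = "vector_context")
}

default_gene_names <- function() {
  c(paste0("SLC25A", seq_len(53)), paste0("SLCM", seq_len(7)))
}

#' Build a dual-guide library design
#'
#' Constructs the guide catalog for both Cas9 positions: target genes with a
#' fixed guide quota per gene per enzyme, positive-control genes with their
#' own quota, plus non-cutting and cutting (olfactory-receptor-style) control
#' guides. Guide sequences are synthetic, drawn deterministically from the
#' seed; no genomic sequences are involved.
#'
#' @param n_target_genes Number of target genes (default 60).
#' @param guides_per_gene Guides per target gene per enzyme (default 4).
#' @param positive_genes Character vector of positive-control gene names.
#' @param guides_per_positive Guides per positive-control gene (default 2).
#' @param n_noncutting,n_cutting Numbers of non-cutting and cutting control
#'   guides per position (defaults 8 and 19).
#' @param sp_guide_length,sa_guide_length Guide lengths in nt (defaults 20 and
#'   21; each must be 20 or 21).
#' @param gene_names Optional explicit target gene names.
#' @param context A [vector_context()].
#' @param seed Integer seed; the design is a pure function of its arguments.
#' @return A list of class `dual_design` with elements `sp_guides`,
#'   `sa_guides` (data.frames: guide_id, sequence, enzyme, target_gene,
#'   category), `gene_table` (gene, category) and `context`.
#' @export
build_design <- function(n_target_genes = 60L, guides_per_gene = 4L,
                         positive_genes = c("BCL2L1", "MCL1", "EEF2"),
                         guides_per_positive = 2L,
                         n_noncutting = 8L, n_cutting = 19L,
                         sp_guide_length = 20L, sa_guide_length = 21L,
                         gene_names = NULL, context = NULL, seed = 1L) {
  stopifnot(sp_guide_length %in% c(20L, 21L), sa_guide_length %in% c(20L, 21L),
            n_target_genes >= 1)
  if (is.null(gene_names)) {
    pool <- default_gene_names()
    gene_names <- if (n_target_genes <= length(pool)) pool[seq_len(n_target_genes)]
                  else sprintf("GENE%03d", seq_len(n_target_genes))
  }
  stopifnot(length(gene_names) == n_target_genes,
            !anyDuplicated(c(gene_names, positive_genes)))
  if (is.null(context)) context <- vector_context(seed = seed)

  ncc <- sprintf("NONCUT_%02d", seq_len(n_noncutting))
  cc  <- sprintf("CUTCTRL_%02d", seq_len(n_cutting))
  gene_table <- data.frame(
    gene = c(gene_names, positive_genes, ncc, cc),
    category = rep(c("target", "positive_ctrl", "noncutting_ctrl", "cutting_ctrl"),
                   c(length(gene_names), length(positive_genes),
                     n_noncutting, n_cutting)),
    stringsAsFactors = FALSE)

  one_position <- function(enzyme, width, seed) {
    genes <- c(rep(gene_names, each = guides_per_gene),
               rep(positive_genes, each = guides_per_positive),
               ncc, cc)
    idx <- c(unlist(lapply(gene_names, function(g) seq_len(guides_per_gene))),
             unlist(lapply(positive_genes, function(g) seq_len(guides_per_positive))),
             rep(1L, n_noncutting + n_cutting))
    cat_map <- setNames(gene_table$category, gene_table$gene)
    seqs <- with_seed(seed, {
      repeat {
        s <- random_dna(length(genes), width)
        if (!anyDuplicated(s)) break
      }
      s
    })
    data.frame(
      guide_id = ifelse(idx > 1 | cat_map[genes] %in% c("target", "positive_ctrl"),
                        sprintf("%s_%s_g%d", tolower(substr(enzyme, 1, 2)), genes, idx),
                        sprintf("%s_%s", tolower(substr(enzyme, 1, 2)), genes)),
      sequence = seqs, enzyme = enzyme, target_gene = genes,
      category = unname(cat_map[genes]), stringsAsFactors = FALSE)
  }

  design <- structure(list(
    sp_guides = one_position("SpCas9", sp_guide_length, derive_seed(seed, "sp")),
    sa_guides = one_position("SaCas9", sa_guide_length, derive_seed(seed, "sa")),
    gene_table = gene_table, context = context),
    class = "dual_design")
  validate_design(design)
  design
}

#' Build the default 273 x 273 dual-guide design
#'
#' The default quotas: 60 target genes (a 53-member transporter family plus 7
#' additional mitochondrial solute carriers) with four guides per gene per
#' enzyme, three positive-control genes (BCL2L1, MCL1, EEF2) with two guides
#' each, 8 non-cutting controls and 19 cutting controls — 273 guides per Cas9
#' position and 273 x 273 = 74,529 dual-guide constructs.
#'
#' @param seed Integer seed for the synthetic guide sequences.
#' @return A `dual_design`; see [build_design()].
#' @export
build_default_design <- function(seed = 1L) build_design(seed = seed)

#' @export
print.dual_design <- function(x, ...) {
  cat(sprintf("dual_design: %d SpCas9 + %d SaCas9 guides, %d genes (%d scored)\n",
              nrow(x$sp_guides), nrow(x$sa_guides), nrow(x$gene_table),
              length(scored_genes(x))))
  invisible(x)
}

#' Validate a dual-guide design
#'
#' Checks sequence alphabet and length, guide-id uniqueness within each
#' position, and that every guide's target gene appears in the gene table.
#'
#' @param design A `dual_design`.
#' @return The design, invisibly; errors describe the first violation.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "dual_design"))
  for (pos in c("sp_guides", "sa_guides")) {
    g <- design[[pos]]
    if (anyDuplicated(g$guide_id))
      stop("duplicate guide ids in ", pos)
    if (!all(grepl("^[ACGT]+$", g$sequence)))
      stop("non-ACGT characters in ", pos, " sequences")
    if (!all(nchar(g$sequence) %in% c(20L, 21L)))
      stop("guide lengths must be 20 or 21 nt in ", pos)
    if (!all(g$target_gene %in% design$gene_table$gene))
      stop("guides in ", pos, " reference genes missing from gene_table")
  }
  invisible(design)
}

#' Genes scored at the gene level
#'
#' Target and positive-control genes; cutting and non-cutting controls are
#' never scored as genes.
#'
#' @param design A `dual_design`.
#' @return Character vector of gene names.
#' @export
scored_genes <- function(design) {
  design$gene_table$gene[design$gene_table$category %in%
                           c("target", "positive_ctrl")]
}

#' Enumerate all dual-guide constructs
#'
#' The Cartesian product of SpCas9 x SaCas9 guides. `construct_id` is the
#' orientation-preserving `"<sp_guide_id>|<sa_guide_id>"`; the unordered gene
#' pair is carried alongside for downstream symmetrization.
#'
#' @param design A `dual_design`.
#' @return data.frame with columns construct_id, sp_guide_id, sa_guide_id,
#'   sp_gene, sa_gene, sp_category, sa_category, gene_pair (unordered key),
#'   pair_class (`gene_gene`, `gene_ctrl`, `ctrl_ctrl`).
#' @export
enumerate_constructs <- function(design) {
  validate_design(design)
  sp <- design$sp_guides; sa <- design$sa_guides
  i <- rep(seq_len(nrow(sp)), times = nrow(sa))
  k <- rep(seq_len(nrow(sa)), each = nrow(sp))
  sp_ctrl <- sp$category[i] %in% c("cutting_ctrl", "noncutting_ctrl")
  sa_ctrl <- sa$category[k] %in% c("cutting_ctrl", "noncutting_ctrl")
  data.frame(
    construct_id = paste(sp$guide_id[i], sa$guide_id[k], sep = "|"),
    sp_guide_id = sp$guide_id[i], sa_guide_id = sa$guide_id[k],
    sp_gene = sp$target_gene[i], sa_gene = sa$target_gene[k],
    sp_category = sp$category[i], sa_category = sa$category[k],
    gene_pair = pair_key(sp$target_gene[i], sa$target_gene[k]),
    pair_class = ifelse(sp_ctrl & sa_ctrl, "ctrl_ctrl",
                 ifelse(!sp_ctrl & !sa_ctrl, "gene_gene", "gene_ctrl")),
    stringsAsFactors = FALSE)
}

#' Number of gene-level perturbations
#'
#' For G scored genes, the single knockouts plus unordered distinct pairs:
#' G + G(G-1)/2. With the default design's 63 scored genes this is 2016.
#'
#' @param design A `dual_design`.
#' @return Integer count.
#' @export
count_gene_level_perturbations <- function(design) {
  G <- length(scored_genes(design))
  if (G == 0) stop("design has no scored genes")
  as.integer(G + G * (G - 1) / 2)
}

#' Read / write a library design guide table
#'
#' Tab-separated, UTF-8, header required; columns guide_id, sequence, enzyme,
#' target_gene, category.
#'
#' @param design A `dual_design`.
#' @param path File path.
#' @param context A [vector_context()] to attach on read (the TSV carries the
#'   guide catalog only).
#' @return `write_design_tsv` returns `path` invisibly; `read_design_tsv`
#'   returns a `dual_design`.
#' @export
write_design_tsv <- function(design, path) {
  tab <- rbind(design$sp_guides, design$sa_guides)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path, context = vector_context()) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("guide_id", "sequence", "enzyme", "target_gene", "category")
  if (!all(need %in% names(tab)))
    stop("design TSV must have columns: ", paste(need, collapse = ", "))
  gt <- unique(tab[, c("target_gene", "category")])
  names(gt) <- c("gene", "category")
  if (anyDuplicated(gt$gene))
    stop("inconsistent category assignments for a gene in design TSV")
  design <- structure(list(
    sp_guides = tab[tab$enzyme == "SpCas9", need],
    sa_guides = tab[tab$enzyme == "SaCas9", need],
    gene_table = gt[order(match(gt$category,
      c("target", "positive_ctrl", "noncutting_ctrl", "cutting_ctrl"))), ],
    context = context), class = "dual_design")
  rownames(design$sp_guides) <- rownames(design$sa_guides) <-
    rownames(design$gene_table) <- NULL
  validate_design(design)
  design
}
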