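#' Deconvolution parameters
#'
#' @param sa_match_length Number of leading nucleotides of the SaCas9 guide
#'   required to match the reference, in `[8, 21]`. Shortening the reference
#'   rescues reads whose 3' end has degraded quality, as long as the truncated
#'   prefixes remain unique.
#' @param max_mismatches_reference Mismatches tolerated in the guide lookup
#'   (default 0: exact matching).
#' @return List of class `deconv_params`.
#' @export
deconv_params <- function(sa_match_length = 21L, max_mismatches_reference = 0L) {
  stopifnot(sa_match_length >= 8L, sa_match_length <= 21L,
            max_mismatches_reference >= 0L)
  structure(list(sa_match_length = as.integer(sa_match_length),
                 max_mismatches_reference = as.integer(max_mismatches_reference)),
            class = "deconv_params")
}

# Lookup table for truncated SaCas9 references: prefixes shared by more than
# one guide are ambiguous and never assigned.
sa_reference <- function(design, sa_match_length) {
  pref <- substr(design$sa_guides$sequence, 1, sa_match_length)
  dup <- pref %in% pref[duplicated(pref)]
  list(prefix = pref[!dup], guide_id = design$sa_guides$guide_id[!dup])
}

#' Parse dual-cassette reads into guide and sample assignments
#'
#' Implements the anchor/offset algorithm: (1) the first occurrence of the Sp
#' anchor (`CACCG`) is located; the following 20 nt (then 21 nt as fallback)
#' are matched exactly against the SpCas9 reference. (2) Two 21-nt windows
#' are extracted — one starting `sa_offset_nt` after the SpCas9 guide ends,
#' one following the first tracr anchor (`CTTAAAC`) downstream of the SpCas9
#' guide. If the windows agree, the (optionally truncated) sequence is matched
#' against the SaCas9 reference. (3) The sample barcode (leading
#' `barcode_length` nt of the read) is matched against the sample sheet.
#' `status` records the first failing step; reads too short for a step fail
#' at that step, never with an exception.
#'
#' @param reads Character vector of reads (uppercase ACGTN).
#' @param design A `dual_design`.
#' @param params A [deconv_params()].
#' @param barcode_map Optional named character vector barcode -> sample_id;
#'   when `NULL` the sample step is skipped and `sample_id` stays `NA`.
#' @return data.frame with columns sp_guide_id, sa_guide_id, sample_id and
#'   status (one of assigned, no_sp_anchor, sp_unmatched, sa_mismatch,
#'   sa_unmatched, barcode_unmatched).
#' @export
parse_reads <- function(reads, design, params = deconv_params(),
                        barcode_map = NULL) {
  n <- length(reads)
  ctx <- design$context
  sp_id <- rep(NA_character_, n); sa_id <- rep(NA_character_, n)
  smp <- rep(NA_character_, n)
  status <- rep(NA_character_, n)
  if (n == 0)
    return(data.frame(sp_guide_id = sp_id, sa_guide_id = sa_id,
                      sample_id = smp, status = character(0)))

  # --- step 1: Sp anchor and SpCas9 guide -------------------------------
  anchor_pos <- regexpr(ctx$sp_anchor, reads, fixed = TRUE)
  status[anchor_pos < 0] <- "no_sp_anchor"
  live <- anchor_pos > 0
  sp_start <- anchor_pos + nchar(ctx$sp_anchor)
  sp_len <- rep(NA_integer_, n)
  for (w in sort(unique(nchar(design$sp_guides$sequence)))) {
    ref <- design$sp_guides
    refw <- ref[nchar(ref$sequence) == w, ]
    cand <- substr(reads, sp_start, sp_start + w - 1L)
    hit <- live & is.na(sp_id) & cand %in% refw$sequence
    if (any(hit)) {
      sp_id[hit] <- refw$guide_id[match(cand[hit], refw$sequence)]
      sp_len[hit] <- w
    }
  }
  status[live & is.na(sp_id)] <- "sp_unmatched"
  live <- live & !is.na(sp_id)

  # --- step 2: offset window vs tracr window, then SaCas9 lookup --------
  sp_end <- sp_start + sp_len - 1L
  win1 <- substr(reads, sp_end + ctx$sa_offset_nt + 1L,
                 sp_end + ctx$sa_offset_nt + 21L)
  downstream <- substr(reads, sp_end + 1L, nchar(reads))
  tr <- regexpr(ctx$sa_tracr_anchor, downstream, fixed = TRUE)
  tr_start <- ifelse(tr > 0, sp_end + tr + nchar(ctx$sa_tracr_anchor), NA_integer_)
  win2 <- substr(reads, tr_start, tr_start + 20L)
  bad_sa <- live & (tr < 0 | nchar(win1) < 21L | nchar(win2) < 21L | win1 != win2)
  status[bad_sa] <- "sa_mismatch"
  live <- live & !bad_sa

  ref_sa <- sa_reference(design, params$sa_match_length)
  cand_sa <- substr(win1, 1, params$sa_match_length)
  m <- match(cand_sa, ref_sa$prefix)
  hit <- live & !is.na(m)
  sa_id[hit] <- ref_sa$guide_id[m[hit]]
  status[live & is.na(m)] <- "sa_unmatched"
  live <- hit

  # --- step 3: sample barcode -------------------------------------------
  if (!is.null(barcode_map)) {
    bc <- substr(reads, 1, ctx$barcode_length)
    smp_all <- unname(barcode_map[bc])
    smp[live] <- smp_all[live]
    status[live & is.na(smp)] <- "barcode_unmatched"
    live <- live & !is.na(smp)
  }
  status[live] <- "assigned"
  data.frame(sp_guide_id = sp_id, sa_guide_id = sa_id, sample_id = smp,
             status = status, stringsAsFactors = FALSE)
}

read_fastq_seqs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  toupper(as.character(seqs, use.names = FALSE))
}

#' Deconvolve FASTQ files into a construct x sample count matrix
#'
#' Applies [parse_reads()] to every read of every file, assigns samples via
#' the 8-nt barcode from the sample sheet, and tabulates assigned reads per
#' construct. Unassigned reads are never silently dropped: the summary
#' accounts for every input read by status.
#'
#' @param fastq_paths Character vector of FASTQ paths.
#' @param sample_sheet data.frame with columns sample_id, condition, batch,
#'   timepoint, barcode (or a path to such a TSV).
#' @param design A `dual_design`.
#' @param params A [deconv_params()].
#' @return List of class `deconv_result`: `counts` (integer matrix constructs
#'   x samples, all enumerated constructs), `sample_meta`, `summary`
#'   (data.frame status/n with one row per status class, including zero rows),
#'   `n_reads` total input reads.
#' @export
deconvolve <- function(fastq_paths, sample_sheet, design,
                       params = deconv_params()) {
  if (is.character(sample_sheet) && length(sample_sheet) == 1)
    sample_sheet <- read.delim(sample_sheet, stringsAsFactors = FALSE)
  if (anyDuplicated(sample_sheet$barcode))
    stop("duplicate barcodes in sample sheet")
  missing <- !file.exists(fastq_paths)
  if (any(missing))
    stop("FASTQ file not found: ", paste(fastq_paths[missing], collapse = ", "))
  barcode_map <- setNames(sample_sheet$sample_id, sample_sheet$barcode)
  constructs <- enumerate_constructs(design)

  statuses <- c("assigned", "no_sp_anchor", "sp_unmatched", "sa_mismatch",
                "sa_unmatched", "barcode_unmatched")
  counts <- matrix(0L, nrow(constructs), nrow(sample_sheet),
                   dimnames = list(constructs$construct_id,
                                   sample_sheet$sample_id))
  tally <- setNames(integer(length(statuses)), statuses)
  n_reads <- 0L
  for (fp in fastq_paths) {
    reads <- read_fastq_seqs(fp)
    n_reads <- n_reads + length(reads)
    if (length(reads) == 0) next
    asg <- parse_reads(reads, design, params, barcode_map)
    tt <- table(factor(asg$status, levels = statuses))
    tally <- tally + as.integer(tt)
    ok <- asg$status == "assigned"
    if (any(ok)) {
      cid <- paste(asg$sp_guide_id[ok], asg$sa_guide_id[ok], sep = "|")
      inc <- table(factor(cid, levels = rownames(counts)),
                   factor(asg$sample_id[ok], levels = colnames(counts)))
      counts <- counts + as.integer(inc)
    }
  }
  structure(list(counts = counts, sample_meta = sample_sheet,
                 summary = data.frame(status = statuses, n = unname(tally)),
                 n_reads = n_reads),
            class = "deconv_result")
}

#' Write / read a count matrix TSV (constructs x samples)
#'
#' @param counts Integer matrix with construct-id rownames and sample-id
#'   colnames.
#' @param path File path.
#' @return `write_counts_tsv` returns `path` invisibly; `read_counts_tsv`
#'   returns the integer matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(construct_id = rownames(counts), counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$construct_id
  storage.mode(m) <- "integer"
  m
}
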