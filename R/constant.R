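# Constant-region extraction, indel correction, strain-SNP typing and
# IGHJ1-anchored discovery of strain C-exon sequences.

#' Extract the constant-region portion of each read
#'
#' The C segment runs from one nucleotide downstream of the final IGHJ
#' nucleotide (`j_sequence_end`) to the end of the primer-trimmed read.
#'
#' @param records rearrangement tibble with `sequence` and `j_sequence_end`.
#' @param drop_missing if `TRUE`, records without `j_sequence_end` get an
#'   `NA` segment instead of raising the `no_j_call` error.
#' @return tibble with `sequence_id`, `c_seq` and `empty` flag.
#' @export
extract_ighc <- function(records, drop_missing = FALSE) {
  je <- records$j_sequence_end
  if (any(is.na(je)) && !drop_missing) stop("no_j_call")
  ok <- !is.na(je)
  cs <- rep(NA_character_, nrow(records))
  cs[ok] <- substr(records$sequence[ok], je[ok] + 1L,
                   nchar(records$sequence[ok]))
  tibble::tibble(sequence_id = records$sequence_id,
                 c_seq = cs,
                 empty = ok & !is.na(cs) & !nzchar(cs))
}

#' Indel-correct constant segments against a reference exon scaffold
#'
#' Each segment is globally aligned (affine gaps: open 4, extend 1, mismatch
#' 2; free tail gaps on either sequence) to the concatenated reference exons.
#' Read insertions are removed; read deletions are filled with the reference
#' base and flagged low-confidence; substitutions are preserved. Segments
#' aligning with identity below `min_identity` are marked unalignable and
#' left uncorrected.
#'
#' @param c_seqs character vector of raw constant segments.
#' @param ref_exons ordered character vector of reference exon sequences.
#' @param band alignment band half-width (maximum net indel drift).
#' @param min_identity identity threshold below which no correction is made.
#' @return tibble with `corrected`, `conf` (per-base, `"1"` marks
#'   deletion-filled positions), `identity`, `nsub`, `nins`, `ndel`,
#'   `unalignable`.
#' @export
indel_correct <- function(c_seqs, ref_exons, band = 16, min_identity = 0.7) {
  scaffold <- paste(ref_exons, collapse = "")
  if (nchar(scaffold) < 50) stop("reference exons too short (< 50 nt)")
  res <- cpp_correct_c(tolower(c_seqs), scaffold, as.integer(band),
                       2L, 4L, 1L)
  bad <- res$identity < min_identity
  out <- tibble::tibble(
    corrected = ifelse(bad, NA_character_, res$corrected),
    conf = ifelse(bad, NA_character_, res$conf),
    identity = res$identity,
    nsub = res$nsub, nins = res$nins, ndel = res$ndel,
    unalignable = bad
  )
  out
}

#' Type strain SNPs on (corrected) constant segments
#'
#' Reads the base at each SNP offset. Low-confidence positions
#' (deletion-filled during correction) and positions beyond the segment end
#' yield no-calls (`NA`).
#'
#' @param corrected character vector of corrected segments (reference
#'   coordinates).
#' @param conf matching confidence strings from [indel_correct()] (`NULL` to
#'   treat every position as confident, e.g. for raw segments).
#' @param snp_table SNP rows with a `global_offset` column (0-based offsets
#'   into the concatenated exons) and `snp_id`.
#' @return tibble with one column per `snp_id` plus `x_snp_lowconf` (count of
#'   deletion-filled SNP positions per read).
#' @export
type_snps <- function(corrected, conf = NULL, snp_table) {
  n <- length(corrected)
  out <- tibble::tibble(.rows = n)
  lowconf <- integer(n)
  for (i in seq_len(nrow(snp_table))) {
    pos <- snp_table$global_offset[i] + 1L
    base <- substr(corrected, pos, pos)
    base[is.na(corrected) | !nzchar(base)] <- NA_character_
    if (!is.null(conf)) {
      lc <- !is.na(corrected) & substr(conf, pos, pos) == "1"
      base[lc] <- NA_character_
      lowconf <- lowconf + as.integer(lc)
    }
    out[[snp_table$snp_id[i]]] <- base
  }
  out$x_snp_lowconf <- lowconf
  out
}

#' Assign a per-read constant-region strain call from SNP bases
#'
#' The strain call is the unique strain consistent with every called SNP
#' base; any inconsistency, or all-no-call, yields `uncalled` (`""`). With
#' `require_all = TRUE` (the IgG2b rule) every SNP must be called.
#'
#' @param snp_bases tibble from [type_snps()] (one column per snp_id).
#' @param snp_table matching SNP rows with `strainA_base`, `strainB_base`.
#' @param strains two strain labels (A, B).
#' @param require_all require all SNPs called (used for IGHG2B's four SNPs).
#' @return character vector of strain calls (`strains[1]`, `strains[2]` or
#'   `""`).
#' @export
assign_c_call <- function(snp_bases, snp_table, strains = c("BALB", "B6"),
                          require_all = FALSE) {
  ids <- snp_table$snp_id
  bases <- as.matrix(snp_bases[, ids, drop = FALSE])
  n <- nrow(bases)
  matchA <- bases_match_strain(bases, snp_table$strainA_base)
  matchB <- bases_match_strain(bases, snp_table$strainB_base)
  ncalled <- rowSums(!is.na(bases))
  need <- if (require_all) length(ids) else 1L
  out <- rep("", n)
  out[ncalled >= need & matchA & !matchB] <- strains[1]
  out[ncalled >= need & matchB & !matchA] <- strains[2]
  out
}

# all called bases agree with the given per-snp strain bases
bases_match_strain <- function(bases, strain_bases) {
  cmp <- sweep(bases, 2, strain_bases, FUN = "==")
  cmp[is.na(bases)] <- TRUE
  called_ok <- rowSums(!cmp, na.rm = TRUE) == 0
  called_ok & rowSums(!is.na(bases)) > 0
}

#' Type constant regions and add chromosome-anchor calls to a table
#'
#' Classifies each read's constant segment to a C gene (by edit distance of
#' its leading bases to each scaffold), indel-corrects it against the
#' scaffold, types the strain SNPs (IGHM: rs29176517; IGHG2B: four SNPs, all
#' required), and writes a `c_call` of the form `"IgM*BALB"` for reads with a
#' highly confident call (all required SNPs called, none deletion-filled,
#' alignment identity >= `min_identity_confident`). Other reads keep an empty
#' `c_call`. Tool columns `x_isotype`, `x_snp_bases`, `x_c_identity` are
#' added.
#'
#' @param records rearrangement tibble from [annotate_reads()].
#' @param strains two strain labels (A, B).
#' @param snp_table the strain SNP table (see [strain_snps()]).
#' @param scaffolds constant scaffolds from [c_scaffolds()].
#' @param correct apply indel correction before SNP typing (disable to
#'   measure the uncorrected typing accuracy).
#' @param min_identity_confident alignment identity required for a confident
#'   call.
#' @return `records` with `c_call` and the `x_` columns filled.
#' @export
type_constant_regions <- function(records, strains = c("BALB", "B6"),
                                  snp_table = strain_snps(),
                                  scaffolds = c_scaffolds(strains),
                                  correct = TRUE,
                                  min_identity_confident = 0.9) {
  n <- nrow(records)
  records$c_call <- ""
  records$x_isotype <- ""
  records$x_snp_bases <- ""
  records$x_c_identity <- NA_real_
  cs <- extract_ighc(records, drop_missing = TRUE)
  ok <- !is.na(cs$c_seq) & nchar(cs$c_seq) >= 60
  if (!any(ok)) return(records)

  # classify isotype by edit distance of the leading bases to each scaffold
  # (computed once per distinct head: constant prefixes recur across reads)
  labels <- names(scaffolds)
  heads <- substr(cs$c_seq[ok], 1, 60)
  uh <- unique(heads)
  dm <- sapply(labels, function(lab)
    utils::adist(uh, substr(scaffolds[[lab]]$seq, 1, 60))[, 1])
  dm <- matrix(dm, ncol = length(labels))
  best <- max.col(-dm, ties.method = "first")
  bestd <- dm[cbind(seq_len(nrow(dm)), best)]
  iso_u <- ifelse(bestd <= 20, labels[best], "")
  iso <- iso_u[match(heads, uh)]
  records$x_isotype[ok] <- iso

  for (lab in intersect(c("IgM", "IgG2b"), labels)) {
    sel <- which(ok)[iso == lab]
    if (length(sel) == 0) next
    sc <- scaffolds[[lab]]
    st <- snp_global_offsets(snp_table, lab, sc)
    if (nrow(st) == 0) next
    # correct only the scaffold prefix that covers the typed SNPs (plus a
    # margin); downstream exons carry no typing information
    cut <- min(nchar(sc$seq), max(st$global_offset) + 60L)
    if (correct) {
      corr <- indel_correct(cs$c_seq[sel], substr(sc$seq, 1, cut),
                            band = 12)
      bases <- type_snps(corr$corrected, corr$conf, st)
      identity <- corr$identity
    } else {
      bases <- type_snps(tolower(cs$c_seq[sel]), NULL, st)
      identity <- rep(1, length(sel))
    }
    call <- assign_c_call(bases, st, strains,
                          require_all = (lab == "IgG2b"))
    confident <- rowSums(is.na(as.matrix(bases[, st$snp_id]))) == 0 &
      bases$x_snp_lowconf == 0 & identity >= min_identity_confident
    call[!confident] <- ""
    records$c_call[sel] <- ifelse(nzchar(call), paste0(lab, "*", call), "")
    records$x_snp_bases[sel] <- apply(
      as.matrix(bases[, st$snp_id, drop = FALSE]), 1,
      function(b) paste(paste0(st$snp_id, "=",
                               ifelse(is.na(b), ".", b)), collapse = ";"))
    records$x_c_identity[sel] <- identity
  }
  records
}

#' Discover strain constant-region sequences by IGHJ1 anchoring
#'
#' Restricts records to unambiguous IGHJ1 calls, tabulates their unique raw
#' constant segments per anchor allele, and returns the `top_n` most frequent
#' segments per anchor (1 recovers the IgM exons; 2 recovers the two IgG
#' subclass genes of each strain).
#'
#' @param records rearrangement tibble with J calls and sequences.
#' @param anchor_map named character vector mapping IGHJ1 allele name ->
#'   strain label.
#' @param top_n sequences to keep per anchor allele.
#' @return tibble with `anchor`, `strain`, `rank`, `count`, `c_seq`.
#' @export
discover_c_alleles_by_j_anchor <- function(records, anchor_map, top_n = 1) {
  sel <- records$j_call %in% names(anchor_map) & n_calls(records$j_call) == 1
  rec <- records[sel, , drop = FALSE]
  if (nrow(rec) == 0) {
    warning("no reads with an anchor IGHJ1 call")
    return(tibble::tibble(anchor = character(0), strain = character(0),
                          rank = integer(0), count = integer(0),
                          c_seq = character(0)))
  }
  cs <- extract_ighc(rec, drop_missing = TRUE)
  keep <- !is.na(cs$c_seq) & nzchar(cs$c_seq)
  df <- tibble::tibble(anchor = rec$j_call[keep], c_seq = cs$c_seq[keep])
  out <- df %>%
    dplyr::count(.data$anchor, .data$c_seq, name = "count") %>%
    dplyr::group_by(.data$anchor) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$c_seq,
                   .by_group = TRUE) %>%
    dplyr::slice_head(n = top_n) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup()
  out$strain <- unname(anchor_map[out$anchor])
  out[, c("anchor", "strain", "rank", "count", "c_seq")]
}

#' IGHJ1 / constant-region strain concordance
#'
#' For reads carrying both an unambiguous IGHJ1 call and a constant-region
#' strain call, computes per strain call the fraction whose IGHJ1 allele maps
#' to the same strain. One minus the concordance is a pre-filter proxy for
#' chimerism plus typing error.
#'
#' @param records rearrangement tibble with `j_call` and `c_call`.
#' @param anchor_map named character vector IGHJ1 allele -> strain.
#' @return tibble with `strain_call`, `n`, `concordant`, `concordance`.
#' @export
j_anchor_concordance <- function(records, anchor_map) {
  sel <- records$j_call %in% names(anchor_map) &
    n_calls(records$j_call) == 1 & nzchar(records$c_call)
  rec <- records[sel, , drop = FALSE]
  if (nrow(rec) == 0) stop("no reads with both an anchor J call and a c_call")
  c_strain <- sub("^[^*]*\\*", "", rec$c_call)
  j_strain <- unname(anchor_map[rec$j_call])
  tab <- tibble::tibble(strain_call = c_strain,
                        concordant = c_strain == j_strain) %>%
    dplyr::group_by(.data$strain_call) %>%
    dplyr::summarise(n = dplyr::n(),
                     concordant = sum(.data$concordant),
                     concordance = .data$concordant / .data$n)
  tab
}
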