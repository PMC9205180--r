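# Genotype inference: filtering, unique-sequence collapsing, novel-allele
# discovery by the mutation-load intercept test, presence/absence calling and
# allele reassignment.

#' Inference parameters
#'
#' @param germline_min minimum unique sequences assigned to a reference
#'   allele before novel-allele detection is attempted for it.
#' @param min_seqs minimum otherwise-unmutated supporting sequences for a
#'   novel-allele candidate.
#' @param intercept_threshold minimum fitted y-intercept of the substitution
#'   frequency vs mutation load regression.
#' @param genotype_min_support unique unmutated exact-match sequences
#'   required to call an allele present.
#' @param unmutated_max_mismatches maximum V mismatches for a sequence to
#'   count as unmutated.
#' @return a list of class `inference_params`.
#' @export
inference_params <- function(germline_min = 50, min_seqs = 10,
                             intercept_threshold = 0.125,
                             genotype_min_support = 2,
                             unmutated_max_mismatches = 0) {
  p <- as.list(environment())
  stopifnot(p$germline_min >= 1, p$min_seqs >= 1,
            p$genotype_min_support >= 1,
            p$intercept_threshold > 0, p$intercept_threshold < 1)
  class(p) <- "inference_params"
  p
}

#' Filter rearrangements for genotype inference
#'
#' Keeps records that are 5' complete (`complete_vdj`), have a junction
#' (CDR3) and a J call.
#'
#' @param records rearrangement tibble.
#' @return the filtered tibble.
#' @export
filter_rearrangements <- function(records) {
  records[records$complete_vdj & nzchar(records$junction) &
            nzchar(records$j_call), , drop = FALSE]
}

#' Collapse records to unique VDJ nucleotide sequences
#'
#' The VDJ sequence is the read from the V start through the end of the J
#' alignment. One record is kept per distinct VDJ sequence: the member with
#' the lexicographically smallest `sequence_id` represents the group and
#' `duplicate_count` sums the members' counts (conserved). Constant-region
#' calls are aggregated: groups whose members carry conflicting strain calls
#' are flagged `x_c_ambiguous` and their `c_call` cleared.
#'
#' @param records filtered rearrangement tibble.
#' @return collapsed tibble with updated `duplicate_count`, `c_call` and
#'   `x_c_ambiguous`.
#' @export
collapse_unique <- function(records) {
  if (nrow(records) == 0) {
    records$x_c_ambiguous <- logical(0)
    return(records)
  }
  vdj <- substr(records$sequence, records$v_sequence_start,
                records$j_sequence_end)
  records$.vdj <- vdj
  grp <- split(seq_len(nrow(records)), vdj)
  rep_idx <- vapply(grp, function(ix)
    ix[order(records$sequence_id[ix])[1]], integer(1))
  dup <- vapply(grp, function(ix)
    sum(records$duplicate_count[ix]), integer(1))
  calls <- lapply(grp, function(ix)
    unique(records$c_call[ix][nzchar(records$c_call[ix])]))
  strain_of <- function(cc) unique(sub("^[^*]*\\*", "", cc))
  ambig <- vapply(calls, function(cc) length(strain_of(cc)) > 1, logical(1))
  agg_call <- vapply(seq_along(grp), function(g) {
    cc <- calls[[g]]
    if (length(cc) == 0 || ambig[g]) "" else cc[1]
  }, character(1))
  out <- records[rep_idx, , drop = FALSE]
  out$duplicate_count <- unname(dup)
  out$c_call <- unname(agg_call)
  out$x_c_ambiguous <- unname(ambig)
  out$.vdj <- NULL
  out
}

#' Select unmutated records
#'
#' Keeps records whose V mismatch count is at most
#' `params$unmutated_max_mismatches` (default: exact V matches only).
#'
#' @param records rearrangement tibble with `x_v_mismatches`.
#' @param params an [inference_params()].
#' @return the subset.
#' @export
select_unmutated <- function(records, params = inference_params()) {
  records[!is.na(records$x_v_mismatches) &
            records$x_v_mismatches <= params$unmutated_max_mismatches, ,
          drop = FALSE]
}

#' Detect novel germline V alleles by the mutation-load intercept test
#'
#' For each reference allele with at least `germline_min` assigned unique
#' sequences, the fraction of sequences carrying each specific substitution
#' is regressed against the sequences' total V mismatch count over mismatch
#' bins 1..10 (bins weighted by their sequence counts). A germline
#' polymorphism appears at a constant fraction regardless of mutation load,
#' so its fitted y-intercept is large, whereas hypermutation-driven
#' substitutions extrapolate to zero at zero mutations. A substitution with
#' intercept >= `intercept_threshold` that is supported by at least
#' `min_seqs` sequences carrying it as their only V mismatch yields a
#' candidate allele (the reference with that substitution applied),
#' deduplicated against the reference set.
#'
#' @param records collapsed unique-sequence tibble (single V calls are used;
#'   records with indels in V are excluded from the profiles).
#' @param refs V [germline_set()].
#' @param params an [inference_params()].
#' @return a [germline_set()] of candidate novel alleles (possibly empty)
#'   with provenance `"inferred"`; attribute `"detail"` holds a tibble of
#'   per-candidate statistics.
#' @export
find_novel_alleles <- function(records, refs, params = inference_params()) {
  rec <- records[n_calls(records$v_call) == 1 &
                   !is.na(records$x_v_mismatches) &
                   records$x_v_nindel == 0, , drop = FALSE]
  cand_name <- character(0)
  cand_seq <- character(0)
  cand_cys <- integer(0)
  detail <- list()
  for (allele in unique(rec$v_call)) {
    sub <- rec[rec$v_call == allele, , drop = FALSE]
    if (nrow(sub) < params$germline_min) next
    ref_row <- refs[refs$name == allele, ]
    if (nrow(ref_row) == 0) next
    m <- sub$x_v_mismatches
    inbin <- m >= 1 & m <= 10
    if (!any(inbin)) next
    # long table of (sequence, substitution label) pairs over binned seqs
    widx <- which(inbin)
    muts <- lapply(sub$x_v_muts[widx], parse_muts)
    nmut <- vapply(muts, nrow, integer(1))
    if (sum(nmut) == 0) next
    long <- tibble::tibble(
      seq_idx = rep(widx, nmut),
      lab = unlist(lapply(muts, function(mm)
        if (nrow(mm) == 0) character(0) else paste0(mm$pos, ":", mm$base)))
    )
    long$m <- m[long$seq_idx]
    # only substitutions with enough single-mismatch support can qualify
    sup_tab <- table(long$lab[long$m == 1])
    cand_labs <- names(sup_tab)[sup_tab >= params$min_seqs]
    if (length(cand_labs) == 0) next
    bins <- sort(unique(m[inbin]))
    bin_n <- vapply(bins, function(b) sum(m == b), integer(1))
    for (lab in cand_labs) {
      support <- sup_tab[[lab]]
      carriers <- long$m[long$lab == lab]
      y <- vapply(bins, function(b) sum(carriers == b), numeric(1)) / bin_n
      if (length(bins) >= 2) {
        fit <- stats::lm(y ~ bins, weights = bin_n)
        intercept <- unname(stats::coef(fit)[1])
      } else {
        intercept <- y[1]
      }
      if (is.na(intercept) || intercept < params$intercept_threshold) next
      pb <- strsplit(lab, ":", fixed = TRUE)[[1]]
      pos <- as.integer(pb[1])
      newseq <- set_base(ref_row$sequence, pos, pb[2])
      if (newseq %in% refs$sequence) next
      nm <- paste0(allele, "_",
                   toupper(base_at(ref_row$sequence, pos)), pos,
                   toupper(pb[2]))
      if (nm %in% cand_name) next
      cand_name <- c(cand_name, nm)
      cand_seq <- c(cand_seq, newseq)
      cand_cys <- c(cand_cys, ref_row$cys)
      detail[[nm]] <- tibble::tibble(
        novel_allele = nm, base_allele = allele, position = pos,
        base = pb[2], intercept = intercept, support = support)
    }
  }
  out <- germline_set(cand_name, rep("V", length(cand_name)), cand_seq,
                      provenance = "inferred", cys = cand_cys,
                      label = "novel_candidates")
  attr(out, "detail") <- dplyr::bind_rows(detail)
  out
}

#' Infer the presence/absence genotype
#'
#' An allele is present when at least `genotype_min_support` unique unmutated
#' sequences match it exactly (zero V mismatches, the allele among their best
#' calls). Alleles with exactly one such sequence are listed as provisional
#' rather than present. Frequencies are computed over all reads
#' (duplicate-count weighted) assigned to each allele, tie calls split
#' evenly.
#'
#' @param records collapsed unique-sequence tibble.
#' @param refs V [germline_set()] (reference plus any accepted novels).
#' @param params an [inference_params()].
#' @return tibble with `allele`, `unmutated_support`, `total_support`,
#'   `frequency`, `present`, `note`, sorted by decreasing frequency.
#' @export
infer_genotype <- function(records, refs, params = inference_params()) {
  rec <- records[nzchar(records$v_call), , drop = FALSE]
  calls <- strsplit(rec$v_call, ",", fixed = TRUE)
  nc <- lengths(calls)
  total_reads <- sum(rec$duplicate_count)
  long <- tibble::tibble(
    allele = unlist(calls),
    seq_idx = rep(seq_len(nrow(rec)), nc),
    w = rep(rec$duplicate_count / nc, nc),
    unmut = rep(!is.na(rec$x_v_mismatches) &
                  rec$x_v_mismatches <= params$unmutated_max_mismatches, nc)
  )
  gt <- long %>%
    dplyr::group_by(.data$allele) %>%
    dplyr::summarise(
      unmutated_support = sum(.data$unmut),
      total_support = dplyr::n(),
      frequency = sum(.data$w) / total_reads) %>%
    dplyr::ungroup()
  gt <- gt[gt$allele %in% refs$name, , drop = FALSE]
  gt$present <- gt$unmutated_support >= params$genotype_min_support
  gt$note <- ifelse(gt$present, "",
                    ifelse(gt$unmutated_support == 1, "provisional",
                           "insufficient_unmutated_support"))
  dplyr::arrange(gt, dplyr::desc(.data$frequency))
}

#' Reassign alleles against the inferred genotype
#'
#' Records are re-annotated against only the alleles called present, updating
#' call strings, coordinates and mismatch counts.
#'
#' @param records rearrangement tibble.
#' @param genotype tibble from [infer_genotype()] (or a character vector of
#'   allele names).
#' @param refs the V [germline_set()] the genotype refers to.
#' @return `records` with V columns recomputed against the genotype alleles.
#' @export
reassign_alleles <- function(records, genotype, refs) {
  present <- if (is.character(genotype)) genotype
             else genotype$allele[genotype$present]
  if (length(present) == 0) stop("empty genotype")
  sub <- germline_subset(refs, intersect(present, refs$name))
  ord <- order(sub$name)
  rs <- sub$sequence[ord]
  nm <- sub$name[ord]
  res <- cpp_annotate_v(records$sequence, rs, 13L, 3L, 6L, 10L, 3L,
                        50L, 1L, -2L, -3L, 420L)
  v_call <- calls_to_names(res$call_idx, nm)
  has_v <- nzchar(v_call)
  records$v_call <- v_call
  records$v_sequence_start <- ifelse(has_v, res$q_start, NA_integer_)
  records$v_sequence_end <- ifelse(has_v, res$q_end, NA_integer_)
  records$x_v_mismatches <- ifelse(has_v, res$nsub + res$nins + res$ndel,
                                   NA_integer_)
  records$x_v_germline_start <- ifelse(has_v, res$r_start, NA_integer_)
  records$x_v_germline_end <- ifelse(has_v, res$r_end, NA_integer_)
  records$x_v_muts <- ifelse(has_v, res$muts, "")
  records$x_v_nindel <- ifelse(has_v, res$nins + res$ndel, NA_integer_)
  records
}
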