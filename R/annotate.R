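# Germline-guided VDJ annotation of primer-trimmed long reads.

#' Extract UMIs and trim primers from raw reads
#'
#' The UMI is the first `umi_length` bases. If primers are supplied, the 5'
#' primer is located (up to `max_mismatch` mismatches) near the read start and
#' removed together with everything before it; the 3' primer is located as its
#' reverse complement near the read end and removed together with everything
#' after its start. Reads in which a supplied primer cannot be located, or
#' that are shorter than UMI plus primers, are excluded with a reason.
#'
#' @param reads tibble with `read_id` and `sequence` (raw reads).
#' @param primer_5p,primer_3p primer sequences (as synthesised, 5'->3');
#'   `NULL` to skip that end.
#' @param umi_length UMI length to split off.
#' @param max_mismatch mismatches tolerated when locating a primer.
#' @return list with `reads` (kept reads: `read_id`, `umi`, `sequence`) and
#'   `excluded` (`read_id`, `reason`).
#' @export
trim_primer_umi <- function(reads, primer_5p = NULL, primer_3p = NULL,
                            umi_length = 0, max_mismatch = 2) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  seqs <- tolower(reads$sequence)
  min_len <- umi_length + nchar(primer_5p %||% "") + nchar(primer_3p %||% "")
  reason <- rep(NA_character_, n)
  reason[nchar(seqs) <= min_len] <- "too_short"
  umi <- substr(seqs, 1, umi_length)
  body <- substr(seqs, umi_length + 1, nchar(seqs))
  start <- rep(1L, n)
  end <- nchar(body)
  locate <- function(pattern, subject_head) {
    hits <- Biostrings::vmatchPattern(
      pattern, Biostrings::DNAStringSet(toupper(subject_head)),
      max.mismatch = max_mismatch, with.indels = FALSE)
    vapply(as.list(hits), function(ir) {
      if (length(ir) == 0) NA_integer_ else BiocGenerics::start(ir)[1]
    }, integer(1))
  }
  if (!is.null(primer_5p)) {
    head_len <- nchar(primer_5p) + 8L
    p <- locate(toupper(primer_5p), substr(body, 1, head_len))
    miss <- is.na(p) & is.na(reason)
    reason[miss] <- "primer_not_found"
    ok <- !is.na(p)
    start[ok] <- p[ok] + nchar(primer_5p)
  }
  if (!is.null(primer_3p)) {
    rc <- tolower(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(toupper(primer_3p)))))
    tail_len <- nchar(rc) + 8L
    tail_start <- pmax(1L, nchar(body) - tail_len + 1L)
    tails <- substr(body, tail_start, nchar(body))
    p <- locate(toupper(rc), tails)
    miss <- is.na(p) & is.na(reason)
    reason[miss] <- "primer_not_found"
    ok <- !is.na(p)
    end[ok] <- tail_start[ok] + p[ok] - 2L
  }
  keep <- is.na(reason) & end >= start
  list(
    reads = tibble::tibble(read_id = reads$read_id[keep],
                           umi = umi[keep],
                           sequence = substr(body, start, end)[keep]),
    excluded = tibble::tibble(read_id = reads$read_id[!keep],
                              reason = ifelse(is.na(reason[!keep]),
                                              "empty_after_trim",
                                              reason[!keep]))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# map call-index strings ("1,3") to sorted allele-name strings
calls_to_names <- function(call_idx, names_sorted) {
  vapply(call_idx, function(ci) {
    if (is.na(ci) || !nzchar(ci)) return("")
    paste(names_sorted[as.integer(strsplit(ci, ",", fixed = TRUE)[[1]])],
          collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

#' Align sequences against a reference segment set
#'
#' For each query, computes the best local alignment against every reference
#' allele (match +1, mismatch -2, gap -3) and reports the allele(s) achieving
#' the maximum score with an aligned reference span of at least
#' `min_overlap`. Ties are reported comma-separated in ascending name order.
#' Mismatch counts include substitutions and indels inside the aligned span;
#' unaligned overhangs (end gaps) are not counted.
#'
#' @param seqs character vector of query sequences.
#' @param refs a [germline_set()] of one segment class.
#' @param segment `"V"` or `"J"`; sets the default `min_overlap` (50 / 20).
#' @param min_overlap minimum aligned reference span for a call.
#' @param seeded use the k-mer-seeded banded path (fast, for large reference
#'   sets); the default `FALSE` scans every reference exhaustively.
#' @return tibble with `call`, `score`, `q_start`, `q_end`, `r_start`,
#'   `r_end`, `mismatches`, `nsub`, `nins`, `ndel`, `muts`.
#' @export
align_segment <- function(seqs, refs, segment = c("V", "J"),
                          min_overlap = NULL, seeded = FALSE) {
  segment <- match.arg(segment)
  if (nrow(refs) == 0) stop("empty reference set")
  min_overlap <- min_overlap %||% if (segment == "V") 50L else 20L
  ord <- order(refs$name)
  rs <- refs$sequence[ord]
  nm <- refs$name[ord]
  res <- if (seeded) {
    cpp_annotate_v(tolower(seqs), rs, 13L, 2L, 8L, 12L, 3L,
                   as.integer(min_overlap), 1L, -2L, -3L, 100000L)
  } else {
    cpp_align_exhaustive(tolower(seqs), rs, as.integer(min_overlap),
                         1L, -2L, -3L)
  }
  tibble::tibble(
    call = calls_to_names(res$call_idx, nm),
    score = res$score,
    q_start = res$q_start, q_end = res$q_end,
    r_start = res$r_start, r_end = res$r_end,
    mismatches = res$nsub + res$nins + res$ndel,
    nsub = res$nsub, nins = res$nins, ndel = res$ndel,
    muts = res$muts
  )
}

#' Annotate reads against germline V, D and J reference sets
#'
#' Produces an AIRR-style rearrangement table. The V call is made on the read
#' prefix with a k-mer-seeded banded local aligner; the J call on the window
#' following the V span; the D call by the longest ungapped match (>= 5 nt)
#' inside the junction window. The junction runs from the V reference's
#' conserved cysteine codon (the `cys` column of the V set) to the end of the
#' J tryptophan codon (`tgggg` motif). `complete_vdj` requires both V and J
#' calls with the V alignment starting at reference position <= 5.
#'
#' @param reads tibble with `read_id` and `sequence` (primer-trimmed, no
#'   UMI), or a character vector of sequences.
#' @param v_ref,d_ref,j_ref [germline_set()]s.
#' @param min_overlap_v,min_overlap_j minimum aligned reference spans.
#' @param v_complete_max_start maximum V reference start position for a read
#'   to count as 5' complete.
#' @return an AIRR-style tibble (one row per read) with standard columns
#'   (`sequence_id`, `sequence`, `v_call`, `d_call`, `j_call`, `c_call`,
#'   `junction`, coordinates, `duplicate_count`, `complete_vdj`) and tool
#'   columns prefixed `x_`.
#' @export
annotate_reads <- function(reads, v_ref, d_ref = NULL, j_ref,
                           min_overlap_v = 50, min_overlap_j = 20,
                           v_complete_max_start = 5) {
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = sprintf("seq%07d", seq_along(reads)),
                            sequence = reads)
  }
  seqs <- tolower(reads$sequence)
  n <- length(seqs)

  vord <- order(v_ref$name)
  vseqs <- v_ref$sequence[vord]
  vnames <- v_ref$name[vord]
  vcys <- v_ref$cys[vord]
  va <- cpp_annotate_v(seqs, vseqs, 13L, 3L, 6L, 10L, 3L,
                       as.integer(min_overlap_v), 1L, -2L, -3L, 420L)
  v_call <- calls_to_names(va$call_idx, vnames)
  v_first_idx <- suppressWarnings(as.integer(first_call(va$call_idx)))
  has_v <- nzchar(v_call)

  # J: search the window after the V span (whole read when V is absent)
  win_start <- ifelse(has_v, va$q_end + 1L, 1L)
  win_end <- pmin(nchar(seqs), win_start + 120L)
  jwin <- substr(seqs, win_start, win_end)
  jord <- order(j_ref$name)
  jseqs <- j_ref$sequence[jord]
  jnames <- j_ref$name[jord]
  # the J start lies within ~60 nt of the window start (N regions + trims);
  # reads whose V alignment stops early (e.g. chimeric templates) get a
  # second, wider search
  ja <- cpp_align_exhaustive(jwin, jseqs, as.integer(min_overlap_j),
                             1L, -2L, -3L, -10L, 70L)
  retry <- which(!nzchar(ja$call_idx) | is.na(ja$call_idx))
  if (length(retry) > 0) {
    win_end2 <- pmin(nchar(seqs), win_start + 400L)
    jwin2 <- substr(seqs[retry], win_start[retry], win_end2[retry])
    ja2 <- cpp_align_exhaustive(jwin2, jseqs, as.integer(min_overlap_j),
                                1L, -2L, -3L, -10L, 360L)
    for (f in names(ja)) ja[[f]][retry] <- ja2[[f]]
  }
  j_call <- calls_to_names(ja$call_idx, jnames)
  has_j <- nzchar(j_call)
  j_first_idx <- suppressWarnings(as.integer(first_call(ja$call_idx)))
  j_start <- ifelse(has_j, win_start + ja$q_start - 1L, NA_integer_)
  j_end <- ifelse(has_j, win_start + ja$q_end - 1L, NA_integer_)

  # D: ungapped match inside the junction window
  d_call <- rep("", n)
  if (!is.null(d_ref) && nrow(d_ref) > 0) {
    dwin_ok <- has_v & has_j & (j_start - va$q_end > 1)
    dwin <- ifelse(dwin_ok, substr(seqs, va$q_end + 1L, j_start - 1L), "")
    dord <- order(d_ref$name)
    da <- cpp_call_d(dwin, d_ref$sequence[dord], 5L)
    d_call <- calls_to_names(da$call_idx, d_ref$name[dord])
  }

  # junction: conserved V cysteine codon .. end of J tryptophan codon
  jtrp <- regexpr("tgggg", jseqs, fixed = TRUE)
  junction <- rep("", n)
  idx <- which(has_v & has_j)
  for (i in idx) {
    cy <- vcys[v_first_idx[i]]
    tw <- jtrp[j_first_idx[i]]
    if (is.na(cy) || tw < 0) next
    if (va$r_start[i] > cy || va$r_end[i] < cy + 2) next
    if (ja$r_start[i] > tw || ja$r_end[i] < tw + 2) next
    cys_read <- va$q_start[i] + (cy - va$r_start[i])
    trp_read <- j_start[i] + (tw - ja$r_start[i]) + 2L
    if (trp_read > cys_read) {
      junction[i] <- substr(seqs[i], cys_read, trp_read)
    }
  }

  complete_vdj <- has_v & has_j & !is.na(va$r_start) &
    va$r_start >= 1 & va$r_start <= v_complete_max_start

  tibble::tibble(
    sequence_id = reads$read_id,
    sequence = seqs,
    v_call = v_call, d_call = d_call, j_call = j_call,
    c_call = "",
    junction = junction,
    v_sequence_start = ifelse(has_v, va$q_start, NA_integer_),
    v_sequence_end = ifelse(has_v, va$q_end, NA_integer_),
    j_sequence_start = j_start,
    j_sequence_end = j_end,
    duplicate_count = 1L,
    complete_vdj = complete_vdj,
    x_umi = if ("umi" %in% names(reads)) reads$umi else "",
    x_v_mismatches = ifelse(has_v, va$nsub + va$nins + va$ndel, NA_integer_),
    x_v_germline_start = ifelse(has_v, va$r_start, NA_integer_),
    x_v_germline_end = ifelse(has_v, va$r_end, NA_integer_),
    x_v_muts = ifelse(has_v, va$muts, ""),
    x_v_nindel = ifelse(has_v, va$nins + va$ndel, NA_integer_),
    x_j_germline_start = ifelse(has_j, ja$r_start, NA_integer_),
    x_j_germline_end = ifelse(has_j, ja$r_end, NA_integer_)
  )
}
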