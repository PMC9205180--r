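# Reference-set curation: extension of truncated records, 3'-end
# confirmation from rearrangement evidence, variant labelling, export, and
# completeness evaluation.

#' Extend a truncated germline record using a full-length donor
#'
#' Finds the donor allele whose sequence contains the truncated record with
#' the fewest mismatches (overlap >= `min_overlap`, identity >= 95%) and
#' copies the donor's flanking bases onto both ends. Provenance is set to
#' `"extended"`.
#'
#' @param truncated one-row [germline_set()] (or a list with `name` and
#'   `sequence`).
#' @param donors [germline_set()] of candidate full-length donors.
#' @param min_overlap minimum aligned overlap.
#' @return a one-row [germline_set()]; attributes `"donor"`, `"ext5"`,
#'   `"ext3"` record the donor and extension lengths.
#' @export
extend_truncated_reference <- function(truncated, donors, min_overlap = 100) {
  tseq <- tolower(truncated$sequence[1])
  res <- cpp_align_exhaustive(tseq, donors$sequence,
                              as.integer(min_overlap), 1L, -2L, -3L)
  span <- res$span[1]
  if (is.na(res$call_idx[1]) || !nzchar(res$call_idx[1])) {
    stop("no_suitable_donor")
  }
  # best-scoring donor; require high identity over the overlap
  cand <- as.integer(strsplit(res$call_idx[1], ",")[[1]])
  identity <- (span - res$nsub[1]) / span
  if (identity < 0.95) stop("no_suitable_donor")
  di <- cand[1]
  donor <- donors[di, ]
  qs <- res$q_start[1]; qe <- res$q_end[1]
  rs <- res$r_start[1]; re <- res$r_end[1]
  prefix <- substr(donor$sequence, 1, rs - qs)
  suffix <- substr(donor$sequence,
                   re + (nchar(tseq) - qe) + 1, nchar(donor$sequence))
  if (nchar(prefix) == 0 && nchar(suffix) == 0) {
    stop("no_suitable_donor")          # donor does not extend the record
  }
  out <- germline_set(truncated$name[1], "V",
                      paste0(prefix, tseq, suffix),
                      functionality = truncated$functionality[1] %||% "unknown",
                      strain = truncated$strain[1] %||% NA_character_,
                      provenance = "extended")
  attr(out, "donor") <- donor$name
  attr(out, "ext5") <- nchar(prefix)
  attr(out, "ext3") <- nchar(suffix)
  out
}

#' Confirm or revise the 3' end of a V allele from rearrangement evidence
#'
#' Exonuclease trimming removes a geometric number of 3' bases, so the
#' fraction of unmutated reads whose alignment reaches each terminal
#' reference position decays smoothly for a correct reference end. The end is
#' extended while reads aligned through the current end show a dominant
#' (>= `dominant_min`) next nucleotide, and trailing reference positions are
#' trimmed while they are reached by fewer than `reach_min` of reads and the
#' reads stopping just short of them do not support the reference base.
#'
#' @param v_allele allele name.
#' @param records rearrangement tibble (unmutated records with a single call
#'   of `v_allele` are used).
#' @param refs V [germline_set()] containing `v_allele`.
#' @param min_depth minimum assigned sequences for a verdict.
#' @param dominant_min dominant-nucleotide fraction for extension/support.
#' @param reach_min reach fraction below which a terminal position is a trim
#'   candidate.
#' @param max_scan terminal positions examined.
#' @return list of class `end_profile` with `v_allele`, `verdict`
#'   (`confirmed`, `extend_by_k`, `trim_by_k`, `inconclusive`), `k`,
#'   `extension` (bases, for extensions) and a per-position `profile` tibble.
#' @export
confirm_3prime_ends <- function(v_allele, records, refs, min_depth = 20,
                                dominant_min = 0.6, reach_min = 0.1,
                                max_scan = 10) {
  ref_row <- refs[refs$name == v_allele, ]
  if (nrow(ref_row) == 0) stop("unknown allele: ", v_allele)
  L <- nchar(ref_row$sequence)
  rec <- records[records$v_call == v_allele &
                   !is.na(records$x_v_mismatches) &
                   records$x_v_mismatches == 0, , drop = FALSE]
  n <- nrow(rec)
  positions <- seq(max(1L, L - max_scan + 1L), L)
  prof <- tibble::tibble(
    position = positions,
    reach_count = vapply(positions, function(j)
      sum(rec$x_v_germline_end >= j), integer(1)))
  prof$reach_frac <- if (n > 0) prof$reach_count / n else NA_real_
  out <- list(v_allele = v_allele, verdict = "inconclusive", k = 0L,
              extension = "", profile = prof, n = n)
  class(out) <- "end_profile"
  if (n < min_depth) return(out)

  next_base_frac <- function(sub, offset, target = NULL) {
    # distribution of the read base `offset` past the aligned end
    pos <- sub$v_sequence_end + offset
    ok <- pos <= nchar(sub$sequence)
    b <- substr(sub$sequence[ok], pos[ok], pos[ok])
    if (length(b) == 0) return(list(n = 0L, base = NA, frac = 0))
    tb <- sort(table(b), decreasing = TRUE)
    if (!is.null(target)) {
      return(list(n = length(b), base = target,
                  frac = sum(b == target) / length(b)))
    }
    list(n = length(b), base = names(tb)[1], frac = tb[[1]] / length(b))
  }

  # extension: reads aligned through the current reference end
  at_end <- rec[rec$x_v_germline_end == L, , drop = FALSE]
  k_ext <- 0L
  ext <- character(0)
  while (nrow(at_end) >= max(10, min_depth / 2)) {
    nb <- next_base_frac(at_end, k_ext + 1L)
    if (nb$n < max(10, min_depth / 2) || nb$frac < dominant_min) break
    k_ext <- k_ext + 1L
    ext <- c(ext, nb$base)
  }
  if (k_ext > 0) {
    out$verdict <- paste0("extend_by_", k_ext)
    out$k <- k_ext
    out$extension <- paste(ext, collapse = "")
    return(out)
  }

  # trimming: trailing positions unreached and unsupported
  k_trim <- 0L
  for (j in seq(L, max(1L, L - max_scan + 1L))) {
    reach <- sum(rec$x_v_germline_end >= j) / n
    if (reach >= reach_min) break
    boundary <- rec[rec$x_v_germline_end == j - 1L, , drop = FALSE]
    supported <- FALSE
    if (nrow(boundary) >= 5) {
      nb <- next_base_frac(boundary, 1L,
                           target = base_at(ref_row$sequence, j))
      supported <- nb$frac >= dominant_min
    }
    if (supported) break
    k_trim <- k_trim + 1L
  }
  if (k_trim > 0) {
    out$verdict <- paste0("trim_by_", k_trim)
    out$k <- k_trim
  } else {
    out$verdict <- "confirmed"
  }
  out
}

#' Positions and labels of differences between two equal-length sequences
#'
#' @param seq_a,seq_b equal-length DNA sequences.
#' @return tibble with 1-based `position`, bases `a` and `b`, and `label`
#'   of the form `C100T` (upper-case).
#' @export
pairwise_diff <- function(seq_a, seq_b) {
  a <- tolower(seq_a); b <- tolower(seq_b)
  if (nchar(a) != nchar(b)) {
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b),
         "); align them first")
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  tibble::tibble(position = pos, a = ca[pos], b = cb[pos],
                 label = paste0(toupper(ca[pos]), pos, toupper(cb[pos])))
}

#' Export per-strain reference sets
#'
#' Writes one FASTA per anchor chromosome containing the genotype alleles
#' assigned to it (shared alleles in both), a side FASTA of genotype alleles
#' that could not be haplotyped, and a metadata table.
#'
#' @param genotype tibble from [infer_genotype()].
#' @param haplotype tibble from [infer_haplotype()].
#' @param refs V [germline_set()] with the allele sequences.
#' @param dir output directory.
#' @return list with the per-strain `paths`, the `unassigned` path and the
#'   `metadata` tibble.
#' @export
export_reference_set <- function(genotype, haplotype, refs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  present <- genotype$allele[genotype$present]
  hp <- haplotype[match(present, haplotype$v_allele), ]
  anchors <- c(haplotype$anchorA[1], haplotype$anchorB[1])
  meta <- tibble::tibble(
    allele = present,
    unmutated_support = genotype$unmutated_support[genotype$present],
    frequency = genotype$frequency[genotype$present],
    count_anchorA = hp$count_anchorA, count_anchorB = hp$count_anchorB,
    assignment = ifelse(is.na(hp$assignment), "unknown", hp$assignment),
    deleted_on = hp$deleted_on,
    provenance = refs$provenance[match(present, refs$name)]
  )
  paths <- setNames(file.path(dir, paste0(anchors, "_IGHV.fasta")), anchors)
  sel <- list(
    meta$assignment %in% c("anchorA_only", "both"),
    meta$assignment %in% c("anchorB_only", "both")
  )
  for (i in 1:2) {
    alleles <- meta$allele[sel[[i]]]
    gs <- germline_subset(refs, alleles)
    gs$strain <- anchors[i]
    write_germline_fasta(gs, paths[[i]])
  }
  un <- meta$allele[meta$assignment == "unknown"]
  unpath <- file.path(dir, "unassigned_IGHV.fasta")
  write_germline_fasta(germline_subset(refs, un), unpath)
  list(paths = paths, unassigned = unpath, metadata = meta)
}

#' Search a genome assembly for reference alleles
#'
#' Marks each allele present when a full-length match with at most
#' `max_mismatches` mismatches exists on either strand of any contig.
#'
#' @param refset [germline_set()] of alleles.
#' @param assembly a `DNAStringSet` of contigs or a FASTA path.
#' @param max_mismatches mismatches tolerated in a full-length hit.
#' @return tibble with `allele`, `present`, `n_hits`; attribute
#'   `"fraction_present"`.
#' @export
search_assembly <- function(refset, assembly, max_mismatches = 0) {
  if (is.character(assembly)) {
    assembly <- Biostrings::readDNAStringSet(assembly)
  }
  if (length(assembly) == 0) stop("empty assembly")
  hits <- vapply(refset$sequence, function(s) {
    pat <- Biostrings::DNAString(toupper(s))
    fwd <- sum(Biostrings::vcountPattern(pat, assembly,
                                         max.mismatch = max_mismatches))
    rev <- sum(Biostrings::vcountPattern(
      Biostrings::reverseComplement(pat), assembly,
      max.mismatch = max_mismatches))
    fwd + rev
  }, numeric(1), USE.NAMES = FALSE)
  out <- tibble::tibble(allele = refset$name, present = hits > 0,
                        n_hits = as.integer(hits))
  attr(out, "fraction_present") <- mean(out$present)
  out
}

#' Distribution of per-read V mismatch counts against a reference set
#'
#' Re-annotates records against `refset` (when given) and histograms the
#' best-alignment V mismatch counts over bins 0..30 and 30+, weighted by
#' duplicate count. The bin-0 mass is the unmutated fraction, the key
#' measure of reference-set completeness.
#'
#' @param records rearrangement tibble.
#' @param refset optional V [germline_set()] to re-annotate against; when
#'   `NULL` the existing `x_v_mismatches` are used.
#' @return tibble with `bin` (`"0"`..`"30"`, `"30+"`), `count`, `fraction`;
#'   attribute `"unmutated_fraction"`.
#' @export
mismatch_distribution <- function(records, refset = NULL) {
  if (!is.null(refset)) {
    records <- reassign_alleles(records, refset$name, refset)
  }
  mm <- records$x_v_mismatches[nzchar(records$v_call)]
  w <- records$duplicate_count[nzchar(records$v_call)]
  ok <- !is.na(mm)
  mm <- mm[ok]; w <- w[ok]
  binlab <- c(as.character(0:30), "30+")
  bins <- ifelse(mm > 30, "30+", as.character(mm))
  count <- vapply(binlab, function(b) sum(w[bins == b]), numeric(1))
  out <- tibble::tibble(bin = binlab, count = as.integer(count),
                        fraction = if (sum(count) > 0) count / sum(count)
                                   else rep(0, length(count)))
  attr(out, "unmutated_fraction") <- out$fraction[1]
  out
}
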