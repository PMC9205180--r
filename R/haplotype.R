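# Chromosome haplotyping of V alleles via the constant-region anchor.

#' Prepare records for haplotype inference
#'
#' Keeps unique sequences that are unmutated (zero V mismatches), observed
#' more than once (`duplicate_count > 1`), carry an unambiguous
#' constant-region strain call for the anchor gene, and have a single V
#' call. Sequences whose duplicates were associated with both anchors
#' (`x_c_ambiguous`) are excluded, as are multi-allele V ties (their count is
#' recorded in attribute `"excluded_multicall"`).
#'
#' @param records collapsed unique-sequence tibble with `c_call`.
#' @param anchor_gene constant gene used as anchor (default `"IgM"`).
#' @return the prepared subset.
#' @export
prepare_haplotype_input <- function(records, anchor_gene = "IgM") {
  has_anchor <- startsWith(records$c_call, paste0(anchor_gene, "*"))
  ambig <- if ("x_c_ambiguous" %in% names(records)) records$x_c_ambiguous
           else FALSE
  base_keep <- has_anchor & !ambig &
    !is.na(records$x_v_mismatches) & records$x_v_mismatches == 0 &
    records$duplicate_count > 1
  multi <- base_keep & n_calls(records$v_call) > 1
  out <- records[base_keep & !multi, , drop = FALSE]
  attr(out, "excluded_multicall") <- sum(multi)
  out
}

#' Infer per-allele chromosome haplotypes
#'
#' Counts, for every V allele, the unique prepared sequences on each anchor
#' chromosome. With n = nA + nB and the minor fraction q = min(nA, nB) / n:
#' alleles with q >= `kThreDel` and minor support >= `min_minor_support` are
#' assigned to both chromosomes; alleles with q < `kThreDel` are assigned to
#' the major anchor alone (the minor anchor is called deleted) when the
#' certainty -- the log10 ratio of binomial likelihoods under a
#' single-chromosome model with leak `epsilon` versus a both-chromosomes
#' model with p = 0.5 -- reaches `certainty_min`; everything else is
#' `unknown`. Each allele is scored independently and the both-model prior is
#' symmetric (no usage weighting).
#'
#' @param records prepared tibble from [prepare_haplotype_input()].
#' @param anchors the two anchor strain labels (defaults to the strains seen
#'   in `c_call`, sorted).
#' @param alleles alleles to report on (default: those present in
#'   `records`); alleles without prepared records are returned `unknown`.
#' @param kThreDel minor-to-total fraction below which the minor chromosome
#'   is a deletion candidate.
#' @param certainty_min minimum certainty (orders of magnitude) for a
#'   single-anchor assignment.
#' @param epsilon leak probability of the single-chromosome model, absorbing
#'   residual chimerism and typing error.
#' @param min_minor_support minimum minor-anchor unique sequences for a
#'   `both` call (a single stray sequence cannot overturn a deletion).
#' @return tibble with `v_allele`, `anchorA`, `anchorB`, `count_anchorA`,
#'   `count_anchorB`, `assignment`, `deleted_on`, `certainty`, `kThreDel`.
#' @export
infer_haplotype <- function(records, anchors = NULL, kThreDel = 0.1,
                            certainty_min = 2, epsilon = 0.01,
                            min_minor_support = 2, alleles = NULL) {
  strain <- sub("^[^*]*\\*", "", records$c_call)
  if (is.null(anchors)) anchors <- sort(unique(strain))
  stopifnot(length(anchors) == 2)
  alleles <- sort(unique(c(records$v_call, alleles)))
  nA <- vapply(alleles, function(a)
    sum(records$v_call == a & strain == anchors[1]), integer(1),
    USE.NAMES = FALSE)
  nB <- vapply(alleles, function(a)
    sum(records$v_call == a & strain == anchors[2]), integer(1),
    USE.NAMES = FALSE)
  hap_call <- function(na, nb) {
    n <- na + nb
    if (n == 0) {
      return(list(assignment = "unknown", deleted_on = NA_character_,
                  certainty = NA_real_))
    }
    minor <- min(na, nb); major <- max(na, nb)
    cert <- minor * log10(epsilon / 0.5) + major * log10((1 - epsilon) / 0.5)
    q <- minor / n
    if (q >= kThreDel && minor >= min_minor_support) {
      return(list(assignment = "both", deleted_on = NA_character_,
                  certainty = cert))
    }
    if (q < kThreDel && cert >= certainty_min) {
      if (na >= nb) {
        return(list(assignment = "anchorA_only", deleted_on = anchors[2],
                    certainty = cert))
      }
      return(list(assignment = "anchorB_only", deleted_on = anchors[1],
                  certainty = cert))
    }
    list(assignment = "unknown", deleted_on = NA_character_, certainty = cert)
  }
  res <- Map(hap_call, nA, nB)
  tibble::tibble(
    v_allele = alleles,
    anchorA = anchors[1], anchorB = anchors[2],
    count_anchorA = nA, count_anchorB = nB,
    assignment = vapply(res, `[[`, character(1), "assignment"),
    deleted_on = vapply(res, `[[`, character(1), "deleted_on"),
    certainty = vapply(res, `[[`, numeric(1), "certainty"),
    kThreDel = kThreDel
  )
}

#' Estimate residual (post-filter) chimerism
#'
#' Counts prepared records whose V allele was assigned to a single anchor but
#' whose own constant-region call is the opposite anchor: after the haplotype
#' filters, such V/C strain discordance indicates PCR chimerism (or residual
#' typing error).
#'
#' @param records prepared tibble from [prepare_haplotype_input()].
#' @param haplotype tibble from [infer_haplotype()].
#' @return list with `count`, `n` (prepared records) and `fraction`.
#' @export
estimate_chimerism <- function(records, haplotype) {
  strain <- sub("^[^*]*\\*", "", records$c_call)
  hp <- haplotype[match(records$v_call, haplotype$v_allele), ]
  discord <- (hp$assignment == "anchorA_only" & strain == hp$anchorB) |
    (hp$assignment == "anchorB_only" & strain == hp$anchorA)
  discord[is.na(discord)] <- FALSE
  list(count = sum(discord), n = nrow(records),
       fraction = if (nrow(records) > 0) sum(discord) / nrow(records) else 0)
}

#' Per-chromosome allele usage
#'
#' For each anchor chromosome, the frequency of each V allele among that
#' anchor's prepared records. Frequencies within an anchor sum to 1; shared
#' alleles appear under both anchors.
#'
#' @param records prepared tibble from [prepare_haplotype_input()].
#' @param haplotype tibble from [infer_haplotype()] (used for the anchor
#'   labels).
#' @return tibble with `anchor`, `v_allele`, `count`, `frequency`.
#' @export
usage_by_chromosome <- function(records, haplotype) {
  anchors <- c(haplotype$anchorA[1], haplotype$anchorB[1])
  strain <- sub("^[^*]*\\*", "", records$c_call)
  out <- lapply(anchors, function(a) {
    sub <- records[strain == a, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble::tibble(anchor = character(0), v_allele = character(0),
                            count = integer(0), frequency = numeric(0)))
    }
    tab <- table(sub$v_call)
    tibble::tibble(anchor = a, v_allele = names(tab),
                   count = as.integer(tab),
                   frequency = as.integer(tab) / nrow(sub))
  })
  dplyr::bind_rows(out)
}
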