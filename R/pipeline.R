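# End-to-end driver: annotate -> type constant regions -> filter/collapse ->
# genotype -> reassign -> haplotype.

#' Run the full F1 inference pipeline on a read set
#'
#' Convenience driver chaining [annotate_reads()],
#' [type_constant_regions()], [filter_rearrangements()],
#' [collapse_unique()], optionally [find_novel_alleles()],
#' [infer_genotype()], [reassign_alleles()], [prepare_haplotype_input()],
#' [infer_haplotype()], [estimate_chimerism()] and [usage_by_chromosome()].
#'
#' @param reads tibble with `read_id` and `sequence` (primer-trimmed, no
#'   UMI).
#' @param v_ref,d_ref,j_ref germline reference sets used for annotation.
#' @param strains the two strain labels (anchor A, anchor B).
#' @param snp_table strain SNP table (see [strain_snps()]).
#' @param scaffolds constant-region scaffolds (see [c_scaffolds()]).
#' @param params an [inference_params()].
#' @param detect_novel run novel-allele detection and add accepted candidates
#'   to the reference before genotyping.
#' @param anchor_gene constant gene used as the haplotype anchor.
#' @return list with `airr` (per-read annotations), `collapsed` (unique
#'   sequences after reassignment), `novel`, `genotype`, `prepared`,
#'   `haplotype`, `chimerism`, `usage`, and the final `v_ref`.
#' @export
run_f1_pipeline <- function(reads, v_ref, d_ref, j_ref,
                            strains = c("BALB", "B6"),
                            snp_table = strain_snps(),
                            scaffolds = c_scaffolds(strains),
                            params = inference_params(),
                            detect_novel = FALSE,
                            anchor_gene = "IgM") {
  airr <- annotate_reads(reads, v_ref, d_ref, j_ref)
  airr <- type_constant_regions(airr, strains = strains,
                                snp_table = snp_table,
                                scaffolds = scaffolds)
  flt <- filter_rearrangements(airr)
  collapsed <- collapse_unique(flt)
  novel <- NULL
  if (detect_novel) {
    unmut_pool <- collapsed
    novel <- find_novel_alleles(unmut_pool, v_ref, params)
    if (nrow(novel) > 0) {
      v_ref <- dplyr::bind_rows(v_ref, novel)
      class(v_ref) <- c("germline_set", class(tibble::tibble()))
      collapsed <- reassign_alleles(collapsed, v_ref$name, v_ref)
    }
  }
  genotype <- infer_genotype(collapsed, v_ref, params)
  present <- genotype$allele[genotype$present]
  if (length(present) > 0) {
    collapsed <- reassign_alleles(collapsed, genotype, v_ref)
  }
  prepared <- prepare_haplotype_input(collapsed, anchor_gene = anchor_gene)
  haplotype <- infer_haplotype(prepared, anchors = strains,
                               alleles = present)
  chimerism <- estimate_chimerism(prepared, haplotype)
  usage <- usage_by_chromosome(prepared, haplotype)
  list(airr = airr, collapsed = collapsed, novel = novel,
       genotype = genotype, prepared = prepared, haplotype = haplotype,
       chimerism = chimerism, usage = usage, v_ref = v_ref)
}

#' Combine the two parental haplotypes into annotation reference sets
#'
#' Takes the union (by allele name) of the V, D and J sets of the two
#' parental haplotypes -- the reference a real study would assemble from
#' strain databases before annotating F1 reads.
#'
#' @param haps pair of haplotypes from [build_parental_haplotypes()].
#' @return list with `v`, `d`, `j` [germline_set()]s.
#' @export
combine_haplotype_references <- function(haps) {
  comb <- function(get) {
    x <- dplyr::bind_rows(lapply(haps, get))
    x <- x[!duplicated(x$name), , drop = FALSE]
    class(x) <- c("germline_set", class(tibble::tibble()))
    x
  }
  list(v = comb(function(h) h$v),
       d = comb(function(h) h$d),
       j = comb(function(h) h$j))
}
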