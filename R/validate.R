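# Parameter-recovery validation: run the generator and the full pipeline and
# score the inference against the planted truth. These drivers back the
# package's acceptance checks and are useful for benchmarking configuration
# changes.

#' Plant a novel germline V allele into a parental haplotype
#'
#' Adds a 1-SNP variant of an existing strain-A allele to the haplotype (the
#' variant is expressed by the simulator but deliberately absent from the
#' annotation reference), emulating an unreported germline polymorphism.
#'
#' @param haps pair from [build_parental_haplotypes()].
#' @param usage F1-wide expression of the variant (its per-haplotype weight
#'   is twice this).
#' @param position substituted position within the donor allele.
#' @param donor_rank usage rank (within strain A's exclusive alleles) of the
#'   allele the variant derives from; high ranks give the base allele enough
#'   assigned sequences for detection.
#' @return list with modified `haps` and `variant` (name, donor, position,
#'   sequence).
#' @export
plant_novel_allele <- function(haps, usage = 0.004, position = 150,
                               donor_rank = 90) {
  hapA <- haps[[1]]
  excl <- hapA$v$name[!hapA$v$name %in% haps[[2]]$v$name]
  w <- hapA$usage$v[excl]
  donor <- names(sort(w))[min(donor_rank, length(w))]
  dseq <- hapA$v$sequence[hapA$v$name == donor]
  old <- base_at(dseq, position)
  new <- c(a = "c", c = "g", g = "t", t = "a")[[old]]
  vseq <- set_base(dseq, position, new)
  vname <- "plantedIGHVnov01"
  row <- hapA$v[hapA$v$name == donor, ]
  row$name <- vname
  row$sequence <- vseq
  row$provenance <- "inferred"
  hapA$v <- dplyr::bind_rows(hapA$v, row)
  u <- 2 * usage
  hapA$usage$v <- c(hapA$usage$v * (1 - u), setNames(u, vname))
  haps[[1]] <- hapA
  list(haps = haps,
       variant = list(name = vname, donor = donor, position = position,
                      ref_base = old, alt_base = new, sequence = vseq))
}

#' Generate decoy V alleles absent from the simulated repertoire
#'
#' Decoys are existing alleles mutated at `n_mut` positions; they populate the
#' annotation reference so that false-presence calls are detectable.
#'
#' @param v_ref V [germline_set()].
#' @param n number of decoys.
#' @param n_mut substitutions per decoy.
#' @param seed RNG seed.
#' @return a [germline_set()] of decoys named `decoyIGHVxx`.
#' @export
make_decoy_alleles <- function(v_ref, n = 20, n_mut = 8, seed = 1) {
  set.seed(derive_seed(seed, 4L))
  src <- v_ref$sequence[rep_len(seq_len(nrow(v_ref)), n)]
  cys <- v_ref$cys[rep_len(seq_len(nrow(v_ref)), n)]
  seqs <- vapply(src, function(s) {
    repeat {
      out <- mutate_positions(s, sample.int(nchar(s) - 20L, 8L))
      if (!out %in% v_ref$sequence) return(out)
    }
  }, character(1), USE.NAMES = FALSE)
  germline_set(sprintf("decoyIGHV%02d", seq_len(n)), "V", seqs,
               provenance = "reported", cys = cys, label = "decoys")
}

#' Simulate an F1 repertoire and score end-to-end recovery
#'
#' Builds the parental haplotypes, optionally plants a novel 1-SNP variant,
#' simulates reads, runs the full pipeline (with decoy alleles in the
#' reference and novel-allele detection on), and scores genotype
#' sensitivity/false calls, novel-allele detection, haplotype assignment,
#' shared-allele recovery, chimerism, and constant-region typing against the
#' planted truth. Alleles are matched by sequence so that detected novel
#' candidates count regardless of their derived name.
#'
#' @param seed simulation seed.
#' @param n_reads reads to simulate.
#' @param n_decoys decoy alleles added to the annotation reference.
#' @param plant_novel plant the 1-SNP variant?
#' @param detect_novel run novel-allele detection (defaults to
#'   `plant_novel`; enable without planting to measure false detections).
#' @param novel_usage F1-wide usage of the planted variant.
#' @param config_overrides named list of [sim_config()] arguments to
#'   override.
#' @return a list of metrics (see the methods vignette).
#' @export
validate_recovery <- function(seed, n_reads = 50000, n_decoys = 20,
                              plant_novel = TRUE, detect_novel = plant_novel,
                              novel_usage = 0.004,
                              config_overrides = list()) {
  args <- c(list(n_reads = n_reads, seed = seed), config_overrides)
  cfg <- do.call(sim_config, args)
  haps <- build_parental_haplotypes(cfg)
  shared <- attr(haps, "shared_names")
  refs <- combine_haplotype_references(haps)   # reference lacks the variant
  variant <- NULL
  if (plant_novel) {
    pl <- plant_novel_allele(haps, usage = novel_usage)
    haps <- pl$haps
    variant <- pl$variant
  }
  v_ref <- refs$v
  if (n_decoys > 0) {
    v_ref <- dplyr::bind_rows(v_ref, make_decoy_alleles(refs$v, n_decoys,
                                                        seed = seed))
    class(v_ref) <- c("germline_set", class(tibble::tibble()))
  }
  sim <- simulate_f1(haps, cfg)
  res <- run_f1_pipeline(sim$reads, v_ref, refs$d, refs$j,
                         strains = cfg$strains,
                         detect_novel = detect_novel)

  # planted truth: name, sequence, F1-wide usage, chromosome membership
  strains <- cfg$strains
  wA <- haps[[1]]$usage$v / 2
  wB <- haps[[2]]$usage$v / 2
  all_names <- union(names(wA), names(wB))
  f1_usage <- setNames(rep(0, length(all_names)), all_names)
  f1_usage[names(wA)] <- f1_usage[names(wA)] + wA
  f1_usage[names(wB)] <- f1_usage[names(wB)] + wB
  planted <- dplyr::bind_rows(haps[[1]]$v, haps[[2]]$v)
  planted <- planted[!duplicated(planted$name), c("name", "sequence")]
  planted$usage <- f1_usage[planted$name]
  planted$chromosome <- ifelse(
    planted$name %in% shared, "both",
    ifelse(planted$name %in% haps[[1]]$v$name, "anchorA_only",
           "anchorB_only"))

  gt <- res$genotype
  called <- gt$allele[gt$present]
  called_seqs <- res$v_ref$sequence[match(called, res$v_ref$name)]
  hi <- planted[planted$usage >= 5e-4, ]
  sensitivity <- mean(hi$sequence %in% called_seqs)
  false_alleles <- sum(!called_seqs %in% planted$sequence)

  novel_detected <- NA
  novel_support <- NA_integer_
  if (detect_novel && !is.null(res$novel)) {
    novel_detected <- if (plant_novel) {
      variant$sequence %in% res$novel$sequence
    } else NA
    det <- attr(res$novel, "detail")
    if (plant_novel && !is.null(det) && nrow(det) > 0) {
      nm <- res$novel$name[match(variant$sequence, res$novel$sequence)]
      if (!is.na(nm) && nm %in% det$novel_allele) {
        novel_support <- det$support[det$novel_allele == nm]
      }
    }
    spurious_novels <- sum(!res$novel$sequence %in% planted$sequence)
  } else {
    spurious_novels <- NA_integer_
  }

  # haplotype scoring (alleles matched to planted truth by sequence)
  hp <- res$haplotype
  hp$n <- hp$count_anchorA + hp$count_anchorB
  hp$seq <- res$v_ref$sequence[match(hp$v_allele, res$v_ref$name)]
  hp$truth <- planted$chromosome[match(hp$seq, planted$sequence)]
  h8 <- hp[hp$n >= 8 & !is.na(hp$truth), ]
  hap_accuracy <- if (nrow(h8) > 0) mean(h8$assignment == h8$truth) else NA
  both_seqs <- hp$seq[hp$assignment == "both"]
  shared_seqs <- planted$sequence[planted$name %in% shared]
  shared_called_both <- sum(shared_seqs %in% both_seqs)
  nonshared_called_both <- sum(!both_seqs %in% shared_seqs)

  # chimerism: estimate vs planted truth among prepared records
  tr <- sim$truth
  prep_truth <- tr[match(res$prepared$sequence_id, tr$read_id), ]
  chim_truth <- mean(prep_truth$is_chimera)
  chim_est <- res$chimerism$fraction

  # constant typing accuracy (corrected path) on non-chimeric IgM reads
  airr <- res$airr
  idx <- !tr$is_chimera & tr$c_gene == "IgM"
  calledc <- idx & nzchar(airr$c_call)
  snp_accuracy <- mean(sub("^[^*]*\\*", "", airr$c_call[calledc]) ==
                         tr$chromosome[calledc])

  # pre-filter V/C strain discordance (chimera proxy)
  excl_of <- function(nm) ifelse(
    nm %in% shared, NA_character_,
    ifelse(nm %in% haps[[1]]$v$name, strains[1],
           ifelse(nm %in% haps[[2]]$v$name, strains[2], NA_character_)))
  single_v <- n_calls(airr$v_call) == 1 & nzchar(airr$c_call)
  vstr <- excl_of(first_call(airr$v_call))
  cstr <- sub("^[^*]*\\*", "", airr$c_call)
  okd <- single_v & !is.na(vstr)
  prefilter_discordance <- mean(vstr[okd] != cstr[okd])

  conc <- tryCatch(
    j_anchor_concordance(airr, setNames(strains,
                                        c("IGHJ1*01", "IGHJ1*03"))),
    error = function(e) NULL)

  list(seed = seed, n_reads = n_reads,
       planted = planted,
       sensitivity = sensitivity, n_hi = nrow(hi),
       false_alleles = false_alleles,
       novel_detected = novel_detected, novel_support = novel_support,
       spurious_novels = spurious_novels,
       hap_accuracy = hap_accuracy, n_hap8 = nrow(h8),
       shared_called_both = shared_called_both,
       nonshared_called_both = nonshared_called_both,
       chimerism_truth = chim_truth, chimerism_estimate = chim_est,
       n_prepared = nrow(res$prepared),
       snp_accuracy = snp_accuracy,
       prefilter_discordance = prefilter_discordance,
       j_concordance = conc,
       genotype = gt, haplotype = hp)
}

#' Score constant-region SNP typing with and without indel correction
#'
#' Simulates an F1 read set, annotates it, and types the IGHM strain SNP both
#' through the indel-correction path and directly on the raw extracted
#' segments, scoring each against the planted chromosome of origin of
#' non-chimeric IgM reads.
#'
#' @param seed simulation seed.
#' @param n_reads reads to simulate.
#' @return list with `corrected` / `uncorrected` accuracies and call rates.
#' @export
validate_snp_typing <- function(seed, n_reads = 4000) {
  cfg <- sim_config(n_reads = n_reads, seed = seed)
  haps <- build_parental_haplotypes(cfg)
  sim <- simulate_f1(haps, cfg)
  refs <- combine_haplotype_references(haps)
  airr <- annotate_reads(sim$reads, refs$v, refs$d, refs$j)
  tr <- sim$truth
  idx <- !tr$is_chimera & tr$c_gene == "IgM"
  score <- function(correct) {
    a2 <- type_constant_regions(airr, strains = cfg$strains,
                                correct = correct)
    calledc <- idx & nzchar(a2$c_call)
    list(accuracy = mean(sub("^[^*]*\\*", "", a2$c_call[calledc]) ==
                           tr$chromosome[calledc]),
         call_rate = mean(nzchar(a2$c_call[idx])))
  }
  co <- score(TRUE)
  un <- score(FALSE)
  list(corrected = co$accuracy, corrected_call_rate = co$call_rate,
       uncorrected = un$accuracy, uncorrected_call_rate = un$call_rate,
       n_igm = sum(idx))
}

#' Score reference-set completeness evaluation by allele deletion
#'
#' Simulates an error-free, mutation-free repertoire, removes one planted
#' allele (chosen so that its nearest neighbour is unambiguous and its
#' differing positions sit away from the segment ends) from the reference,
#' and measures the mismatch-histogram spike that appears at the allele's
#' nearest-neighbour distance, then confirms the mass returns to bin 0 when
#' the allele is restored.
#'
#' @param seed simulation seed.
#' @param n_reads reads to simulate.
#' @return list with the planted distance `d`, the observed and expected
#'   spike masses, and the restored distribution's bin-0 masses.
#' @export
validate_reference_eval <- function(seed, n_reads = 10000) {
  cfg <- sim_config(n_reads = n_reads, seed = seed,
                    subst_error_rate = 0, homopolymer_indel_rate = 0,
                    shm_rate_igm = 0, shm_rate_igg = 0,
                    igm_unmutated_prob = 1, chimera_rate = 0,
                    trim_mean_v3 = 0)
  haps <- build_parental_haplotypes(cfg)
  refs <- combine_haplotype_references(haps)
  v <- refs$v
  # candidate targets: mid/high usage, nearest neighbour unique and interior
  wA <- haps[[1]]$usage$v / 2
  lens <- nchar(v$sequence)
  target <- NULL
  for (nm in names(sort(wA, decreasing = TRUE))) {
    if (!nm %in% v$name) next
    if (wA[nm] < 0.005 || wA[nm] > 0.04) next
    ts <- v$sequence[v$name == nm]
    same_len <- which(lens == nchar(ts) & v$name != nm)
    if (length(same_len) == 0) next
    dd <- vapply(v$sequence[same_len], function(s) hamming(ts, s), numeric(1))
    o <- order(dd)
    d1 <- dd[o[1]]
    if (d1 < 2) next
    if (length(dd) > 1 && dd[o[2]] == d1) next       # ambiguous neighbour
    diffs <- pairwise_diff(ts, v$sequence[same_len[o[1]]])$position
    if (min(diffs) < 8 || max(diffs) > nchar(ts) - 12) next
    target <- nm
    d <- as.integer(d1)
    break
  }
  if (is.null(target)) stop("no suitable target allele found")
  sim <- simulate_f1(haps, cfg)
  tr <- sim$truth
  v_minus <- v[v$name != target, ]
  class(v_minus) <- c("germline_set", class(tibble::tibble()))
  airr <- annotate_reads(sim$reads, v_minus, refs$d, refs$j)
  md <- mismatch_distribution(airr)
  spike_mass <- md$fraction[md$bin == as.character(d)]
  expected_mass <- mean(tr$v_call == target)
  airr_full <- annotate_reads(sim$reads, v, refs$d, refs$j)
  md_full <- mismatch_distribution(airr_full)
  list(target = target, d = d,
       spike_mass = spike_mass, expected_mass = expected_mass,
       n = nrow(airr),
       bin0_minus = md$fraction[md$bin == "0"],
       bin0_full = md_full$fraction[md_full$bin == "0"],
       spike_full = md_full$fraction[md_full$bin == as.character(d)])
}
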