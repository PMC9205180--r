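# Synthetic F1 VDJ-C repertoire generator with full ground truth.

#' Simulation configuration
#'
#' Parameters of the synthetic F1 repertoire. Defaults emulate the study
#' conditions the inference pipeline assumes: two homozygous parental IGH
#' haplotypes of 100 IGHV alleles each with 4 shared, per-allele usage
#' spanning roughly 0.01\%-5\% of the F1 repertoire, an IgM-dominated isotype
#' mix, mostly-unmutated IgM, PacBio CCS-like substitution and
#' homopolymer-indel errors, clonal read duplication (several reads per
#' unique molecule), and PCR template-switch chimeras at a 14\% pre-filter
#' rate of which a small fraction arise early enough in amplification to be
#' duplicated.
#'
#' @param n_reads number of reads to emit.
#' @param n_v IGHV alleles per parental haplotype.
#' @param shared_fraction fraction of V alleles shared by both haplotypes.
#' @param isotype_mix named probabilities for `IgM` and `IgG` clones.
#' @param chimera_rate fraction of reads replaced by cross-chromosome
#'   template-switch products (the pre-filter chimera rate).
#' @param early_chimera_fraction fraction of chimeric read mass formed at the
#'   clone (early-PCR) level, and therefore subject to duplication.
#' @param shm_rate_igm,shm_rate_igg per-base somatic hypermutation rates for
#'   mutated IgM clones and for IgG clones.
#' @param igm_unmutated_prob probability that an IgM clone carries no somatic
#'   mutations.
#' @param trim_mean_v3,trim_mean_d5,trim_mean_d3,trim_mean_j5 mean exonuclease
#'   trims (geometric) at the V 3', D 5'/3' and J 5' ends.
#' @param n_insert_max maximum length of each N-region insert (uniform 0..max).
#' @param subst_error_rate per-base sequencing substitution rate.
#' @param homopolymer_indel_rate per-homopolymer-run (length >= 2) probability
#'   of a single-base insertion or deletion.
#' @param umi_length length of the unique molecular identifier.
#' @param reads_per_clone mean reads per unique VDJ molecule (clone).
#' @param strains labels of the two parental strains (strain A, strain B).
#' @param seed integer seed; fully determines all outputs.
#' @return a list of class `f1_sim_config`.
#' @export
sim_config <- function(n_reads = 50000, n_v = 100, shared_fraction = 0.04,
                       isotype_mix = c(IgM = 0.85, IgG = 0.15),
                       chimera_rate = 0.14, early_chimera_fraction = 0.05,
                       shm_rate_igm = 0.005, shm_rate_igg = 0.02,
                       igm_unmutated_prob = 0.8,
                       trim_mean_v3 = 3, trim_mean_d5 = 2,
                       trim_mean_d3 = 2, trim_mean_j5 = 2,
                       n_insert_max = 6,
                       subst_error_rate = 0.002,
                       homopolymer_indel_rate = 0.01,
                       umi_length = 10, reads_per_clone = 2.5,
                       strains = c("BALB", "B6"), seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$shared_fraction, cfg$isotype_mix, cfg$chimera_rate,
             cfg$early_chimera_fraction, cfg$shm_rate_igm, cfg$shm_rate_igg,
             cfg$igm_unmutated_prob, cfg$subst_error_rate,
             cfg$homopolymer_indel_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$isotype_mix) - 1) > 1e-9) stop("isotype_mix must sum to 1")
  stopifnot(cfg$n_reads >= 1, cfg$n_v >= 2, length(cfg$strains) == 2,
            cfg$chimera_rate < 1)
  class(cfg) <- "f1_sim_config"
  cfg
}

# geometric draws with per-element caps, resampling out-of-range values
capped_geom <- function(n, mean, cap) {
  if (mean <= 0) return(integer(n))
  p <- 1 / (1 + mean)
  x <- rgeom(n, p)
  bad <- which(x > cap)
  while (length(bad) > 0) {
    x[bad] <- rgeom(length(bad), p)
    bad <- bad[x[bad] > cap[bad]]
  }
  x
}

# vectorised random DNA
random_dna_vec <- function(lens) {
  out <- rep("", length(lens))
  tot <- sum(lens)
  if (tot == 0) return(out)
  ch <- sample(c("a", "c", "g", "t"), tot, replace = TRUE)
  grp <- rep.int(seq_along(lens), lens)
  sp <- split(ch, grp)
  out[as.integer(names(sp))] <- vapply(sp, paste, character(1), collapse = "")
  out
}

#' Build a pair of homozygous parental IGH haplotypes
#'
#' Generates two parental germline haplotypes whose V sets overlap by exactly
#' `round(shared_fraction * n_v)` alleles. V alleles are organised in gene
#' families (random founders mutated at 3-25 positions), ending in a fixed
#' framework-3 tail that carries the conserved cysteine codon used as the
#' junction anchor. Per-allele usage weights are log-spaced so that F1-wide
#' allele frequencies span roughly 0.005\%-3\%, with shared alleles near 1\%
#' (the regime reported for genes found in both strains). The two IGHJ1
#' alleles differ at exactly one base, and the constant-region genes differ at
#' every configured strain SNP.
#'
#' @param config a [sim_config()].
#' @param shared_fraction overrides `config$shared_fraction`.
#' @return a list of two `parental_haplotype` objects (strain A, strain B),
#'   with attribute `"shared_names"`.
#' @export
build_parental_haplotypes <- function(config = sim_config(),
                                      shared_fraction = config$shared_fraction) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1)
  set.seed(derive_seed(config$seed, 1L))
  n_v <- config$n_v
  n_shared <- round(shared_fraction * n_v)
  if (n_shared > n_v) stop("shared count exceeds the smaller V set")
  n_excl <- n_v - n_shared

  nfam <- 12L
  tail14 <- "tactgtgcaagaga"
  fam_len <- sample(292:300, nfam, replace = TRUE)
  founders <- paste0(random_dna_vec(fam_len - 14L), tail14)
  seen <- new.env(parent = emptyenv())
  gen_allele <- function(fam) {
    L <- fam_len[fam]
    repeat {
      k <- sample(3:25, 1)
      pos <- sample.int(L - 14L, k)
      s <- mutate_positions(founders[fam], pos)
      if (is.null(seen[[s]])) { seen[[s]] <- TRUE; return(s) }
    }
  }
  mk_v <- function(prefix, n) {
    fams <- rep_len(seq_len(nfam), n)
    seqs <- vapply(fams, gen_allele, character(1))
    tibble::tibble(name = sprintf("%sIGHV%03d", prefix, seq_len(n)),
                   sequence = seqs, cys = nchar(seqs) - 10L)
  }
  va <- mk_v(tolower(config$strains[1]), n_excl)
  vb <- mk_v(tolower(config$strains[2]), n_excl)
  vs <- if (n_shared > 0) {
    fams <- rep_len(seq_len(nfam), n_shared)
    seqs <- vapply(fams, gen_allele, character(1))
    tibble::tibble(name = sprintf("musIGHV%03d", 900L + seq_len(n_shared)),
                   sequence = seqs, cys = nchar(seqs) - 10L)
  } else tibble::tibble(name = character(0), sequence = character(0),
                        cys = integer(0))

  usage_v <- function(excl_names, shared_names) {
    raw <- exp(seq(log(2e-4), log(0.12), length.out = length(excl_names)))
    w <- c(setNames(raw, excl_names),
           setNames(rep(0.02, length(shared_names)), shared_names))
    w / sum(w)
  }

  # D segments (shared between strains)
  d_len <- sample(12:22, 10, replace = TRUE)
  dgs <- tibble::tibble(name = sprintf("IGHD%02d*01", 1:10),
                        sequence = random_dna_vec(d_len))

  # J genes: IGHJ1 differs between strains at one base; others shared
  j_core <- paste0(random_dna_vec(rep(20L, 4)), "ctgggg",
                   random_dna_vec(rep(22L, 4)))
  j1a <- j_core[1]
  j1b <- set_base(j1a, 10L, sample(setdiff(c("a", "c", "g", "t"),
                                           base_at(j1a, 10L)), 1))
  mk_j <- function(j1, j1name) {
    tibble::tibble(name = c(j1name, "IGHJ2*01", "IGHJ3*01", "IGHJ4*01"),
                   sequence = c(j1, j_core[2:4]))
  }
  jw <- c(0.2, 0.3, 0.3, 0.2)

  cg <- c_gene_exons(config$strains)
  mk_hap <- function(strain, vx, jtab, cgenes) {
    vall <- dplyr::bind_rows(vx, vs)
    hap <- list(
      strain = strain,
      v = germline_set(vall$name, "V", vall$sequence, strain = strain,
                       cys = vall$cys, label = paste0(strain, "_V")),
      d = germline_set(dgs$name, "D", dgs$sequence, label = "D"),
      j = germline_set(jtab$name, "J", jtab$sequence, label = "J"),
      c_genes = cgenes,
      usage = list(v = usage_v(vx$name, vs$name),
                   d = setNames(rep(1 / nrow(dgs), nrow(dgs)), dgs$name),
                   j = setNames(jw, jtab$name))
    )
    stopifnot(abs(sum(hap$usage$v) - 1) < 1e-9)
    class(hap) <- "parental_haplotype"
    hap
  }
  hapA <- mk_hap(config$strains[1], va,
                 mk_j(j1a, "IGHJ1*01"), cg[[1]])
  hapB <- mk_hap(config$strains[2], vb,
                 mk_j(j1b, "IGHJ1*03"), cg[[2]])
  out <- list(hapA, hapB)
  names(out) <- config$strains
  attr(out, "shared_names") <- vs$name
  out
}

#' Apply somatic hypermutation
#'
#' Independent per-base substitutions at the given rate; a mutated base is
#' always changed to a different base. Uses the current RNG stream.
#'
#' @param seqs character vector of DNA sequences.
#' @param rate per-base mutation probability, scalar or per-sequence vector.
#' @return list with `seq` (mutated sequences), `positions` (list of integer
#'   vectors) and `count`.
#' @export
apply_shm <- function(seqs, rate) {
  n <- length(seqs)
  rate <- rep_len(rate, n)
  stopifnot(all(rate >= 0 & rate < 1))
  lens <- nchar(seqs)
  k <- rbinom(n, lens, rate)
  positions <- vector("list", n)
  out <- seqs
  for (i in which(k > 0)) {
    pos <- sort(sample.int(lens[i], k[i]))
    out[i] <- mutate_positions(seqs[i], pos)
    positions[[i]] <- pos
  }
  positions[k == 0] <- list(integer(0))
  list(seq = out, positions = positions, count = k)
}

#' Apply sequencing errors
#'
#' Per-base substitutions at `subst_error_rate` plus, at each homopolymer run
#' of length >= 2, a single-base insertion or deletion of the run base with
#' probability `homopolymer_indel_rate` (insertions and deletions equally
#' likely). Uses the current RNG stream.
#'
#' @param seqs character vector of DNA sequences.
#' @param config a [sim_config()] supplying the two rates.
#' @return list with `seq`, `sub_pos` (original-coordinate substitution
#'   positions, `;`-joined), `nsub`, `nins`, `ndel`.
#' @export
apply_sequencing_errors <- function(seqs, config = sim_config()) {
  cpp_seq_errors(seqs, config$subst_error_rate, config$homopolymer_indel_rate)
}

# template-switch product: prefix of a up to breakpoint b (inside the V
# region, homologous coordinates), suffix of b from the same coordinate
switch_templates <- function(seq_a, seq_b, vlen_a, vlen_b) {
  lo <- max(1L, ceiling(0.3 * vlen_a))
  hi <- max(lo, floor(0.9 * min(vlen_a, vlen_b)))
  b <- if (hi > lo) sample(lo:hi, 1) else lo
  list(seq = paste0(substr(seq_a, 1, b), substr(seq_b, b + 1, nchar(seq_b))),
       breakpoint = b)
}

# vectorised clone generation from one parental haplotype
sim_vdj_batch <- function(hap, n, c_labels, config) {
  if (n == 0) {
    return(tibble::tibble(v_call = character(0)))
  }
  vgs <- hap$v; dgs <- hap$d; jgs <- hap$j
  vi <- sample.int(nrow(vgs), n, replace = TRUE,
                   prob = hap$usage$v[vgs$name])
  di <- sample.int(nrow(dgs), n, replace = TRUE,
                   prob = hap$usage$d[dgs$name])
  ji <- sample.int(nrow(jgs), n, replace = TRUE,
                   prob = hap$usage$j[jgs$name])
  vseq <- vgs$sequence[vi]; vlen <- nchar(vseq)
  dseq <- dgs$sequence[di]; dlen <- nchar(dseq)
  jseq <- jgs$sequence[ji]; jlen <- nchar(jseq)
  tv <- capped_geom(n, config$trim_mean_v3, vlen - 1L)
  d5 <- capped_geom(n, config$trim_mean_d5, dlen)
  d3 <- capped_geom(n, config$trim_mean_d3, dlen - d5)
  tj <- capped_geom(n, config$trim_mean_j5, pmax(0L, jlen - 20L))
  n1l <- sample(0:config$n_insert_max, n, replace = TRUE)
  n2l <- sample(0:config$n_insert_max, n, replace = TRUE)
  n1 <- random_dna_vec(n1l)
  n2 <- random_dna_vec(n2l)
  vdj <- paste0(substr(vseq, 1, vlen - tv), n1,
                substr(dseq, d5 + 1, dlen - d3), n2,
                substr(jseq, tj + 1, jlen))
  is_igm <- c_labels == "IgM"
  unmut <- is_igm & (runif(n) < config$igm_unmutated_prob)
  rate <- ifelse(unmut, 0,
                 ifelse(is_igm, config$shm_rate_igm, config$shm_rate_igg))
  shm <- apply_shm(vdj, rate)
  cparts <- vapply(hap$c_genes, paste, character(1), collapse = "")
  template <- paste0(shm$seq, cparts[c_labels])
  tibble::tibble(
    chromosome = hap$strain, chrom_5p = hap$strain, chrom_3p = hap$strain,
    v_call = vgs$name[vi], d_call = dgs$name[di], j_call = jgs$name[ji],
    c_gene = c_labels,
    trim_v3 = tv, trim_d5 = d5, trim_d3 = d3, trim_j5 = tj,
    n1 = n1, n2 = n2,
    v_len = vlen - tv, vdj_len = nchar(shm$seq),
    shm_count = shm$count,
    shm_pos = vapply(shm$positions, paste, character(1), collapse = ";"),
    template = template, is_chimera = FALSE, donor_clone = NA_integer_
  )
}

#' Simulate a single VDJ-C rearrangement
#'
#' Draws segment alleles from the haplotype's usage weights, applies
#' geometric exonuclease trims and N-region inserts, somatic hypermutation,
#' and appends the spliced constant-region exons (truncated at the CH3
#' primer site). Uses the current RNG stream.
#'
#' @param hap a `parental_haplotype`.
#' @param isotype a C gene label present in `hap$c_genes` (e.g. `"IgM"`).
#' @param config a [sim_config()].
#' @param n number of rearrangements to draw.
#' @return a tibble with the template sequence and its full truth record.
#' @export
simulate_rearrangement <- function(hap, isotype = "IgM",
                                   config = sim_config(), n = 1) {
  if (!isotype %in% names(hap$c_genes)) {
    stop("isotype not carried by this haplotype: ", isotype)
  }
  sim_vdj_batch(hap, n, rep(isotype, n), config)
}

#' Replace a fraction of reads with PCR template-switch chimeras
#'
#' A fraction `rate` of reads is replaced by a switch product: the prefix of
#' one read up to a breakpoint chosen uniformly inside its V region joined to
#' the suffix of a read from the opposite chromosome at the homologous
#' coordinate. Replaced reads get truth chromosome `"chimera"`.
#'
#' @param reads tibble with a `sequence` column (insert-only, no UMI).
#' @param truth matching truth tibble (columns `chromosome`, `v_len`, ...).
#' @param rate fraction of reads to replace.
#' @return list with modified `reads` and `truth`.
#' @export
inject_chimeras <- function(reads, truth, rate) {
  stopifnot(rate >= 0, rate < 1, nrow(reads) == nrow(truth))
  n <- nrow(reads)
  n_c <- round(rate * n)
  if (n_c == 0) return(list(reads = reads, truth = truth))
  if (n < 2) {
    warning("fewer than 2 reads; no chimeras injected")
    return(list(reads = reads, truth = truth))
  }
  eligible <- which(!truth$is_chimera)
  victims <- sample(eligible, min(n_c, length(eligible)))
  nv <- length(victims)
  # donors: non-chimeric, non-victim reads from the opposite chromosome
  pool_ok <- !truth$is_chimera
  pool_ok[victims] <- FALSE
  donor <- integer(nv)
  for (cv in unique(truth$chromosome[victims])) {
    vi <- which(truth$chromosome[victims] == cv)
    pool <- which(pool_ok & truth$chromosome != cv)
    if (length(pool) == 0) pool <- setdiff(seq_len(n), victims)
    donor[vi] <- pool[sample.int(length(pool), length(vi), replace = TRUE)]
  }
  vl_v <- truth$v_len[victims]
  vl_d <- truth$v_len[donor]
  lo <- pmax(1L, ceiling(0.3 * vl_v))
  hi <- pmax(lo, floor(0.9 * pmin(vl_v, vl_d)))
  b <- lo + as.integer(floor(runif(nv) * (hi - lo + 1L)))
  b <- pmin(b, hi)
  reads$sequence[victims] <- paste0(
    substr(reads$sequence[victims], 1, b),
    substr(reads$sequence[donor], b + 1, nchar(reads$sequence[donor])))
  truth$chrom_3p[victims] <- truth$chromosome[donor]
  truth$d_call[victims] <- truth$d_call[donor]
  truth$j_call[victims] <- truth$j_call[donor]
  truth$c_gene[victims] <- truth$c_gene[donor]
  truth$vdj_len[victims] <- truth$vdj_len[donor]
  truth$chromosome[victims] <- "chimera"
  truth$is_chimera[victims] <- TRUE
  if ("clone_id" %in% names(truth)) {
    truth$donor_clone[victims] <- truth$clone_id[donor]
  }
  list(reads = reads, truth = truth)
}

#' Simulate a complete F1 VDJ-C read set with ground truth
#'
#' Reads are drawn from a clone pool (unique molecules; mean
#' `reads_per_clone` reads each) built from both parental haplotypes, so that
#' unique VDJ sequences recur with realistic multiplicity. Chimeras are
#' injected at `chimera_rate` of the read mass: a fraction
#' `early_chimera_fraction` at the clone level (early-PCR products that can be
#' duplicated), the rest as singleton read replacements. Sequencing errors are
#' applied last. Fully determined by `config$seed`.
#'
#' @param haps the pair of haplotypes from [build_parental_haplotypes()].
#' @param config a [sim_config()].
#' @return a list of class `f1_sim` with `reads` (read_id, umi, sequence),
#'   `truth` (one row per read), `clones`, `haps` and `config`.
#' @export
simulate_f1 <- function(haps, config = sim_config()) {
  set.seed(derive_seed(config$seed, 2L))
  hapA <- haps[[1]]; hapB <- haps[[2]]
  strains <- config$strains
  n <- config$n_reads
  n_clones <- max(2L, as.integer(round(n / config$reads_per_clone)))
  chrom <- sample(strains, n_clones, replace = TRUE)
  iso <- sample(names(config$isotype_mix), n_clones, replace = TRUE,
                prob = config$isotype_mix)
  c_gene <- character(n_clones)
  c_gene[iso == "IgM"] <- "IgM"
  for (s in strains) {
    idx <- which(iso == "IgG" & chrom == s)
    excl <- if (s == strains[1]) "IgG2a" else "IgG2c"
    c_gene[idx] <- sample(c("IgG2b", excl), length(idx), replace = TRUE)
  }
  idxA <- which(chrom == strains[1])
  idxB <- which(chrom == strains[2])
  clA <- sim_vdj_batch(hapA, length(idxA), c_gene[idxA], config)
  clB <- sim_vdj_batch(hapB, length(idxB), c_gene[idxB], config)
  clones <- dplyr::bind_rows(
    dplyr::mutate(clA, .idx = idxA),
    dplyr::mutate(clB, .idx = idxB)
  )
  clones <- clones[order(clones$.idx), ]
  clones$clone_id <- seq_len(n_clones)
  clones$.idx <- NULL

  # early (clone-level) chimeras
  n_ec <- round(config$chimera_rate * config$early_chimera_fraction * n_clones)
  if (n_ec > 0) {
    victims <- sample.int(n_clones, n_ec)
    for (v in victims) {
      opp <- which(clones$chromosome %in% strains &
                     clones$chromosome != clones$chromosome[v])
      if (length(opp) == 0) next
      d <- if (length(opp) == 1) opp else sample(opp, 1)
      sw <- switch_templates(clones$template[v], clones$template[d],
                             clones$v_len[v], clones$v_len[d])
      clones$template[v] <- sw$seq
      clones$chrom_3p[v] <- clones$chromosome[d]
      clones$d_call[v] <- clones$d_call[d]
      clones$j_call[v] <- clones$j_call[d]
      clones$c_gene[v] <- clones$c_gene[d]
      clones$vdj_len[v] <- sw$breakpoint +
        (clones$vdj_len[d] - sw$breakpoint)
      clones$chromosome[v] <- "chimera"
      clones$is_chimera[v] <- TRUE
      clones$donor_clone[v] <- clones$clone_id[d]
    }
  }

  # sample reads from the clone pool
  ridx <- sample.int(n_clones, n, replace = TRUE)
  reads <- tibble::tibble(
    read_id = sprintf("read%07d", seq_len(n)),
    sequence = clones$template[ridx]
  )
  truth <- clones[ridx, ]
  truth$read_id <- reads$read_id

  # late (read-level) singleton chimeras
  n_rc <- round(config$chimera_rate * (1 - config$early_chimera_fraction) * n)
  if (n_rc > 0 && n >= 2) {
    injected <- inject_chimeras(reads, truth, n_rc / n)
    reads <- injected$reads
    truth <- injected$truth
  }

  # sequencing errors and UMIs
  err <- apply_sequencing_errors(reads$sequence, config)
  reads$sequence <- err$seq
  truth$err_nsub <- err$nsub
  truth$err_nins <- err$nins
  truth$err_ndel <- err$ndel
  umi_mat <- matrix(sample(c("a", "c", "g", "t"), n * config$umi_length,
                           replace = TRUE), nrow = n)
  reads$umi <- do.call(paste0, as.data.frame(umi_mat, stringsAsFactors = FALSE))
  reads <- reads[, c("read_id", "umi", "sequence")]
  truth <- dplyr::select(truth, "read_id", "clone_id", "chromosome",
                         "chrom_5p", "chrom_3p", "v_call", "d_call", "j_call",
                         "c_gene", "trim_v3", "trim_d5", "trim_d3", "trim_j5",
                         "n1", "n2", "v_len", "vdj_len", "shm_count",
                         "is_chimera", "donor_clone",
                         "err_nsub", "err_nins", "err_ndel")
  out <- list(reads = reads, truth = truth, clones = clones,
              haps = haps, config = config)
  class(out) <- "f1_sim"
  out
}

#' Write a simulated dataset to disk
#'
#' Emits `reads.fastq` (UMI prepended to each read, uniform Q30-proxy
#' qualities), `truth.tsv`, `haplotypes.fasta` (the planted germline sets with
#' strain tags) and `config.echo` (key-value echo of the configuration).
#'
#' @param sim an `f1_sim` from [simulate_f1()].
#' @param dir output directory (created if needed).
#' @param overwrite overwrite existing files? Existing files error otherwise.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(sim, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("reads.fastq", "truth.tsv",
                            "haplotypes.fasta", "config.echo"))
  if (!overwrite && any(file.exists(paths))) {
    stop("output files already exist in ", dir)
  }
  seqs <- Biostrings::DNAStringSet(toupper(paste0(sim$reads$umi,
                                                  sim$reads$sequence)))
  names(seqs) <- sim$reads$read_id
  quals <- Biostrings::BStringSet(
    vapply(Biostrings::width(seqs),
           function(w) paste(rep("?", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(seqs, paths[1], format = "fastq",
                              qualities = quals)
  readr::write_tsv(sim$truth, paths[2])
  germ <- dplyr::bind_rows(
    lapply(sim$haps, function(h) dplyr::bind_rows(h$v, h$d, h$j)))
  germ <- germ[!duplicated(germ$name), ]
  cex <- dplyr::bind_rows(lapply(names(sim$haps), function(s) {
    h <- sim$haps[[s]]
    tibble::tibble(
      name = unlist(lapply(names(h$c_genes), function(g)
        paste(s, g, names(h$c_genes[[g]]), sep = "_"))),
      segment = "C",
      sequence = unlist(lapply(h$c_genes, unname)),
      functionality = "functional", strain = s,
      provenance = "reported", cys = NA_integer_)
  }))
  all_germ <- dplyr::bind_rows(germ, cex)
  class(all_germ) <- c("germline_set", class(tibble::tibble()))
  write_germline_fasta(all_germ, paths[3])
  cfg <- sim$config
  kv <- vapply(names(cfg), function(k)
    paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1))
  writeLines(kv, paths[4])
  invisible(dir)
}

#' Read back a FASTQ written by [write_dataset()]
#'
#' @param path FASTQ file.
#' @param umi_length length of the prepended UMI to split off.
#' @return tibble with `read_id`, `umi`, `sequence` (lower-case, UMI removed).
#' @export
read_fastq_reads <- function(path, umi_length = 0) {
  xs <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- unname(tolower(as.character(xs)))
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(xs)),
    umi = substr(seqs, 1, umi_length),
    sequence = substr(seqs, umi_length + 1, nchar(seqs))
  )
}
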