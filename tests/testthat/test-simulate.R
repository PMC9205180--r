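test_that("identical configurations produce byte-identical datasets", {
  cfg <- quick_config(n_reads = 300, seed = 21)
  h1 <- build_parental_haplotypes(cfg)
  h2 <- build_parental_haplotypes(cfg)
  expect_identical(h1[[1]]$v, h2[[1]]$v)
  s1 <- simulate_f1(h1, cfg)
  s2 <- simulate_f1(h2, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_dataset(s1, d1, overwrite = TRUE)
  write_dataset(s2, d2, overwrite = TRUE)
  for (f in c("reads.fastq", "truth.tsv", "haplotypes.fasta", "config.echo")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_error(write_dataset(s1, d1), "exist")
})

test_that("parental haplotypes satisfy their construction contracts", {
  cfg <- quick_config(seed = 3)
  haps <- build_parental_haplotypes(cfg)
  shared <- intersect(haps[[1]]$v$name, haps[[2]]$v$name)
  expect_length(shared, round(0.04 * cfg$n_v))
  expect_setequal(shared, attr(haps, "shared_names"))
  for (h in haps) {
    expect_equal(sum(h$usage$v), 1, tolerance = 1e-9)
    expect_false(anyDuplicated(h$v$name) > 0)
  }
  # disjoint V sets at shared_fraction 0
  h0 <- build_parental_haplotypes(cfg, shared_fraction = 0)
  expect_length(intersect(h0[[1]]$v$name, h0[[2]]$v$name), 0)
  expect_error(build_parental_haplotypes(cfg, shared_fraction = 1.3))
  # IGHJ1 alleles differ at exactly one base
  j1a <- haps[[1]]$j$sequence[haps[[1]]$j$name == "IGHJ1*01"]
  j1b <- haps[[2]]$j$sequence[haps[[2]]$j$name == "IGHJ1*03"]
  expect_equal(nrow(pairwise_diff(j1a, j1b)), 1)
  # constant genes differ at every configured strain SNP offset
  snp <- strain_snps()
  cg <- c_gene_exons(cfg$strains)
  for (i in seq_len(nrow(snp))) {
    gene <- c(IGHM = "IgM", IGHG2B = "IgG2b")[[snp$gene[i]]]
    ea <- cg[[1]][[gene]][[snp$exon[i]]]
    eb <- cg[[2]][[gene]][[snp$exon[i]]]
    expect_identical(substr(ea, snp$offset[i] + 1, snp$offset[i] + 1),
                     snp$strainA_base[i])
    expect_identical(substr(eb, snp$offset[i] + 1, snp$offset[i] + 1),
                     snp$strainB_base[i])
  }
})

test_that("segment usage follows the planted weights (multinomial oracle)", {
  cfg <- quick_config(seed = 12)
  haps <- build_parental_haplotypes(cfg)
  set.seed(1)
  n <- 10000
  rr <- simulate_rearrangement(haps[[1]], "IgM", cfg, n = n)
  w <- haps[[1]]$usage$v
  top <- names(sort(w, decreasing = TRUE))[1:10]
  for (a in top) {
    p <- w[[a]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(rr$v_call == a) - p), 3 * se + 1e-9)
  }
  # identity configuration: no trims, no inserts, no mutations
  cfg0 <- quick_config(seed = 12, trim_mean_v3 = 0, trim_mean_d5 = 0,
                       trim_mean_d3 = 0, trim_mean_j5 = 0, n_insert_max = 0,
                       shm_rate_igm = 0, igm_unmutated_prob = 1)
  set.seed(2)
  r0 <- simulate_rearrangement(haps[[1]], "IgM", cfg0, n = 20)
  h <- haps[[1]]
  for (k in seq_len(20)) {
    exp_seq <- paste0(
      h$v$sequence[h$v$name == r0$v_call[k]],
      h$d$sequence[h$d$name == r0$d_call[k]],
      h$j$sequence[h$j$name == r0$j_call[k]],
      paste(h$c_genes$IgM, collapse = ""))
    expect_identical(r0$template[k], exp_seq)
  }
  expect_error(simulate_rearrangement(haps[[1]], "IgG2c", cfg))
})

test_that("somatic hypermutation matches its binomial model", {
  set.seed(31)
  s <- paste(sample(c("a", "c", "g", "t"), 300, TRUE), collapse = "")
  r0 <- apply_shm(s, 0)
  expect_identical(r0$seq, s)
  expect_length(r0$positions[[1]], 0)
  reps <- apply_shm(rep(s, 1000), 0.02)
  m <- mean(reps$count)
  se <- sqrt(300 * 0.02 * 0.98 / 1000)
  expect_lt(abs(m - 6), 3 * se)
  # mutated bases always differ from the original
  ch <- strsplit(s, "")[[1]]
  for (i in which(reps$count > 0)[1:50]) {
    pos <- reps$positions[[i]]
    expect_true(all(strsplit(reps$seq[i], "")[[1]][pos] != ch[pos]))
  }
})

test_that("sequencing errors follow the configured rates", {
  set.seed(41)
  s <- paste(sample(c("a", "c", "g", "t"), 10000, TRUE), collapse = "")
  id <- apply_sequencing_errors(s, sim_config(subst_error_rate = 0,
                                              homopolymer_indel_rate = 0))
  expect_identical(id$seq[1], s)
  # substitutions only: binomial oracle
  sub <- apply_sequencing_errors(rep(s, 30),
                                 sim_config(subst_error_rate = 0.002,
                                            homopolymer_indel_rate = 0))
  m <- mean(sub$nsub)
  se <- sqrt(10000 * 0.002 * 0.998 / 30)
  expect_lt(abs(m - 20), 3 * se)
  # homopolymer indels only: per-run binomial oracle
  runs <- sum(rle(strsplit(s, "")[[1]])$lengths >= 2)
  hp <- apply_sequencing_errors(rep(s, 30),
                                sim_config(subst_error_rate = 0,
                                           homopolymer_indel_rate = 0.01))
  events <- mean(hp$nins + hp$ndel)
  se <- sqrt(runs * 0.01 * 0.99 / 30)
  expect_lt(abs(events - runs * 0.01), 3 * se)
  # forced single-run edits change the run length by exactly one
  set.seed(5)
  forced <- apply_sequencing_errors(rep("aaaa", 40),
                                    sim_config(subst_error_rate = 0,
                                               homopolymer_indel_rate = 1))
  lens <- nchar(forced$seq)
  expect_true(all(lens %in% c(3L, 5L)))
  expect_true(all(grepl("^a+$", forced$seq)))
  expect_true(any(lens == 3) && any(lens == 5))
})

test_that("chimera injection flags the configured fraction of reads", {
  cfg <- quick_config(n_reads = 10000, seed = 8, chimera_rate = 0)
  haps <- build_parental_haplotypes(cfg)
  sim <- simulate_f1(haps, cfg)
  expect_equal(sum(sim$truth$is_chimera), 0)
  set.seed(77)
  out <- inject_chimeras(sim$reads, sim$truth, 0.14)
  frac <- mean(out$truth$is_chimera)
  se <- sqrt(0.14 * 0.86 / 10000)
  expect_lt(abs(frac - 0.14), 3 * se)
  expect_true(all(out$truth$chromosome[out$truth$is_chimera] == "chimera"))
  # rate 0 is a no-op; tiny inputs warn
  out0 <- inject_chimeras(sim$reads, sim$truth, 0)
  expect_identical(out0$reads, sim$reads)
  expect_warning(inject_chimeras(sim$reads[1, ], sim$truth[1, ], 0.9))
  # end-to-end chimera mass matches the configured rate
  cfg2 <- quick_config(n_reads = 10000, seed = 8)
  sim2 <- simulate_f1(build_parental_haplotypes(cfg2), cfg2)
  expect_lt(abs(mean(sim2$truth$is_chimera) - 0.14), 3 * se + 0.01)
})

test_that("written datasets round-trip", {
  cfg <- quick_config(n_reads = 120, seed = 55)
  sim <- simulate_f1(build_parental_haplotypes(cfg), cfg)
  d <- file.path(tempdir(), "rt")
  write_dataset(sim, d, overwrite = TRUE)
  back <- read_fastq_reads(file.path(d, "reads.fastq"),
                           umi_length = cfg$umi_length)
  expect_identical(back$sequence, sim$reads$sequence)
  expect_identical(back$umi, sim$reads$umi)
  truth <- readr::read_tsv(file.path(d, "truth.tsv"), show_col_types = FALSE)
  expect_equal(nrow(truth), nrow(sim$reads))
  germ <- read_germline_fasta(file.path(d, "haplotypes.fasta"))
  expect_true(all(sim$haps[[1]]$v$name %in% germ$name))
  expect_true(any(germ$segment == "C"))
})
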