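test_that("constant-segment extraction follows the one-past-J rule", {
  rec <- tibble::tibble(sequence_id = "r1",
                        sequence = paste(rep("acgt", 250), collapse = ""),
                        j_sequence_end = 450L)
  cs <- extract_ighc(rec)
  expect_equal(nchar(cs$c_seq), 550)
  expect_identical(cs$c_seq, substr(rec$sequence, 451, 1000))
  expect_false(cs$empty)
  # J ending at the read end: empty segment, flagged
  rec$j_sequence_end <- 1000L
  expect_true(extract_ighc(rec)$empty)
  rec$j_sequence_end <- NA_integer_
  expect_error(extract_ighc(rec), "no_j_call")
  expect_true(is.na(extract_ighc(rec, drop_missing = TRUE)$c_seq))
})

test_that("indel correction removes insertions and flags filled deletions", {
  set.seed(71)
  ref <- c(ex1 = paste0(paste(sample(c("a", "c", "g", "t"), 40, TRUE),
                              collapse = ""),
                        "aaaa",
                        paste(sample(c("a", "c", "g", "t"), 40, TRUE),
                              collapse = "")))
  # identity
  r0 <- indel_correct(ref, ref)
  expect_identical(r0$corrected, unname(ref))
  expect_equal(r0$nsub + r0$nins + r0$ndel, 0)
  expect_equal(r0$identity, 1)
  # one extra base in the homopolymer run, plus a substitution elsewhere
  withsub <- f1ighv:::set_base(ref, 20, setdiff(c("a", "c", "g", "t"),
                                                substr(ref, 20, 20))[1])
  ins <- paste0(substr(withsub, 1, 42), "a", substr(withsub, 43, nchar(ref)))
  r1 <- indel_correct(ins, ref)
  expect_identical(r1$corrected, withsub)     # insertion gone, sub preserved
  expect_equal(r1$nins, 1)
  expect_false(grepl("1", r1$conf))
  # one deleted base: restored from the reference, flagged low-confidence
  del <- paste0(substr(ref, 1, 42), substr(ref, 44, nchar(ref)))
  r2 <- indel_correct(del, ref)
  expect_identical(r2$corrected, unname(ref))
  expect_equal(r2$ndel, 1)
  # the filled position lies inside the homopolymer run (placement within
  # the run is degenerate) and is the only low-confidence base
  expect_true(grepl("1", substr(r2$conf, 41, 45)))
  expect_equal(lengths(regmatches(r2$conf, gregexpr("1", r2$conf))), 1L)
  # idempotence: correcting a corrected sequence is the identity
  r3 <- indel_correct(r1$corrected, ref)
  expect_identical(r3$corrected, r1$corrected)
  expect_equal(r3$nins + r3$ndel, 0)
  # unalignable input
  set.seed(72)
  junk <- paste(sample(c("a", "c", "g", "t"), 84, TRUE), collapse = "")
  expect_true(indel_correct(junk, ref)$unalignable)
  expect_error(indel_correct("acgt", c(x = "acgtacgt")), "short")
})

test_that("SNP typing reads bases and respects confidence", {
  snp <- strain_snps()
  st <- snp[snp$gene == "IGHM", ]
  st$global_offset <- st$offset
  cg <- c_gene_exons()
  ch1a <- cg$BALB$IgM[["CH1"]]
  ch1b <- cg$B6$IgM[["CH1"]]
  conf_hi <- paste(rep("0", nchar(ch1a)), collapse = "")
  tb <- type_snps(c(ch1a, ch1b), c(conf_hi, conf_hi), st)
  expect_identical(tb$rs29176517, c("g", "a"))
  # deletion-filled SNP position: no-call
  conf_lo <- conf_hi
  substr(conf_lo, st$offset[1] + 1, st$offset[1] + 1) <- "1"
  tb2 <- type_snps(ch1a, conf_lo, st)
  expect_true(is.na(tb2$rs29176517))
  expect_equal(tb2$x_snp_lowconf, 1L)
  # offset beyond the corrected segment: no-call
  tb3 <- type_snps(substr(ch1a, 1, 100), conf_hi, st)
  expect_true(is.na(tb3$rs29176517))
})

test_that("strain calls require consistent SNP bases", {
  snp <- strain_snps()
  g2b <- snp[snp$gene == "IGHG2B", ]
  bases_a <- tibble::tibble(rs45969375 = "c", rs49934817 = "c",
                            rs45822066 = "c", rs46899601 = "c",
                            x_snp_lowconf = 0L)
  expect_identical(assign_c_call(bases_a, g2b, require_all = TRUE), "BALB")
  mixed <- bases_a
  mixed$rs49934817 <- "t"                     # one B6 base among BALB bases
  expect_identical(assign_c_call(mixed, g2b, require_all = TRUE), "")
  partial <- bases_a
  partial$rs46899601 <- NA_character_
  expect_identical(assign_c_call(partial, g2b, require_all = TRUE), "")
  expect_identical(assign_c_call(partial, g2b, require_all = FALSE), "BALB")
  none <- tibble::tibble(rs45969375 = NA_character_,
                         rs49934817 = NA_character_,
                         rs45822066 = NA_character_,
                         rs46899601 = NA_character_, x_snp_lowconf = 0L)
  expect_identical(assign_c_call(none, g2b, require_all = FALSE), "")
})

test_that("J-anchored discovery recovers the planted constant regions", {
  # IgG-heavy, low-error configuration so subclass segments are observable
  cfg <- quick_config(n_reads = 6000, seed = 17,
                      isotype_mix = c(IgM = 0.3, IgG = 0.7),
                      chimera_rate = 0,
                      subst_error_rate = 0.001,
                      homopolymer_indel_rate = 0.005)
  haps <- build_parental_haplotypes(cfg)
  sim <- simulate_f1(haps, cfg)
  refs <- combine_haplotype_references(haps)
  airr <- annotate_reads(sim$reads, refs$v, refs$d, refs$j)
  airr <- type_constant_regions(airr, strains = cfg$strains)
  anchor_map <- c("IGHJ1*01" = "BALB", "IGHJ1*03" = "B6")
  igm <- airr[airr$x_isotype == "IgM", ]
  top1 <- discover_c_alleles_by_j_anchor(igm, anchor_map, top_n = 1)
  for (s in names(haps)) {
    planted <- paste(haps[[s]]$c_genes$IgM, collapse = "")
    expect_identical(top1$c_seq[top1$strain == s], planted)
  }
  # IgG: the top two sequences per anchor are the two planted subclass genes
  igg <- airr[airr$x_isotype %in% c("IgG2a", "IgG2b", "IgG2c"), ]
  top2 <- discover_c_alleles_by_j_anchor(igg, anchor_map, top_n = 2)
  for (s in names(haps)) {
    genes <- setdiff(names(haps[[s]]$c_genes), "IgM")
    planted <- vapply(haps[[s]]$c_genes[genes], paste, character(1),
                      collapse = "")
    expect_setequal(top2$c_seq[top2$strain == s], unname(planted))
  }
  # single-strain input leaves the other anchor group empty
  one <- igm[sub("^[^*]*\\*", "", igm$c_call) == "BALB" &
               nzchar(igm$c_call), ]
  t1 <- discover_c_alleles_by_j_anchor(one, anchor_map, top_n = 1)
  expect_true(all(t1$strain == "BALB"))
  expect_warning(discover_c_alleles_by_j_anchor(igm[0, ], anchor_map))
})

test_that("J-anchor concordance is perfect without chimeras or errors", {
  cfg <- errorfree_config(n_reads = 500, seed = 23)
  haps <- build_parental_haplotypes(cfg)
  sim <- simulate_f1(haps, cfg)
  refs <- combine_haplotype_references(haps)
  airr <- annotate_reads(sim$reads, refs$v, refs$d, refs$j)
  airr <- type_constant_regions(airr, strains = cfg$strains)
  anchor_map <- c("IGHJ1*01" = "BALB", "IGHJ1*03" = "B6")
  conc <- j_anchor_concordance(airr, anchor_map)
  expect_true(all(conc$concordance == 1))
  expect_setequal(conc$strain_call, c("BALB", "B6"))
  expect_error(j_anchor_concordance(airr[0, ], anchor_map), "no reads")
})
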