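test_that("the printed novel-allele pair differs only by C100T", {
  t1 <- table1_alleles()
  expect_equal(nrow(t1), 6)
  d <- pairwise_diff(t1$sequence[t1$name == "b6IGHV040"],
                     t1$sequence[t1$name == "balbIGHV041"])
  expect_equal(nrow(d), 1)
  expect_equal(d$position, 100)
  expect_identical(d$label, "C100T")
  # identical sequences: no differences
  expect_equal(nrow(pairwise_diff("acgt", "acgt")), 0)
  # random pair agrees with a position-by-position scan
  set.seed(44)
  a <- paste(sample(c("a", "c", "g", "t"), 300, TRUE), collapse = "")
  b <- paste(sample(c("a", "c", "g", "t"), 300, TRUE), collapse = "")
  d2 <- pairwise_diff(a, b)
  expect_identical(d2$position,
                   which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
  expect_error(pairwise_diff("acgt", "acg"), "length")
})

test_that("truncated references are extended from their best donor", {
  refs <- toy_refs(6, 300, seed = 8)
  donor <- refs$sequence[4]
  # missing the last 3 nucleotides
  tr3 <- germline_set("trunc3", "V", substr(donor, 1, 297))
  ext <- extend_truncated_reference(tr3, refs)
  expect_identical(ext$sequence, donor)
  expect_equal(attr(ext, "ext3"), 3)
  expect_identical(attr(ext, "donor"), refs$name[4])
  expect_identical(ext$provenance, "extended")
  # missing the first 57 nucleotides
  tr57 <- germline_set("trunc57", "V", substr(donor, 58, 300))
  ext2 <- extend_truncated_reference(tr57, refs)
  expect_identical(ext2$sequence, donor)
  expect_equal(attr(ext2, "ext5"), 57)
  # round trip: trimming the extension returns the original record
  e5 <- attr(ext2, "ext5"); e3 <- attr(ext2, "ext3")
  expect_identical(substr(ext2$sequence, e5 + 1, nchar(ext2$sequence) - e3),
                   tr57$sequence)
  # unrelated sequence: no suitable donor
  set.seed(9)
  junk <- germline_set("junk", "V",
                       paste(sample(c("a", "c", "g", "t"), 250, TRUE),
                             collapse = ""))
  expect_error(extend_truncated_reference(junk, refs), "no_suitable_donor")
})

# synthetic assigned-read records emulating annotation output for one allele:
# reads carry the true gene trimmed geometrically, then random junction bases
mk_end_records <- function(true_gene, ref_len, n = 300, trim_mean = 3,
                           seed = 1) {
  set.seed(seed)
  trims <- rgeom(n, 1 / (1 + trim_mean))
  trims <- pmin(trims, 15)
  gene_part <- substring(true_gene, 1, nchar(true_gene) - trims)
  tails <- vapply(seq_len(n), function(i)
    paste(sample(c("a", "c", "g", "t"), 25, TRUE), collapse = ""),
    character(1))
  aligned_end <- pmin(nchar(gene_part), ref_len)
  tibble::tibble(
    sequence_id = sprintf("e%04d", seq_len(n)),
    v_call = "VX",
    sequence = paste0(gene_part, tails),
    v_sequence_end = aligned_end,
    x_v_germline_end = aligned_end,
    x_v_mismatches = 0L)
}

test_that("3' end verdicts: confirmed, trim and extend", {
  set.seed(52)
  gene <- paste(sample(c("a", "c", "g", "t"), 300, TRUE), collapse = "")
  # correct reference end
  refs_ok <- germline_set("VX", "V", gene)
  rec <- mk_end_records(gene, 300, seed = 2)
  expect_identical(confirm_3prime_ends("VX", rec, refs_ok)$verdict,
                   "confirmed")
  # reference two bases too long: terminal positions unreached, unsupported
  refs_long <- germline_set("VX", "V", paste0(gene, "gg"))
  ep_long <- confirm_3prime_ends("VX", rec, refs_long)
  expect_identical(ep_long$verdict, "trim_by_2")
  # reference one base short of a gene with a fixed next base
  refs_short <- germline_set("VX", "V", substr(gene, 1, 299))
  rec_s <- mk_end_records(gene, 299, seed = 3)
  ep_s <- confirm_3prime_ends("VX", rec_s, refs_short)
  expect_identical(ep_s$verdict, "extend_by_1")
  expect_identical(ep_s$extension, substr(gene, 300, 300))
  # insufficient depth
  expect_identical(confirm_3prime_ends("VX", rec[1:5, ], refs_ok)$verdict,
                   "inconclusive")
  # reach counts never increase towards the 3' end
  prof <- confirm_3prime_ends("VX", rec, refs_ok)$profile
  expect_true(all(diff(prof$reach_count) <= 0))
})

test_that("correct ends are rarely revised across replicates", {
  set.seed(53)
  gene <- paste(sample(c("a", "c", "g", "t"), 300, TRUE), collapse = "")
  refs_ok <- germline_set("VX", "V", gene)
  verdicts <- vapply(1:20, function(s) {
    confirm_3prime_ends("VX", mk_end_records(gene, 300, seed = 100 + s),
                        refs_ok)$verdict
  }, character(1))
  expect_gte(mean(verdicts == "confirmed"), 0.95)
})

test_that("per-strain reference export splits alleles by assignment", {
  refs <- toy_refs(5, 120)
  genotype <- tibble::tibble(
    allele = refs$name, unmutated_support = c(9L, 8L, 7L, 3L, 2L),
    total_support = 10L, frequency = 0.2, present = TRUE, note = "")
  haplotype <- tibble::tibble(
    v_allele = refs$name, anchorA = "BALB", anchorB = "B6",
    count_anchorA = c(10L, 0L, 6L, 10L, 0L),
    count_anchorB = c(0L, 10L, 7L, 1L, 0L),
    assignment = c("anchorA_only", "anchorB_only", "both", "anchorA_only",
                   "unknown"),
    deleted_on = c("B6", "BALB", NA, "B6", NA),
    certainty = c(3, 3, 0.5, 2.5, NA), kThreDel = 0.1)
  d <- file.path(tempdir(), "refset")
  out <- export_reference_set(genotype, haplotype, refs, d)
  balb <- read_germline_fasta(out$paths[["BALB"]])
  b6 <- read_germline_fasta(out$paths[["B6"]])
  expect_setequal(balb$name, c("TOY01", "TOY03", "TOY04"))
  expect_setequal(b6$name, c("TOY02", "TOY03"))
  expect_true("TOY03" %in% balb$name && "TOY03" %in% b6$name)
  un <- read_germline_fasta(out$unassigned)
  expect_identical(un$name, "TOY05")
  # exported sequences survive the FASTA round trip
  expect_identical(balb$sequence,
                   refs$sequence[match(balb$name, refs$name)])
})

test_that("assembly search is strand-symmetric with exact-match semantics", {
  refs <- toy_refs(3, 80, seed = 21)
  rc <- function(s) tolower(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(s)))))
  set.seed(22)
  pad <- function(n) paste(sample(c("a", "c", "g", "t"), n, TRUE),
                           collapse = "")
  mut1 <- f1ighv:::set_base(refs$sequence[3], 40,
                            setdiff(c("a", "c", "g", "t"),
                                    substr(refs$sequence[3], 40, 40))[1])
  contigs <- Biostrings::DNAStringSet(toupper(c(
    ctg1 = paste0(pad(50), refs$sequence[1], pad(50)),
    ctg2 = paste0(pad(30), rc(refs$sequence[2]), pad(30)),
    ctg3 = paste0(pad(20), mut1, pad(20)))))
  hits <- search_assembly(refs, contigs)
  expect_identical(hits$present, c(TRUE, TRUE, FALSE))
  hits1 <- search_assembly(refs, contigs, max_mismatches = 1)
  expect_true(all(hits1$present))
  # contig order does not matter
  hits_r <- search_assembly(refs, rev(contigs))
  expect_identical(hits_r$present, hits$present)
  expect_error(search_assembly(refs, contigs[0]), "empty")
})

test_that("mismatch histograms are proper and improve with supersets", {
  recs <- tibble::tibble(
    sequence_id = c("a", "b", "c"), v_call = "V1",
    x_v_mismatches = c(0L, 0L, 3L), duplicate_count = c(2L, 1L, 1L))
  md <- mismatch_distribution(recs)
  expect_equal(sum(md$fraction), 1)
  expect_equal(md$fraction[md$bin == "0"], 0.75)
  expect_equal(md$fraction[md$bin == "3"], 0.25)
  expect_equal(attr(md, "unmutated_fraction"), 0.75)
  # adding an allele back to the reference never decreases the bin-0 mass
  cfg <- quick_config(n_reads = 1500, seed = 37, chimera_rate = 0)
  haps <- build_parental_haplotypes(cfg)
  sim <- simulate_f1(haps, cfg)
  refs <- combine_haplotype_references(haps)
  airr <- annotate_reads(sim$reads, refs$v, refs$d, refs$j)
  top <- names(sort(table(sim$truth$v_call), decreasing = TRUE))[1]
  minus <- refs$v[refs$v$name != top, ]
  class(minus) <- class(refs$v)
  md_minus <- mismatch_distribution(airr, minus)
  md_full <- mismatch_distribution(airr, refs$v)
  expect_gte(attr(md_full, "unmutated_fraction"),
             attr(md_minus, "unmutated_fraction"))
})
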