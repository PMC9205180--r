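# synthetic rearrangement rows for rule-level tests
mk_rec <- function(id, seq = "acgtacgt", v = "V1", j = "J1", junc = "tgtgcg",
                   complete = TRUE, dup = 1L, mm = 0L, nindel = 0L,
                   muts = "", c_call = "") {
  tibble::tibble(sequence_id = id, sequence = seq, v_call = v, d_call = "",
                 j_call = j, c_call = c_call, junction = junc,
                 v_sequence_start = 1L, v_sequence_end = 4L,
                 j_sequence_start = 5L, j_sequence_end = nchar(seq),
                 duplicate_count = dup, complete_vdj = complete,
                 x_v_mismatches = mm, x_v_nindel = nindel, x_v_muts = muts)
}

test_that("rearrangement filtering drops truncated and junction-less reads", {
  recs <- dplyr::bind_rows(
    mk_rec("a"),
    mk_rec("b", junc = ""),
    mk_rec("c", complete = FALSE),
    mk_rec("d", j = ""))
  expect_identical(filter_rearrangements(recs)$sequence_id, "a")
  expect_equal(nrow(filter_rearrangements(recs[0, ])), 0)
})

test_that("collapsing conserves counts and aggregates anchor calls", {
  recs <- dplyr::bind_rows(
    mk_rec(sprintf("r%d", 1:5), seq = "aaaacccc", c_call = "IgM*BALB"),
    mk_rec("r6", seq = "ggggtttt", c_call = "IgM*BALB"),
    mk_rec("r7", seq = "ggggtttt", c_call = "IgM*B6"),
    mk_rec("r8", seq = "acacacac"))
  col <- collapse_unique(recs)
  expect_equal(nrow(col), 3)
  expect_equal(sum(col$duplicate_count), nrow(recs))   # conservation
  five <- col[col$sequence == "aaaacccc", ]
  expect_equal(five$duplicate_count, 5L)
  expect_identical(five$sequence_id, "r1")             # smallest member id
  expect_identical(five$c_call, "IgM*BALB")
  amb <- col[col$sequence == "ggggtttt", ]
  expect_true(amb$x_c_ambiguous)                        # both anchors seen
  expect_identical(amb$c_call, "")
  # all-distinct input collapses to itself
  d <- dplyr::bind_rows(mk_rec("x", seq = "aaaa"), mk_rec("y", seq = "cccc"))
  expect_equal(collapse_unique(d)$duplicate_count, c(1L, 1L))
})

test_that("unmutated selection applies the mismatch threshold", {
  recs <- dplyr::bind_rows(mk_rec("a", mm = 0L), mk_rec("b", mm = 1L))
  expect_identical(select_unmutated(recs)$sequence_id, "a")
  p1 <- inference_params(unmutated_max_mismatches = 1)
  expect_equal(nrow(select_unmutated(recs, p1)), 2)
})

test_that("the intercept test finds planted polymorphisms and nothing else", {
  set.seed(61)
  refseq <- paste(sample(c("a", "c", "g", "t"), 300, TRUE), collapse = "")
  refs <- germline_set("VX*01", "V", refseq, cys = 285L)
  pos <- 100L
  alt <- setdiff(c("a", "c", "g", "t"), substr(refseq, pos, pos))[1]
  lab <- paste0(pos, ":", alt)
  # 60 exact sequences + 60 carrying only the variant substitution
  recs <- dplyr::bind_rows(
    mk_rec(sprintf("e%03d", 1:60), v = "VX*01"),
    mk_rec(sprintf("v%03d", 1:60), v = "VX*01", mm = 1L, muts = lab))
  nov <- find_novel_alleles(recs, refs)
  expect_equal(nrow(nov), 1)
  expect_identical(nov$sequence, f1ighv:::set_base(refseq, pos, alt))
  det <- attr(nov, "detail")
  expect_gte(det$intercept, 0.125)
  expect_equal(det$support, 60)
  # support below min_seqs: not reported
  few <- dplyr::bind_rows(
    mk_rec(sprintf("e%03d", 1:80), v = "VX*01"),
    mk_rec(sprintf("v%03d", 1:5), v = "VX*01", mm = 1L, muts = lab))
  expect_equal(nrow(find_novel_alleles(few, refs)), 0)
  # mutation-free data: no candidates
  clean <- mk_rec(sprintf("e%03d", 1:80), v = "VX*01")
  expect_equal(nrow(find_novel_alleles(clean, refs)), 0)
  # hypermutation-like noise (substitutions scattered over positions) does
  # not reach the single-mismatch support threshold
  set.seed(62)
  noisy <- dplyr::bind_rows(lapply(1:80, function(i) {
    m <- sample(1:6, 1)
    ps <- sample(250, m)
    labs <- paste(paste0(ps, ":", sample(c("a", "c", "g", "t"), m, TRUE)),
                  collapse = ";")
    mk_rec(sprintf("n%03d", i), v = "VX*01", mm = m, muts = labs)
  }))
  expect_equal(nrow(find_novel_alleles(dplyr::bind_rows(clean, noisy),
                                       refs)), 0)
})

test_that("genotype presence requires duplicated unmutated exact support", {
  refs <- toy_refs(4, 60)
  recs <- dplyr::bind_rows(
    mk_rec(c("a1", "a2", "a3"), seq = c("s1", "s2", "s3"), v = "TOY01"),
    mk_rec("b1", seq = "s4", v = "TOY02"),
    mk_rec(c("c1", "c2"), seq = c("s5", "s6"), v = "TOY03", mm = 3L))
  gt <- infer_genotype(recs, refs)
  expect_true(gt$present[gt$allele == "TOY01"])
  expect_false(gt$present[gt$allele == "TOY02"])
  expect_identical(gt$note[gt$allele == "TOY02"], "provisional")
  expect_false(gt$present[gt$allele == "TOY03"])
  expect_identical(gt$note[gt$allele == "TOY03"],
                   "insufficient_unmutated_support")
  expect_lte(sum(gt$frequency), 1 + 1e-9)
  expect_false("TOY04" %in% gt$allele[gt$present])
})

test_that("reassignment respects the genotype and never worsens fits", {
  cfg <- quick_config(n_reads = 400, seed = 33)
  haps <- build_parental_haplotypes(cfg)
  sim <- simulate_f1(haps, cfg)
  refs <- combine_haplotype_references(haps)
  airr <- annotate_reads(sim$reads, refs$v, refs$d, refs$j)
  # full-reference reassignment leaves calls unchanged
  re <- reassign_alleles(airr, refs$v$name, refs$v)
  expect_identical(re$v_call, airr$v_call)
  expect_equal(re$x_v_mismatches, airr$x_v_mismatches)
  # dropping one of two identically-sequenced alleles collapses the tie
  twin <- dplyr::bind_rows(
    refs$v[1, ],
    dplyr::mutate(refs$v[1, ], name = "twinIGHV001"))
  class(twin) <- class(refs$v)
  probe <- tibble::tibble(sequence_id = "p",
                          sequence = paste0(refs$v$sequence[1], "gggtcaagg"))
  a <- annotate_reads(probe[, c(1, 2)] |>
                        dplyr::rename(read_id = "sequence_id"),
                      twin, NULL, refs$j)
  expect_identical(a$v_call, paste(sort(twin$name), collapse = ","))
  a2 <- reassign_alleles(a, refs$v$name[1], twin)
  expect_identical(a2$v_call, refs$v$name[1])
  # restricting to the present set never increases mismatches for records
  # whose original call survives
  keep <- refs$v$name[seq(1, nrow(refs$v), 2)]
  sub <- airr[f1ighv:::first_call(airr$v_call) %in% keep &
                nzchar(airr$v_call), ]
  re2 <- reassign_alleles(sub, keep, refs$v)
  expect_true(all(re2$x_v_mismatches <= sub$x_v_mismatches))
  expect_error(reassign_alleles(airr, character(0), refs$v), "empty")
})
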