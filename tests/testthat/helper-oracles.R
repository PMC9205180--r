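# Independent reference implementations used to cross-check the package's
# alignment and haplotype-decision code paths.

# Full-matrix local alignment with the package's scoring contract:
# match +1 / mismatch -2 / gap -3, both alignment ends trimmed back to runs
# of `end_run` consecutive matches. Plain R dynamic programming.
oracle_local_align <- function(q, r, match = 1, mismatch = -2, gap = -3,
                               end_run = 6) {
  qc <- strsplit(tolower(q), "")[[1]]
  rc <- strsplit(tolower(r), "")[[1]]
  n <- length(qc); m <- length(rc)
  H <- matrix(0, n + 1, m + 1)
  D <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      s <- H[i, j] + if (qc[i] == rc[j] && qc[i] != "n") match else mismatch
      d <- 1L
      v <- H[i + 1, j] + gap          # ref consumed alone (deletion in query)
      if (v > s) { s <- v; d <- 2L }
      v <- H[i, j + 1] + gap          # query consumed alone (insertion)
      if (v > s) { s <- v; d <- 3L }
      if (s <= 0) { s <- 0; d <- 0L }
      H[i + 1, j + 1] <- s
      D[i + 1, j + 1] <- d
      if (s > best) { best <- s; bi <- i; bj <- j }
    }
  }
  empty <- list(score = 0, q_start = 0, q_end = 0, r_start = 0, r_end = 0,
                nsub = 0, nins = 0, ndel = 0, span = 0)
  if (best <= 0) return(empty)
  # traceback path (ops forward order: 1 diag, 2 del, 3 ins)
  ops <- integer(0); i <- bi; j <- bj
  while (i >= 0 && j >= 0) {
    d <- D[i + 1, j + 1]
    if (d == 0L) break
    ops <- c(d, ops)
    if (d == 1L) { i <- i - 1; j <- j - 1 }
    else if (d == 2L) j <- j - 1
    else i <- i - 1
  }
  qs <- i + 1; rs <- j + 1
  # match mask in forward order
  len <- length(ops)
  is_match <- logical(len)
  ri <- rs; qi <- qs
  for (t in seq_len(len)) {
    if (ops[t] == 1L) {
      is_match[t] <- qc[qi] == rc[ri] && qc[qi] != "n"
      qi <- qi + 1; ri <- ri + 1
    } else if (ops[t] == 2L) ri <- ri + 1
    else qi <- qi + 1
  }
  runs <- function(t) t + end_run - 1 <= len && all(is_match[t:(t + end_run - 1)])
  tstart <- 1
  while (tstart <= len && !runs(tstart)) tstart <- tstart + 1
  if (tstart > len) return(empty)
  rune <- function(t) t - end_run + 1 >= 1 && all(is_match[(t - end_run + 1):t])
  tend <- len
  while (tend >= tstart && !rune(tend)) tend <- tend - 1
  if (tend < tstart) return(empty)
  qi <- qs; ri <- rs
  out <- list(score = 0, nsub = 0, nins = 0, ndel = 0)
  for (t in seq_len(tend)) {
    if (t == tstart) { out$q_start <- qi; out$r_start <- ri }
    if (ops[t] == 1L) {
      if (t >= tstart) {
        if (is_match[t]) out$score <- out$score + match
        else { out$nsub <- out$nsub + 1; out$score <- out$score + mismatch }
      }
      qi <- qi + 1; ri <- ri + 1
    } else if (ops[t] == 2L) {
      if (t >= tstart) { out$ndel <- out$ndel + 1; out$score <- out$score + gap }
      ri <- ri + 1
    } else {
      if (t >= tstart) { out$nins <- out$nins + 1; out$score <- out$score + gap }
      qi <- qi + 1
    }
  }
  out$q_end <- qi - 1; out$r_end <- ri - 1
  out$span <- out$r_end - out$r_start + 1
  out
}

# exhaustive oracle call set: best-scoring references with span >= min_overlap
oracle_call_set <- function(q, refs, min_overlap = 20) {
  alns <- lapply(refs$sequence, function(r) oracle_local_align(q, r))
  score <- vapply(alns, `[[`, numeric(1), "score")
  span <- vapply(alns, `[[`, numeric(1), "span")
  ok <- span >= min_overlap & score > 0
  if (!any(ok)) return("")
  best <- max(score[ok])
  paste(sort(refs$name[ok & score == best]), collapse = ",")
}

# direct binomial-likelihood haplotype decision (independent of the package's
# closed form): single-chromosome model with leak eps vs both-chromosome
# model with p = 0.5
oracle_hap_decision <- function(na, nb, anchors = c("A", "B"),
                                kThreDel = 0.1, certainty_min = 2,
                                epsilon = 0.01, min_minor_support = 2) {
  n <- na + nb
  if (n == 0) return(list(assignment = "unknown", certainty = NA_real_))
  minor <- min(na, nb)
  cert <- log10(dbinom(minor, n, epsilon) / dbinom(minor, n, 0.5))
  q <- minor / n
  if (q >= kThreDel && minor >= min_minor_support) {
    return(list(assignment = "both", certainty = cert))
  }
  if (q < kThreDel && cert >= certainty_min) {
    return(list(assignment = if (na >= nb) "anchorA_only" else "anchorB_only",
                certainty = cert))
  }
  list(assignment = "unknown", certainty = cert)
}

split_calls_chr <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",")[[1]]
}

# tiny deterministic germline set for toy alignments
toy_refs <- function(n = 5, len = 50, seed = 99) {
  set.seed(seed)
  germline_set(sprintf("TOY%02d", seq_len(n)), "V",
               vapply(seq_len(n), function(i)
                 paste(sample(c("a", "c", "g", "t"), len, TRUE),
                       collapse = ""), character(1)))
}

# small fast simulation configuration for unit tests
quick_config <- function(n_reads = 600, seed = 5, ...) {
  sim_config(n_reads = n_reads, seed = seed, ...)
}

errorfree_config <- function(n_reads = 300, seed = 9, ...) {
  sim_config(n_reads = n_reads, seed = seed,
             subst_error_rate = 0, homopolymer_indel_rate = 0,
             shm_rate_igm = 0, shm_rate_igg = 0, igm_unmutated_prob = 1,
             chimera_rate = 0, ...)
}
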