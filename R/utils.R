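# internal helpers

# derive a deterministic sub-seed (< 2^31) for an independent stage
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 99991 * stream) %% 2147483646 + 1)
}

# random DNA strings of the given lengths using the current RNG stream
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    if (L <= 0) return("")
    paste(sample(c("a", "c", "g", "t"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# substitute `k` random positions of `seq` with random different bases
mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("a", "c", "g", "t"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

base_at <- function(seq, pos) substr(seq, pos, pos)

set_base <- function(seq, pos, value) {
  paste0(substr(seq, 1, pos - 1), value, substr(seq, pos + 1, nchar(seq)))
}

# Hamming distance of equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# split a comma-separated call string into a character vector (empty -> chr(0))
split_calls <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ",", fixed = TRUE)[[1]]
}

first_call <- function(x) {
  ifelse(is.na(x) | !nzchar(x), NA_character_,
         vapply(strsplit(x, ",", fixed = TRUE), `[`, character(1), 1L))
}

n_calls <- function(x) {
  ifelse(is.na(x) | !nzchar(x), 0L, lengths(strsplit(x, ",", fixed = TRUE)))
}

# parse "refpos:base;refpos:base" mutation strings into a two-column matrix
parse_muts <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(pos = integer(0), base = character(0)))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(pos = as.integer(vapply(parts, `[`, character(1), 1L)),
             base = vapply(parts, `[`, character(1), 2L))
}
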