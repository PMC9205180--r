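#' Construct a germline reference set
#'
#' A germline set is a tibble of germline segment alleles (V, D, J or C exon)
#' with one row per allele. It is the common currency of the package: the
#' simulator emits one, the annotator consumes one, and curation functions
#' return updated ones.
#'
#' @param name character vector of unique allele names.
#' @param segment segment class of each allele: `"V"`, `"D"`, `"J"` or `"C"`.
#' @param sequence DNA sequences (lower-case `acgtn`).
#' @param functionality `"functional"`, `"ORF"`, `"pseudogene"` or `"unknown"`.
#' @param strain optional strain assignment (e.g. `"BALB"`, `"B6"`).
#' @param provenance `"reported"`, `"extended"` or `"inferred"`.
#' @param cys for V alleles, 1-based position of the first base of the
#'   conserved framework-3 cysteine codon (junction anchor); `NA` otherwise.
#' @param label a label for the whole set (stored as attribute `"label"`).
#'
#' @return a tibble of class `germline_set`.
#' @export
germline_set <- function(name, segment, sequence,
                         functionality = "functional", strain = NA_character_,
                         provenance = "reported", cys = NA_integer_,
                         label = "reference") {
  gs <- tibble::tibble(
    name = as.character(name),
    segment = as.character(segment),
    sequence = tolower(as.character(sequence)),
    functionality = rep_len(functionality, length(name)),
    strain = rep_len(as.character(strain), length(name)),
    provenance = rep_len(provenance, length(name)),
    cys = rep_len(as.integer(cys), length(name))
  )
  class(gs) <- c("germline_set", class(gs))
  attr(gs, "label") <- label
  validate_germline_set(gs)
  gs
}

#' Validate a germline set
#'
#' Checks name uniqueness, non-empty sequences and the `acgtn` alphabet.
#' Duplicate sequences under different names are legal (common for mouse IGHV)
#' and are reported by [duplicated_sequence_groups()] rather than rejected.
#'
#' @param gs a [germline_set()].
#' @return `gs`, invisibly; errors on violation.
#' @export
validate_germline_set <- function(gs) {
  stopifnot(all(c("name", "segment", "sequence") %in% names(gs)))
  if (anyDuplicated(gs$name)) {
    stop("duplicate allele names: ",
         paste(unique(gs$name[duplicated(gs$name)]), collapse = ", "))
  }
  if (any(!nzchar(gs$sequence))) stop("empty sequences in germline set")
  if (any(grepl("[^acgtn]", gs$sequence))) {
    stop("sequences must use the alphabet {a,c,g,t,n}")
  }
  invisible(gs)
}

#' Report groups of identical sequences within a germline set
#'
#' @param gs a [germline_set()].
#' @return a list of character vectors, one per group of alleles sharing an
#'   identical sequence (groups of size one omitted).
#' @export
duplicated_sequence_groups <- function(gs) {
  sp <- split(gs$name, gs$sequence)
  unname(sp[lengths(sp) > 1])
}

#' Read a germline set from FASTA
#'
#' Headers may carry `|key=value` metadata fields (`segment`, `strain`,
#' `functionality`, `provenance`, `cys`, and free-form notes), as written by
#' [write_germline_fasta()].
#'
#' @param path FASTA file.
#' @param segment default segment class for records without a `segment` field.
#' @return a [germline_set()].
#' @export
read_germline_fasta <- function(path, segment = "V") {
  xs <- Biostrings::readDNAStringSet(path)
  heads <- names(xs)
  parse_field <- function(h, key) {
    m <- regmatches(h, regexpr(paste0("\\|", key, "=[^|]*"), h))
    if (length(m) == 0) return(NA_character_)
    sub(paste0("^\\|", key, "="), "", m)
  }
  nm <- sub("\\|.*$", "", heads)
  seg <- vapply(heads, parse_field, character(1), key = "segment")
  gs <- germline_set(
    name = nm,
    segment = ifelse(is.na(seg), segment, seg),
    sequence = tolower(as.character(xs)),
    functionality = {
      f <- vapply(heads, parse_field, character(1), key = "functionality")
      ifelse(is.na(f), "functional", f)
    },
    strain = vapply(heads, parse_field, character(1), key = "strain"),
    provenance = {
      p <- vapply(heads, parse_field, character(1), key = "provenance")
      ifelse(is.na(p), "reported", p)
    },
    cys = suppressWarnings(as.integer(
      vapply(heads, parse_field, character(1), key = "cys")))
  )
  gs
}

#' Write a germline set to FASTA with metadata headers
#'
#' @param gs a [germline_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(gs, path) {
  heads <- paste0(
    gs$name,
    "|segment=", gs$segment,
    ifelse(is.na(gs$strain), "", paste0("|strain=", gs$strain)),
    "|functionality=", gs$functionality,
    "|provenance=", gs$provenance,
    ifelse(is.na(gs$cys), "", paste0("|cys=", gs$cys))
  )
  xs <- Biostrings::DNAStringSet(gs$sequence)
  names(xs) <- heads
  Biostrings::writeXStringSet(xs, path, width = 80)
  invisible(path)
}

#' Subset a germline set by allele name
#'
#' @param gs a [germline_set()].
#' @param names allele names to keep.
#' @return the subset, in the order given.
#' @export
germline_subset <- function(gs, names) {
  out <- gs[match(names, gs$name), , drop = FALSE]
  if (anyNA(out$name)) {
    stop("alleles not in set: ",
         paste(setdiff(names, gs$name), collapse = ", "))
  }
  out
}
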