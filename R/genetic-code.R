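#' The standard nuclear genetic code
#'
#' Returns the standard genetic code as a named character vector mapping all
#' 64 DNA triplets to amino-acid one-letter codes, with `"*"` for the three
#' stop codons (TAA, TAG, TGA). This is the default code used throughout the
#' package; alternative codes (any named length-64 vector with the same key
#' structure) can be injected into every function that takes a `code`
#' argument.
#'
#' @return Named character vector of length 64; names are codons over
#'   `{A,C,G,T}`, values are one-letter amino-acid codes or `"*"`.
#' @examples
#' code <- standard_genetic_code()
#' code[["ATG"]]                     # "M"
#' sum(code == "*")                  # 3 stop codons
#' @export
standard_genetic_code <- function() {
  # codon order: first base slowest, bases ordered T, C, A, G
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aas, codons)
}

validate_genetic_code <- function(code) {
  if (!is.character(code) || length(code) != 64L || is.null(names(code)) ||
      anyDuplicated(names(code)) || any(nchar(names(code)) != 3L) ||
      any(grepl("[^ACGT]", names(code)))) {
    abort("`code` must map all 64 distinct ACGT triplets to amino acids.",
          class = "degronscan_config_error")
  }
  if (any(!code %in% aa_alphabet(include_stop = TRUE))) {
    abort("`code` values must be one-letter amino-acid codes or \"*\".",
          class = "degronscan_config_error")
  }
  invisible(code)
}

#' Translate DNA sequences codon-by-codon
#'
#' Deterministic lookup translation. Input sequences must consist only of
#' `A`, `C`, `G`, `T` (IUPAC ambiguity codes are rejected here; reads with
#' ambiguous bases are filtered out upstream by [extract_and_classify()]) and
#' have length a positive multiple of 3. Stop codons translate to `"*"` and
#' are carried in the output rather than truncating it.
#'
#' @param dna Character vector of DNA sequences.
#' @param code Genetic code, as returned by [standard_genetic_code()].
#' @return Character vector of peptides, `nchar(dna)/3` residues each.
#' @examples
#' translate_dna("ATTCATCCGTATTGG")   # "IHPYW"
#' translate_dna(c("TAA", "ATGATG")) # "*", "MM"
#' @export
translate_dna <- function(dna, code = standard_genetic_code()) {
  validate_genetic_code(code)
  if (length(dna) == 0L) return(character(0))
  if (!is.character(dna) || anyNA(dna)) {
    abort("`dna` must be a character vector without NAs.",
          class = "degronscan_alphabet_error")
  }
  len <- nchar(dna)
  if (any(len == 0L) || any(len %% 3L != 0L)) {
    abort("All sequences must have length a positive multiple of 3.",
          class = "degronscan_length_error")
  }
  if (any(grepl("[^ACGT]", dna))) {
    abort("Sequences may only contain A, C, G, T.",
          class = "degronscan_alphabet_error")
  }
  out <- character(length(dna))
  for (L in unique(len)) {
    i <- which(len == L)
    starts <- seq.int(1L, L - 2L, by = 3L)
    codons <- vapply(starts, function(s) substr(dna[i], s, s + 2L),
                     character(length(i)))
    aa <- matrix(code[codons], nrow = length(i))
    out[i] <- do.call(paste0, lapply(seq_len(ncol(aa)), function(j) aa[, j]))
  }
  out
}

#' Theoretical diversity of a randomized library
#'
#' Number of distinct sequences over an alphabet of `alphabet_size` symbols
#' at `num_positions` independent positions, `alphabet_size ^ num_positions`.
#' For a pentapeptide library over the 20 amino acids this is
#' `20^5 = 3,200,000`.
#'
#' @param num_positions,alphabet_size Positive integers.
#' @return A single number (exact for all library sizes representable in a
#'   double, i.e. below 2^53).
#' @examples
#' theoretical_diversity(5, 20)  # 3.2e6
#' @export
theoretical_diversity <- function(num_positions, alphabet_size) {
  assert_scalar_number(num_positions, "num_positions", lower = 1)
  assert_scalar_number(alphabet_size, "alphabet_size", lower = 1)
  if (num_positions != round(num_positions) ||
      alphabet_size != round(alphabet_size)) {
    abort("`num_positions` and `alphabet_size` must be whole numbers.",
          class = "degronscan_domain_error")
  }
  res <- alphabet_size^num_positions
  if (res >= 2^53) {
    abort("Diversity exceeds exact double-precision integer range.",
          class = "degronscan_domain_error")
  }
  res
}
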