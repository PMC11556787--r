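# IUPAC degenerate nucleotide alphabet, used to parse scheme names like "NNK"
iupac_nucleotides <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

#' Define a degenerate-codon scheme
#'
#' A degenerate-codon scheme describes the randomized codon used at every
#' variable position of the library: one nucleotide alphabet per codon
#' position. It is the "expectation side" of the screen's enrichment ratio —
#' the null amino-acid distribution of the library before any selection.
#'
#' @param name Scheme label. If `position_alphabets` is `NULL` the name is
#'   parsed as three IUPAC degenerate-nucleotide letters (e.g. `"NNN"`,
#'   `"NNK"`).
#' @param position_alphabets Optional list of three character vectors, the
#'   allowed nucleotides at each codon position. Overrides name parsing.
#' @param num_codon_positions Number of randomized codons in the variable
#'   region (5 for a pentapeptide library).
#' @return An object of class `codon_scheme`: a list with fields `name`,
#'   `position_alphabets`, `num_codon_positions` and the enumerated codon set
#'   `codons`.
#' @examples
#' codon_scheme("NNN")$codons |> length()  # 64
#' codon_scheme("NNK")$codons |> length()  # 32
#' @export
codon_scheme <- function(name = "NNN", position_alphabets = NULL,
                         num_codon_positions = 5L) {
  assert_scalar_number(num_codon_positions, "num_codon_positions", lower = 1)
  if (is.null(position_alphabets)) {
    if (!is.character(name) || length(name) != 1L || nchar(name) != 3L) {
      abort("`name` must be a 3-letter IUPAC codon label (e.g. \"NNN\").",
            class = "degronscan_config_error")
    }
    letters3 <- strsplit(toupper(name), "")[[1]]
    iupac <- iupac_nucleotides()
    if (any(!letters3 %in% names(iupac))) {
      abort(sprintf("Unknown IUPAC letter in scheme name \"%s\".", name),
            class = "degronscan_config_error")
    }
    position_alphabets <- unname(iupac[letters3])
  }
  if (!is.list(position_alphabets) || length(position_alphabets) != 3L) {
    abort("`position_alphabets` must be a list of three nucleotide sets.",
          class = "degronscan_config_error")
  }
  for (al in position_alphabets) {
    if (length(al) == 0L || anyDuplicated(al) || any(!al %in% c("A", "C", "G", "T"))) {
      abort("Each codon-position alphabet must be a non-empty subset of {A,C,G,T}.",
            class = "degronscan_config_error")
    }
  }
  codons <- as.vector(outer(
    as.vector(outer(position_alphabets[[1]], position_alphabets[[2]], paste0)),
    position_alphabets[[3]], paste0))
  structure(
    list(name = name,
         position_alphabets = position_alphabets,
         num_codon_positions = as.integer(num_codon_positions),
         codons = codons),
    class = "codon_scheme")
}

#' @export
print.codon_scheme <- function(x, ...) {
  cat(sprintf("<codon_scheme %s: %d codons/position, %d positions>\n",
              x$name, length(x$codons), x$num_codon_positions))
  invisible(x)
}

#' Per-position amino-acid null distribution of a degenerate codon
#'
#' The expected amino-acid frequency at any randomized position is the number
#' of codons in the scheme's codon set encoding that amino acid divided by the
#' size of the set. For an NNN library, isoleucine is expected at 3/64
#' (4.7%) and leucine at 6/64 (9.4%) of positions. Stop mass is carried in the
#' distribution under the symbol `"*"` because those printed fractions are out
#' of all 64 codons, stops included; set `renormalize_sense = TRUE` to condition
#' on sense codons instead.
#'
#' @param scheme A [codon_scheme()].
#' @param code Genetic code (see [standard_genetic_code()]).
#' @param renormalize_sense If `TRUE`, drop `"*"` and renormalize over the 61
#'   (for NNN) sense codons.
#' @return A tibble of class `aa_distribution` with columns `symbol` (the 20
#'   amino acids, plus `"*"` unless renormalized) and `probability`, and an
#'   attribute `scheme_name`. Probabilities sum to 1.
#' @examples
#' null <- position_null_distribution(codon_scheme("NNN"))
#' null$probability[null$symbol == "I"]  # 3/64
#' @export
position_null_distribution <- function(scheme, code = standard_genetic_code(),
                                       renormalize_sense = FALSE) {
  if (!inherits(scheme, "codon_scheme")) {
    abort("`scheme` must be a codon_scheme object.",
          class = "degronscan_config_error")
  }
  validate_genetic_code(code)
  if (length(scheme$codons) == 0L) {
    abort("Scheme enumerates no codons.", class = "degronscan_config_error")
  }
  aa <- code[scheme$codons]
  symbols <- aa_alphabet(include_stop = !renormalize_sense)
  counts <- table(factor(aa, levels = symbols))
  total <- if (renormalize_sense) sum(counts) else length(scheme$codons)
  if (total == 0L) {
    abort("Scheme has no sense codons to renormalize over.",
          class = "degronscan_config_error")
  }
  out <- tibble(symbol = symbols,
                probability = as.numeric(counts) / total)
  attr(out, "scheme_name") <- scheme$name
  attr(out, "renormalized") <- renormalize_sense
  class(out) <- c("aa_distribution", class(out))
  out
}

#' Write an amino-acid distribution as TSV
#'
#' @param dist An `aa_distribution` tibble.
#' @param path Output path.
#' @export
write_null_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "aa_distribution"))
  readr::write_tsv(tibble(symbol = dist$symbol,
                          probability = dist$probability), path)
  invisible(path)
}
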