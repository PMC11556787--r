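# Shared fixtures: small geometries so unit tests stay fast. The full 217-bp
# default geometry is exercised in the pipeline and acceptance tests.

tiny_read_cfg <- function(reads_per_sample = 200L,
                          substitution_error_rate = 0,
                          seed = 7L, ...) {
  read_sim_config(
    upstream_flank = "ACGTACGTACGTACGTACGA",
    downstream_flank = "TGCATGCATGCATGCATGCA",
    reads_per_sample = reads_per_sample,
    substitution_error_rate = substitution_error_rate,
    seed = seed,
    ...)
}

tiny_layout <- function(cfg = tiny_read_cfg(), ...) default_layout(cfg, ...)

# one FASTQ record per element of `seqs`, constant quality
write_tiny_fastq <- function(seqs, path = tempfile(fileext = ".fastq"),
                             quality_char = "I") {
  n <- length(seqs)
  lines <- character(4 * n)
  lines[seq(1, by = 4, length.out = n)] <- paste0("@r", seq_len(n))
  lines[seq(2, by = 4, length.out = n)] <- seqs
  lines[seq(3, by = 4, length.out = n)] <- "+"
  lines[seq(4, by = 4, length.out = n)] <- strrep(quality_char, nchar(seqs))
  writeLines(lines, path)
  path
}

# peptide -> one DNA encoding, via the first codon per amino acid
encode_peptide <- function(peptide) {
  code <- standard_genetic_code()
  first_codon <- names(code)[!duplicated(code)]
  names(first_codon) <- code[!duplicated(code)]
  paste(first_codon[strsplit(peptide, "")[[1]]], collapse = "")
}
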