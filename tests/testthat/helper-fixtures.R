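# In-code fixtures shared across test files.

# A tiny genome from a compact gene table. Gene DNA spans are filled with a
# repeated codon so translations are well defined but arbitrary.
tinyGenome <- function(genes, len = max(genes$end) + 10L, acc = "TOY001") {
  seq <- strrep("ACGTTGCAGG", ceiling(len / 10))
  seq <- substr(seq, 1, len)
  if (!"protein_seq" %in% names(genes)) genes$protein_seq <- NA_character_
  PhageGenome(accession = acc, sequence = seq, features = genes)
}

# Gene table row helper
gene <- function(id, start, end, strand = "+", product = "hypothetical protein",
                 role = NULL, protein = NA_character_) {
  df <- data.frame(feature_id = id, start = start, end = end, strand = strand,
                   product = product, protein_seq = protein,
                   stringsAsFactors = FALSE)
  if (!is.null(role)) df$role <- role
  df
}

# A cassette genome with roles pre-assigned (skips keyword classification)
rolesGenome <- function(roles, strand = "+", gap = 50L, acc = "TOY001") {
  n <- length(roles)
  width <- 300L
  starts <- 1L + (seq_len(n) - 1L) * (width + gap)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    gene(sprintf("%s_%02d", acc, i), starts[i], starts[i] + width - 1L,
         strand = strand, product = roles[i], role = roles[i])
  }))
  tinyGenome(df, acc = acc)
}

# Minimal domain hit rows in the package's annotated layout
hitRow <- function(protein_id, domain, from, to, e = 1e-10, bits = 100) {
  annotateHits(data.frame(protein_id = protein_id, domain_name = domain,
                          source_db = "PF_SYN", ali_from = from, ali_to = to,
                          e_value = e, bit_score = bits,
                          stringsAsFactors = FALSE))
}
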