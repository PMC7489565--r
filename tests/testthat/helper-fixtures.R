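# Shared fixtures, built in code and memoised for the session.

.fixture_cache <- new.env(parent = emptyenv())

# The canonical mad fixture bundle (seed 42 is the packaged fixture seed).
mad_bundle <- function() {
  if (is.null(.fixture_cache$mad))
    .fixture_cache$mad <- make_cluster(mad_architecture(), seed = 42)
  .fixture_cache$mad
}

mad_target <- function() {
  if (is.null(.fixture_cache$target))
    .fixture_cache$target <- chain_from_target(
      pk_extdata("tetromadurin_target.json"))
  .fixture_cache$target
}

mad_calls <- function() {
  if (is.null(.fixture_cache$calls))
    .fixture_cache$calls <- annotate_cluster(mad_bundle()$cluster,
                                             target = mad_target())
  .fixture_cache$calls
}

# Independent SMILES -> formula oracle: Open Babel, batch over one file.
obabel_formulas <- function(smiles) {
  smi <- tempfile(fileext = ".smi")
  writeLines(smiles, smi)
  out <- system2("obabel", c(smi, "-otxt", "--append", "formula"),
                 stdout = TRUE, stderr = FALSE)
  out[seq_along(smiles)]
}

# A random valid linear chain for property tests (seeded by the caller).
random_chain <- function() {
  starter <- monomer_state("LM", sample(c("acetate", "propionate"), 1))
  n <- sample(1:8, 1)
  ext <- lapply(seq_len(n), function(i) {
    extd <- sample(c("acetate", "propionate", "methoxymalonate"), 1,
                   prob = c(0.45, 0.45, 0.1))
    beta <- sample(c("ketone", "hydroxyl", "enoyl_double_bond", "methylene"), 1)
    bst <- if (beta == "hydroxyl") sample(c("D", "L"), 1) else "none"
    alpha <- switch(extd, acetate = "none", propionate = "methyl",
                    methoxymalonate = "methoxy")
    ast <- if (alpha == "methyl" && beta %in% c("hydroxyl", "methylene"))
      sample(c("D", "L", "none"), 1) else "none"
    monomer_state(i, extd, beta, bst, alpha, ast)
  })
  linear_chain(starter, ext, "from_target")
}

# Write a minimal GenBank flat file; returns the path.
write_genbank_fixture <- function(cds, locus = "SYNCLUST01") {
  lines <- c(sprintf(
    "LOCUS       %s              9000 bp    DNA     linear   BCT 01-JAN-2026",
    locus),
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..9000")
  at <- 1L
  for (g in cds) {
    lines <- c(lines, sprintf("     CDS             %d..%d", at, at + 299L))
    at <- at + 400L
    if (!is.null(g$gene))
      lines <- c(lines, sprintf("                     /gene=\"%s\"", g$gene))
    if (!is.null(g$locus_tag))
      lines <- c(lines, sprintf("                     /locus_tag=\"%s\"", g$locus_tag))
    if (!is.null(g$product))
      lines <- c(lines, sprintf("                     /product=\"%s\"", g$product))
    if (!is.null(g$translation))
      lines <- c(lines, sprintf("                     /translation=\"%s\"", g$translation))
  }
  lines <- c(lines, "ORIGIN", "//")
  path <- tempfile(fileext = ".gb")
  writeLines(lines, path)
  path
}

# Reverse-translate a peptide with fixed codons (for start-revision fixtures).
reverse_translate <- function(peptide) {
  codons <- c(M = "ATG", S = "AGC", D = "GAC", V = "GTG", I = "ATC",
              G = "GGC", A = "GCG", P = "CCG", L = "CTG", K = "AAG",
              T = "ACC", E = "GAG", R = "CGC", F = "TTC", H = "CAC")
  paste(codons[strsplit(peptide, "")[[1]]], collapse = "")
}
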