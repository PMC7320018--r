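# Shared builders for small in-memory fixtures.

# A tiny omics view from a values matrix given as sample x attribute.
make_view <- function(name, values, samples = NULL, attrs = NULL,
                      genes = NULL) {
  if (is.null(samples)) {
    samples <- rownames(values)
    if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(values)))
  }
  if (is.null(attrs)) {
    attrs <- colnames(values)
    if (is.null(attrs)) attrs <- sprintf("%s_a%02d", name, seq_len(ncol(values)))
  }
  dimnames(values) <- list(samples, attrs)
  omics_view(name, values, gene_symbols = genes)
}

# Small TCGA-BRCA-shaped cohort for pipeline tests.
small_cohort <- function(n = 120, width = 200, delta = 2.5, n_down = 3,
                         n_up = 2, seed = 3,
                         view_widths = c(isoform = width), ...) {
  generate_cohort(cohort_config(
    n_samples = n, view_widths = view_widths,
    n_planted_down = n_down, n_planted_up = n_up, effect_size = delta,
    seed = seed, ...))
}

# Write a SAINTexpress-style table; rows is a data frame with columns
# Bait, Prey, PreyGene, AvgSpec, FoldChange, BFDR (extra columns allowed).
write_saint_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

saint_rows <- function(genes, bfdr, bait = "BAIT") {
  data.frame(Bait = bait, Prey = paste0("P_", genes), PreyGene = genes,
             AvgSpec = seq_along(genes) + 1, FoldChange = 2,
             BFDR = bfdr, stringsAsFactors = FALSE)
}

write_crapome_fixture <- function(genes, counts,
                                  path = tempfile(fileext = ".tsv")) {
  write.table(data.frame(Gene = genes, NumExpt = counts), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path
}
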