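#' Read a SAINTexpress-style interaction score table
#'
#' Reads a tab-delimited bait-prey table as produced by SAINTexpress. Column
#' matching is tolerant: `Bait`, `Prey`, `PreyGene`, `AvgSpec`, `FoldChange`
#' and `BFDR` are recognised case-insensitively and ignoring punctuation
#' (so `Prey.Gene`, `prey_gene` and `PreyGene` are equivalent). `Bait`,
#' `Prey`, `PreyGene` and `BFDR` are mandatory; a missing one raises an error
#' naming it. Rows with an unparseable or out-of-range BFDR are dropped with a
#' warning listing their line numbers.
#'
#' @param path file path.
#' @param assay `"apms"` or `"bioid"`; recorded on every row.
#' @return data frame of class `"saint_table"` with columns `bait`, `prey`,
#'   `prey_gene`, `avg_spec`, `fold_change`, `bfdr`, `assay`.
#' @export
read_saint_table <- function(path, assay = c("apms", "bioid")) {
  assay <- match.arg(assay)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  have <- norm(names(df))
  pick <- function(key) {
    j <- which(have == key)
    if (length(j)) df[[j[1L]]] else NULL
  }
  mandatory <- c(Bait = "bait", Prey = "prey", PreyGene = "preygene",
                 BFDR = "bfdr")
  for (nm in names(mandatory)) {
    if (!mandatory[[nm]] %in% have) {
      stop("missing mandatory column '", nm, "' in ", path)
    }
  }
  bfdr <- suppressWarnings(as.numeric(pick("bfdr")))
  bad <- which(is.na(bfdr) | bfdr < 0 | bfdr > 1)
  out <- data.frame(
    bait = as.character(pick("bait")),
    prey = as.character(pick("prey")),
    prey_gene = as.character(pick("preygene")),
    avg_spec = if (is.null(pick("avgspec"))) NA_real_ else
      suppressWarnings(as.numeric(pick("avgspec"))),
    fold_change = if (is.null(pick("foldchange"))) NA_real_ else
      suppressWarnings(as.numeric(pick("foldchange"))),
    bfdr = bfdr,
    assay = assay,
    stringsAsFactors = FALSE
  )
  if (length(bad)) {
    warning("dropping ", length(bad), " malformed row(s) (file line ",
            paste(bad + 1L, collapse = ", "), "): BFDR missing or outside [0, 1]")
    out <- out[-bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("saint_table", "data.frame")
  out
}

#' Read a contaminant-frequency (Crapome-style) profile
#'
#' A two-column delimited table mapping prey gene symbols to the number of
#' negative-control experiments (out of `n_experiments`) in which the protein
#' was observed.
#'
#' @param path file path (tab-delimited, header row; first column gene, second
#'   column count).
#' @param n_experiments size of the control experiment universe (411 in the
#'   standard FLAG-tag set).
#' @return named integer vector: gene symbol -> observation count.
#' @export
read_crapome_profile <- function(path, n_experiments = 411) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected at least two columns (gene, count)")
  counts <- suppressWarnings(as.integer(df[[2L]]))
  if (anyNA(counts) || any(counts < 0) || any(counts > n_experiments)) {
    stop("contaminant counts must be integers in [0, ", n_experiments, "]")
  }
  stats::setNames(counts, as.character(df[[1L]]))
}

#' Keep interactions at or below a BFDR cutoff
#'
#' Significant interactors are those with a Bayesian false discovery rate at
#' or below the cutoff (the standard threshold is 0.01; the bound is
#' inclusive).
#'
#' @param records a [read_saint_table()] data frame.
#' @param cutoff BFDR cutoff in \[0, 1\].
#' @return the filtered records (a subset of the input; idempotent).
#' @export
filter_bfdr <- function(records, cutoff = 0.01) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  out <- records[records$bfdr <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop frequent contaminants using a control-frequency profile
#'
#' Keeps records whose prey gene was observed at most `max_count` times in the
#' negative-control universe (the standard cut-off is 0-20 of 411
#' experiments, inclusive). A gene absent from the profile has no evidence of
#' being a contaminant and is kept (treated as count 0).
#'
#' @param records a [read_saint_table()] data frame.
#' @param profile named counts from [read_crapome_profile()].
#' @param max_count inclusive upper bound on the contaminant frequency.
#' @return the filtered records (a subset of the input; idempotent).
#' @export
filter_crapome <- function(records, profile, max_count = 20) {
  counts <- profile[records$prey_gene]
  counts[is.na(counts)] <- 0L
  out <- records[counts <= max_count, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of distinct prey genes in a record set
#'
#' Interactor counts are reported per distinct prey gene, not per table row
#' (a prey may occur on several rows).
#'
#' @param records a [read_saint_table()] data frame.
#' @return integer.
#' @export
n_interactors <- function(records) length(unique(records$prey_gene))

#' Classify interactors by assay overlap and prior knowledge
#'
#' Partitions the union of the AP-MS and BioID interactor sets into
#' AP-MS-only, BioID-only and both, and annotates each gene's membership in a
#' known-interactor list (e.g. Biogrid).
#'
#' @param apms_genes,bioid_genes character vectors of prey gene symbols.
#' @param known_genes character vector of previously reported interactors.
#' @return object of class `"overlap_report"`: list with the three disjoint
#'   sets (`apms_only`, `bioid_only`, `both`), their sizes (`counts`), and
#'   `known` (named logical per gene of the union).
#' @export
overlap_report <- function(apms_genes, bioid_genes, known_genes = character(0)) {
  apms_genes <- unique(as.character(apms_genes))
  bioid_genes <- unique(as.character(bioid_genes))
  both <- sort(intersect(apms_genes, bioid_genes))
  apms_only <- sort(setdiff(apms_genes, bioid_genes))
  bioid_only <- sort(setdiff(bioid_genes, apms_genes))
  all_genes <- c(apms_only, bioid_only, both)
  known <- stats::setNames(all_genes %in% known_genes, all_genes)
  structure(list(apms_only = apms_only, bioid_only = bioid_only, both = both,
                 counts = c(apms_only = length(apms_only),
                            bioid_only = length(bioid_only),
                            both = length(both)),
                 known = known),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Interactor overlap: %d AP-MS only, %d BioID only, %d shared\n",
              x$counts[["apms_only"]], x$counts[["bioid_only"]],
              x$counts[["both"]]))
  kn <- names(x$known)[x$known]
  if (length(kn)) {
    cat("  previously reported:", paste(kn, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full interactor filtering chain
#'
#' Applies the BFDR significance filter and then the contaminant-frequency
#' filter (the two commute) to AP-MS and BioID tables of the same bait, and
#' reports the distinct-gene counts at each stage plus the overlap
#' classification.
#'
#' @param apms,bioid [read_saint_table()] data frames.
#' @param profile contaminant profile from [read_crapome_profile()].
#' @param known_genes known interactors for the overlap annotation.
#' @param bfdr_cutoff,max_crapome the two inclusive cut-offs.
#' @return list with the filtered tables (`apms`, `bioid`), a `counts` data
#'   frame (stage x assay distinct-gene counts) and the `overlap` report.
#' @export
filter_interactors <- function(apms, bioid, profile,
                               known_genes = character(0),
                               bfdr_cutoff = 0.01, max_crapome = 20) {
  stage <- function(rec) {
    sig <- filter_bfdr(rec, bfdr_cutoff)
    fin <- filter_crapome(sig, profile, max_crapome)
    list(significant = sig, final = fin)
  }
  a <- stage(apms)
  b <- stage(bioid)
  counts <- data.frame(
    assay = c("apms", "bioid"),
    input = c(n_interactors(apms), n_interactors(bioid)),
    bfdr_significant = c(n_interactors(a$significant),
                         n_interactors(b$significant)),
    final = c(n_interactors(a$final), n_interactors(b$final)),
    stringsAsFactors = FALSE
  )
  list(apms = a$final, bioid = b$final, counts = counts,
       overlap = overlap_report(unique(a$final$prey_gene),
                                unique(b$final$prey_gene), known_genes))
}
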