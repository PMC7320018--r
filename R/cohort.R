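#' Breast cancer subtype and TNBC label from receptor status
#'
#' Immunohistochemistry-style receptor calls determine the subtype: triple
#' negative (ER-, PR-, HER2-) is the positive class; Luminal A is ER+ and/or
#' PR+ with HER2-; Luminal B is ER+ and/or PR+ with HER2+; the HER2 subtype is
#' ER-, PR-, HER2+. The mapping is total over the eight receptor combinations.
#'
#' @param er,pr,her2 receptor status, each `"positive"` or `"negative"`
#'   (vectorised).
#' @return data frame with columns `subtype` (`"TNBC"`, `"LuminalA"`,
#'   `"LuminalB"`, `"HER2"`) and `label` (1 = TNBC).
#' @examples
#' derive_subtype("negative", "negative", "negative")  # TNBC, label 1
#' derive_subtype("positive", "negative", "negative")  # LuminalA, label 0
#' @export
derive_subtype <- function(er, pr, her2) {
  chk <- function(v, what) {
    if (!all(v %in% c("positive", "negative"))) {
      stop(what, " status must be 'positive' or 'negative'")
    }
    v == "positive"
  }
  n <- max(length(er), length(pr), length(her2))
  erp <- rep_len(chk(er, "ER"), n)
  prp <- rep_len(chk(pr, "PR"), n)
  h2p <- rep_len(chk(her2, "HER2"), n)
  hr <- erp | prp  # hormone-receptor positive
  subtype <- ifelse(!hr & !h2p, "TNBC",
             ifelse(hr & !h2p, "LuminalA",
             ifelse(hr & h2p, "LuminalB", "HER2")))
  data.frame(subtype = subtype, label = as.integer(subtype == "TNBC"),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic multi-omics cohort generator
#'
#' Defaults encode the TCGA-BRCA-like study conditions: 877 patients of whom
#' 16% are TNBC, 63% Luminal A, 16% Luminal B and 5% HER2; an RNA isoform
#' expression view of 73,599 attributes, a miRNA view of 1,046 attributes, and
#' two methylation platform views whose probe union is 23,381 (so the fused
#' feature space has 98,026 attributes); and 15 down-regulated plus 5
#' up-regulated discriminative genes planted in the isoform view.
#'
#' @param n_samples number of patients.
#' @param subtype_fractions named fractions for `TNBC`, `LuminalA`,
#'   `LuminalB`, `HER2`; must sum to 1.
#' @param view_widths named attribute counts for the `isoform`, `mirna`,
#'   `methyl450` and `methyl27` views.
#' @param methyl_shared number of probes present on both methylation
#'   platforms; the fused view width is
#'   `methyl450 + methyl27 - methyl_shared`.
#' @param isoforms_per_gene isoform attributes per gene symbol in the isoform
#'   view.
#' @param n_planted_down,n_planted_up number of planted discriminative
#'   attributes (one per gene) shifted down / up in the TNBC class.
#' @param effect_size standardised class-mean shift delta: planted attributes
#'   are shifted by `delta * noise_sd` in TNBC samples.
#' @param noise_sd per-attribute standard deviation of the background signal.
#' @param missing_rate fraction of methylation entries set missing (methylation
#'   is the only view with missingness).
#' @param planted_view view receiving the planted signals (default
#'   `"isoform"`, where all reported discriminative genes were found).
#' @param seed master seed; every view, the clinical table and the planting
#'   draw from substreams derived from it, so the same configuration
#'   reproduces the cohort exactly.
#' @return a validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 877,
                          subtype_fractions = c(TNBC = 0.16, LuminalA = 0.63,
                                                LuminalB = 0.16, HER2 = 0.05),
                          view_widths = c(isoform = 73599, mirna = 1046,
                                          methyl450 = 21381, methyl27 = 4000),
                          methyl_shared = 2000,
                          isoforms_per_gene = 4,
                          n_planted_down = 15, n_planted_up = 5,
                          effect_size = 2, noise_sd = 1,
                          missing_rate = 0.1,
                          planted_view = "isoform",
                          seed = 1) {
  need <- c("TNBC", "LuminalA", "LuminalB", "HER2")
  if (!all(need %in% names(subtype_fractions))) {
    stop("subtype_fractions must name TNBC, LuminalA, LuminalB and HER2")
  }
  subtype_fractions <- subtype_fractions[need]
  if (abs(sum(subtype_fractions) - 1) > 1e-9) {
    stop("subtype_fractions must sum to 1")
  }
  if (n_samples < 2) stop("n_samples must be at least 2")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (is.null(names(view_widths)) || any(!nzchar(names(view_widths)))) {
    stop("view_widths must be a named vector")
  }
  if (!planted_view %in% names(view_widths)) {
    stop("planted_view must be one of the configured views")
  }
  n_planted <- n_planted_down + n_planted_up
  if (n_planted > view_widths[[planted_view]]) {
    stop("more planted attributes than attributes in the planted view")
  }
  methyl_views <- grep("^methyl", names(view_widths), value = TRUE)
  if (length(methyl_views) == 2L) {
    if (methyl_shared > min(view_widths[methyl_views])) {
      stop("methyl_shared exceeds a platform's probe count")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 subtype_fractions = subtype_fractions,
                 view_widths = view_widths,
                 methyl_shared = as.integer(methyl_shared),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 n_planted_down = as.integer(n_planted_down),
                 n_planted_up = as.integer(n_planted_up),
                 effect_size = effect_size, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 planted_view = planted_view,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Largest-remainder apportionment of n into the given fractions: exact total,
# and no count deviates from n * fraction by more than 1.
apportion_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    rem <- raw - base
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

# Receptor combinations consistent with each subtype; luminal subtypes pick
# uniformly among their ER/PR-positive patterns.
receptor_patterns <- list(
  TNBC = matrix(c("negative", "negative", "negative"), 1, 3),
  LuminalA = matrix(c("positive", "positive", "negative",
                      "positive", "negative", "negative",
                      "negative", "positive", "negative"),
                    3, 3, byrow = TRUE),
  LuminalB = matrix(c("positive", "positive", "positive",
                      "positive", "negative", "positive",
                      "negative", "positive", "positive"),
                    3, 3, byrow = TRUE),
  HER2 = matrix(c("negative", "negative", "positive"), 1, 3)
)

#' Generate a labeled synthetic multi-omics cohort
#'
#' Emulates the statistical structure of a TCGA-BRCA-style breast cancer
#' cohort: a clinical table of receptor calls, subtypes and TNBC labels with
#' subtype counts apportioned by largest remainder; one continuous omics view
#' per `view_widths` entry drawn from a class-independent Gaussian background
#' (`mean 0, sd noise_sd`); planted discriminative attributes whose TNBC class
#' mean is shifted by `+/- effect_size * noise_sd`; methylation views with
#' independently missing entries at `missing_rate`; and isoform attributes
#' grouped into genes in blocks of `isoforms_per_gene`. Each planted attribute
#' occupies a distinct gene, and the planted-signal manifest records the
#' ground-truth direction for recovery tests. Every view draws from its own
#' RNG substream derived from the master seed, so adding or dropping a view
#' leaves the others untouched, and the same configuration reproduces the
#' cohort bit for bit.
#'
#' Two methylation platform views share `methyl_shared` probe ids (the higher
#' and lower resolution platforms of [fuse_methylation()]).
#'
#' @param config a [cohort_config()].
#' @return an object of class `"tnbc_cohort"`: list with `clinical` (data
#'   frame `patient_id`, `er`, `pr`, `her2`, `subtype`, `label`), `views`
#'   (named list of [omics_view()]), `planted` (manifest data frame
#'   `attribute_id`, `view`, `gene_symbol`, `direction`, `effect_size`) and
#'   the `config`.
#' @examples
#' cfg <- cohort_config(n_samples = 60,
#'                      view_widths = c(isoform = 40, mirna = 10,
#'                                      methyl450 = 12, methyl27 = 6),
#'                      methyl_shared = 4, n_planted_down = 2,
#'                      n_planted_up = 1, seed = 7)
#' coh <- generate_cohort(cfg)
#' table(coh$clinical$subtype)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  counts <- apportion_counts(n, config$subtype_fractions)

  clinical <- with_seed(derive_seed(config$seed, "clinical"), {
    subtype <- sample(rep(names(counts), counts))
    rec <- t(vapply(subtype, function(s) {
      pat <- receptor_patterns[[s]]
      pat[sample.int(nrow(pat), 1L), ]
    }, character(3)))
    data.frame(patient_id = sprintf("S%05d", seq_len(n)),
               er = rec[, 1], pr = rec[, 2], her2 = rec[, 3],
               stringsAsFactors = FALSE)
  })
  ds <- derive_subtype(clinical$er, clinical$pr, clinical$her2)
  clinical$subtype <- ds$subtype
  clinical$label <- ds$label

  # attribute ids and gene registry per view
  make_ids <- function(view, w) {
    switch(view,
      isoform = {
        gene_idx <- ceiling(seq_len(w) / config$isoforms_per_gene)
        genes <- sprintf("GENE%05d", gene_idx)
        iso <- stats::ave(seq_len(w), gene_idx, FUN = seq_along)
        list(ids = sprintf("%s.iso%d", genes, iso), genes = genes)
      },
      mirna = list(ids = sprintf("mir%04d", seq_len(w)),
                   genes = rep(NA_character_, w)),
      methyl450 = list(ids = sprintf("cg%07d", seq_len(w)),
                       genes = rep(NA_character_, w)),
      methyl27 = {
        # the low-resolution platform shares its first `methyl_shared` probes
        # with the tail of the high-resolution platform
        w450 <- config$view_widths[["methyl450"]]
        start <- if (is.null(w450)) 0L else w450 - config$methyl_shared
        list(ids = sprintf("cg%07d", start + seq_len(w)),
             genes = rep(NA_character_, w))
      },
      list(ids = sprintf("%s_%05d", view, seq_len(w)),
           genes = rep(NA_character_, w))
    )
  }

  # planted attribute selection (in the planted view, one gene each)
  w_pl <- config$view_widths[[config$planted_view]]
  ids_pl <- make_ids(config$planted_view, w_pl)
  n_down <- config$n_planted_down
  n_up <- config$n_planted_up
  planted_cols <- integer(0)
  if (n_down + n_up > 0) {
    planted_cols <- with_seed(derive_seed(config$seed, "planted"), {
      if (config$planted_view == "isoform") {
        # one attribute per distinct gene: pick genes, then their first isoform
        gene_first <- which(!duplicated(ids_pl$genes))
        if (n_down + n_up > length(gene_first)) {
          stop("not enough distinct genes to host the planted attributes")
        }
        sort(sample(gene_first, n_down + n_up))
      } else {
        sort(sample.int(w_pl, n_down + n_up))
      }
    })
  }
  directions <- rep(c("down_in_tnbc", "up_in_tnbc"), c(n_down, n_up))
  if (length(planted_cols)) {
    directions <- with_seed(derive_seed(config$seed, "planted-directions"),
                            sample(directions))
  }

  tnbc_rows <- which(clinical$label == 1L)
  views <- list()
  for (view in names(config$view_widths)) {
    w <- config$view_widths[[view]]
    ids <- make_ids(view, w)
    vals <- with_seed(derive_seed(config$seed, paste0("view:", view)), {
      m <- matrix(stats::rnorm(n * w, 0, config$noise_sd), n, w)
      m
    })
    if (view == config$planted_view && length(planted_cols)) {
      shift <- ifelse(directions == "up_in_tnbc", 1, -1) *
        config$effect_size * config$noise_sd
      for (k in seq_along(planted_cols)) {
        vals[tnbc_rows, planted_cols[k]] <-
          vals[tnbc_rows, planted_cols[k]] + shift[k]
      }
    }
    if (grepl("^methyl", view) && config$missing_rate > 0) {
      mask <- with_seed(derive_seed(config$seed, paste0("missing:", view)),
                        stats::runif(n * w) < config$missing_rate)
      vals[matrix(mask, n, w)] <- NA_real_
    }
    dimnames(vals) <- list(clinical$patient_id, ids$ids)
    views[[view]] <- omics_view(view, vals, gene_symbols = ids$genes)
  }

  planted <- data.frame(
    attribute_id = ids_pl$ids[planted_cols],
    view = rep(config$planted_view, length(planted_cols)),
    gene_symbol = ids_pl$genes[planted_cols],
    direction = directions,
    effect_size = rep(config$effect_size, length(planted_cols)),
    stringsAsFactors = FALSE
  )

  structure(list(clinical = clinical, views = views, planted = planted,
                 config = config),
            class = "tnbc_cohort")
}

#' @export
print.tnbc_cohort <- function(x, ...) {
  tab <- table(x$clinical$subtype)
  cat(sprintf("Synthetic breast cancer cohort: %d samples (%d TNBC, %d non-TNBC)\n",
              nrow(x$clinical), sum(x$clinical$label == 1L),
              sum(x$clinical$label == 0L)))
  cat("  subtypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  for (v in x$views) {
    cat(sprintf("  view %-12s %d attributes, %.1f%% missing\n", v$name,
                ncol(v$values), 100 * mean(is.na(v$values))))
  }
  if (nrow(x$planted)) {
    cat(sprintf("  planted: %d down, %d up (delta = %g)\n",
                sum(x$planted$direction == "down_in_tnbc"),
                sum(x$planted$direction == "up_in_tnbc"),
                x$config$effect_size))
  }
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' One tab-delimited matrix per view (first column `sample_id`, header row of
#' attribute ids, missing as `NA`), the clinical table, and the planted-signal
#' manifest.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tnbc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in cohort$views) {
    p <- file.path(dir, paste0(v$name, ".tsv"))
    write_view_matrix(v, p)
    paths <- c(paths, p)
  }
  pc <- file.path(dir, "clinical.tsv")
  utils::write.table(cohort$clinical, pc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pp <- file.path(dir, "planted.tsv")
  utils::write.table(cohort$planted, pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, pc, pp))
}
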