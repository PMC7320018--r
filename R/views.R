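#' A single omics view
#'
#' One named feature matrix (samples x attributes) with an attribute registry
#' mapping each attribute to its view and, where known, a gene symbol.
#' Missing entries are `NA` in `values`; `missing_mask()` exposes them.
#'
#' @param name view name (e.g. `"isoform"`, `"methyl_fusion"`).
#' @param values numeric matrix with sample ids as row names and unique
#'   attribute ids as column names; `NA` marks a missing measurement.
#' @param gene_symbols optional character vector (length `ncol(values)`)
#'   mapping attributes to gene symbols; `NA` where no gene applies.
#' @return an object of class `"omics_view"`.
#' @export
omics_view <- function(name, values, gene_symbols = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry sample ids (rownames) and attribute ids (colnames)")
  }
  if (anyDuplicated(colnames(values))) {
    stop("attribute ids must be unique within a view")
  }
  if (anyDuplicated(rownames(values))) stop("sample ids must be unique")
  if (is.null(gene_symbols)) gene_symbols <- rep(NA_character_, ncol(values))
  stopifnot(length(gene_symbols) == ncol(values))
  structure(list(name = name, values = values,
                 registry = data.frame(attribute_id = colnames(values),
                                       view = name,
                                       gene_symbol = gene_symbols,
                                       stringsAsFactors = FALSE)),
            class = "omics_view")
}

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf("Omics view '%s': %d samples x %d attributes (%.1f%% missing)\n",
              x$name, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @rdname omics_view
#' @param view an `"omics_view"`.
#' @export
missing_mask <- function(view) {
  stopifnot(inherits(view, "omics_view"))
  is.na(view$values)
}

#' Fuse two methylation platform views into one
#'
#' Builds the `methyl_fusion` view from a high-resolution (450K-style) and a
#' low-resolution (27K-style) methylation array: the attribute set is the
#' union of probe ids, and for a probe assayed on both platforms the
#' high-resolution value is used where observed, falling back to the
#' low-resolution value, else missing. Samples are aligned by id; the two
#' views must cover the same sample set.
#'
#' @param view450 the platform whose values take precedence for shared probes.
#' @param view27 the fallback platform.
#' @param name name of the fused view.
#' @return an `"omics_view"` of width `|probes450| + |probes27| - |shared|`,
#'   in `view450`'s sample order, probes of `view450` first.
#' @export
fuse_methylation <- function(view450, view27, name = "methyl_fusion") {
  stopifnot(inherits(view450, "omics_view"), inherits(view27, "omics_view"))
  s450 <- rownames(view450$values)
  s27 <- rownames(view27$values)
  only450 <- setdiff(s450, s27)
  only27 <- setdiff(s27, s450)
  if (length(only450) || length(only27)) {
    stop("sample sets differ between platforms; offenders: ",
         paste(c(only450, only27), collapse = ", "))
  }
  v27 <- view27$values[s450, , drop = FALSE]  # align to 450K sample order
  a450 <- colnames(view450$values)
  a27 <- colnames(v27)
  extra <- setdiff(a27, a450)
  out <- cbind(view450$values, v27[, extra, drop = FALSE])
  shared <- intersect(a450, a27)
  if (length(shared)) {
    blk <- out[, shared, drop = FALSE]
    fallback <- v27[, shared, drop = FALSE]
    nas <- is.na(blk)
    blk[nas] <- fallback[nas]
    out[, shared] <- blk
  }
  genes450 <- view450$registry$gene_symbol
  genes27 <- view27$registry$gene_symbol[match(extra, a27)]
  omics_view(name, out, gene_symbols = c(genes450, genes27))
}

#' Label-conditional mean imputation
#'
#' Fills each missing entry with the mean of the observed values of that
#' attribute among samples sharing the entry's class label: one mean is built
#' from the TNBC (positive) examples and another from the non-TNBC (negative)
#' examples, and missing values are filled according to their label. If a
#' class has no observed value for an attribute, the overall observed mean of
#' the attribute is used; an attribute with no observation at all is filled
#' with 0. Observed entries are never altered, so the operation is idempotent.
#'
#' @param view an [omics_view()].
#' @param labels binary labels (1 = TNBC) aligned to the view's samples.
#' @return the view with no missing entries.
#' @export
impute_label_conditional <- function(view, labels) {
  stopifnot(inherits(view, "omics_view"))
  labels <- check_binary_labels(labels, nrow(view$values))
  vals <- view$values
  if (!anyNA(vals)) return(view)
  overall <- colMeans(vals, na.rm = TRUE)
  overall[is.nan(overall)] <- 0
  for (cls in c(0L, 1L)) {
    rows <- which(labels == cls)
    if (!length(rows)) next
    sub <- vals[rows, , drop = FALSE]
    cm <- colMeans(sub, na.rm = TRUE)
    cm[is.nan(cm)] <- overall[is.nan(cm)]
    nas <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(nas)) {
      sub[nas] <- cm[nas[, 2L]]
      vals[rows, ] <- sub
    }
  }
  out <- view
  out$values <- vals
  out
}

#' Concatenate imputed views into one learning matrix
#'
#' Horizontal concatenation of fully imputed views sharing a sample set.
#' Global attribute ids are `"<view>::<attribute>"`, which keeps ids unique
#' across views; column order follows the input view order with attributes in
#' their original order within each view, and the attribute registry is
#' carried along so any column maps back to its view, attribute and gene.
#'
#' @param views list of [omics_view()] objects with identical sample sets and
#'   no missing values (see [impute_label_conditional()]).
#' @return an object of class `"feature_space"`: list with `values` (dense
#'   samples x attributes matrix) and `registry` (data frame `global_id`,
#'   `attribute_id`, `view`, `gene_symbol`).
#' @export
assemble_feature_space <- function(views) {
  stopifnot(length(views) >= 1L,
            all(vapply(views, inherits, logical(1), "omics_view")))
  ref <- rownames(views[[1L]]$values)
  parts <- vector("list", length(views))
  regs <- vector("list", length(views))
  for (i in seq_along(views)) {
    v <- views[[i]]
    if (!setequal(rownames(v$values), ref)) {
      stop("view '", v$name, "' does not share the sample set of view '",
           views[[1L]]$name, "'")
    }
    m <- v$values[ref, , drop = FALSE]
    if (anyNA(m)) {
      stop("view '", v$name, "' still has missing values; impute first")
    }
    colnames(m) <- paste0(v$name, "::", colnames(m))
    parts[[i]] <- m
    reg <- v$registry
    reg$global_id <- colnames(m)
    regs[[i]] <- reg[, c("global_id", "attribute_id", "view", "gene_symbol")]
  }
  values <- do.call(cbind, parts)
  if (anyDuplicated(colnames(values))) {
    stop("duplicate global attribute ids after prefixing; rename views")
  }
  structure(list(values = values, registry = do.call(rbind, regs)),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  tab <- table(x$registry$view)
  cat(sprintf("Feature space: %d samples x %d attributes (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read and write view matrices as delimited text
#'
#' The on-disk format is a tab-delimited table: header row of attribute ids,
#' first column `sample_id`, missing values encoded as `NA`.
#'
#' @param view an [omics_view()].
#' @param path file path.
#' @export
write_view_matrix <- function(view, path) {
  stopifnot(inherits(view, "omics_view"))
  df <- data.frame(sample_id = rownames(view$values), view$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_view_matrix
#' @param name view name for the restored object.
#' @param gene_symbols optional gene symbols, as in [omics_view()].
#' @export
read_view_matrix <- function(path, name, gene_symbols = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing sample_id column in ", path)
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  omics_view(name, m, gene_symbols = gene_symbols)
}

#' Write a feature space and its registry sidecar
#'
#' @param fs a [assemble_feature_space()] result.
#' @param matrix_path,registry_path output paths (tab-delimited text).
#' @export
write_feature_space <- function(fs, matrix_path, registry_path) {
  stopifnot(inherits(fs, "feature_space"))
  df <- data.frame(sample_id = rownames(fs$values), fs$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fs$registry, registry_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, registry_path))
}
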