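#' Candidate threshold rules ("rays") for a training matrix
#'
#' The Set Covering Machine chooses its rules from a data-dependent pool of
#' single-attribute threshold predicates. For every attribute, candidate
#' thresholds are placed at the midpoints between consecutive distinct sorted
#' training values, and both orientations (`value <= t` and `value > t`) are
#' emitted. A constant attribute yields no rules.
#'
#' This enumeration is the reference construction; [scm()] performs the same
#' search without materialising the pool.
#'
#' @param x numeric matrix (samples x attributes) with column names, or a
#'   feature space built by [assemble_feature_space()].
#' @param training integer indices of the rows to use (default: all rows).
#' @return data frame with columns `attribute_id`, `direction`
#'   (`"leq"`/`"gt"`) and `threshold`, ordered by attribute, threshold,
#'   direction.
#' @seealso [rule_utility()], [scm()]
#' @export
build_rays <- function(x, training = NULL) {
  x <- as_values_matrix(x)
  if (!is.null(training)) x <- x[training, , drop = FALSE]
  if (nrow(x) == 0L) stop("empty training set: no rays can be built")
  cols <- colnames(x)
  if (is.null(cols)) cols <- paste0("V", seq_len(ncol(x)))
  out <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2L) next
    thr <- v[-length(v)] + diff(v) / 2
    out[[j]] <- data.frame(
      attribute_id = cols[j],
      direction = rep(c("leq", "gt"), each = length(thr)),
      threshold = c(thr, thr),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(attribute_id = character(), direction = character(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$attribute_id, cols), res$threshold,
                   match(res$direction, c("leq", "gt"))), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Utility of a candidate rule against the current coverage state
#'
#' The greedy criterion of the Set Covering Machine. For a conjunction whose
#' positive class is TNBC, a candidate rule `h` earns credit for every
#' still-uncovered negative it classifies correctly (the rule is false on the
#' sample) and pays a penalty `p` for every still-active positive it
#' misclassifies: `U = |N_h| - p * |Pbar_h|`.
#'
#' @param rule one-row data frame (or list) with `attribute_id`, `direction`,
#'   `threshold`, as produced by [build_rays()].
#' @param x numeric matrix or feature space holding the training samples.
#' @param negatives integer indices of the remaining (uncovered) negatives.
#' @param positives integer indices of the active (not yet sacrificed)
#'   positives.
#' @param penalty non-negative penalty `p` on positive mistakes.
#' @return named list with `U`, `n_covered` (`|N_h|`) and `n_mistakes`
#'   (`|Pbar_h|`).
#' @export
rule_utility <- function(rule, x, negatives, positives, penalty) {
  x <- as_values_matrix(x)
  stopifnot(penalty >= 0)
  truth <- eval_rule(rule, x)
  n_covered <- sum(!truth[negatives])
  n_mistakes <- sum(!truth[positives])
  list(U = n_covered - penalty * n_mistakes,
       n_covered = n_covered, n_mistakes = n_mistakes)
}

# Evaluate a single threshold rule on a matrix; returns logical per row.
eval_rule <- function(rule, x) {
  j <- match(rule$attribute_id, colnames(x))
  if (is.na(j)) stop("unknown attribute id: ", rule$attribute_id)
  if (identical(rule$direction, "leq")) x[, j] <= rule$threshold
  else x[, j] > rule$threshold
}

#' Fit a Set Covering Machine
#'
#' Learns a conjunction (or disjunction) of single-attribute threshold rules
#' by greedy maximisation of the utility `U_h = |N_h| - p * |Pbar_h|`:
#' starting from all negatives uncovered and all positives active, the rule
#' with the highest utility is added, the negatives it covers are removed, the
#' positives it sacrifices are dropped, and the search repeats. Fitting stops
#' when every negative is covered, when `max_rules` rules have been selected,
#' or when no candidate has positive utility. Ties in utility are broken
#' towards larger `|N_h|`, then smaller attribute index, then smaller
#' threshold, then `leq` before `gt`, so the fit is deterministic.
#'
#' A disjunction is learned via De Morgan duality: the conjunction algorithm
#' runs on complemented labels and the resulting rules are orientation-flipped
#' on output.
#'
#' @param x numeric matrix (samples x attributes, column names required) or a
#'   feature space from [assemble_feature_space()].
#' @param y binary labels, 1 = TNBC (the positive, minority class).
#' @param penalty penalty `p` >= 0 on misclassified positives.
#' @param max_rules early-stopping point `s` >= 1: maximum number of rules.
#' @param model_type `"conjunction"` (default) or `"disjunction"`.
#' @return an object of class `"scm"`: a list with the fitted `rules` (data
#'   frame `attribute_id`, `direction`, `threshold`), `model_type`, `penalty`,
#'   `max_rules`, and a per-step `trace` (chosen rule, `U`, `|N_h|`,
#'   `|Pbar_h|`).
#' @examples
#' x <- cbind(a = c(1, 2, 3, 7, 8, 9))
#' fit <- scm(x, c(1, 1, 1, 0, 0, 0), penalty = 1, max_rules = 2)
#' coef(fit)
#' predict(fit, cbind(a = c(2.5, 7.5)))
#' @export
scm <- function(x, y, penalty = 1, max_rules = 10,
                model_type = c("conjunction", "disjunction")) {
  model_type <- match.arg(model_type)
  x <- as_values_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- check_binary_labels(y, nrow(x))
  stopifnot(penalty >= 0, max_rules >= 1)
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class; both classes are required")
  }
  scm_fit_core(x, y, penalty, max_rules, model_type, ord_matrix(x))
}

# Per-column sort permutation via one radix sort of the whole matrix.
ord_matrix <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  o <- order(rep.int(seq_len(p), rep.int(n, p)), as.vector(x))
  ord <- matrix(o - rep(seq.int(0L, by = n, length.out = p), each = n), n, p)
  storage.mode(ord) <- "integer"
  ord
}

# Greedy fit given a precomputed sort-order matrix (reused across the
# hyperparameter grid during cross-validation).
scm_fit_core <- function(x, y, penalty, max_rules, model_type, ord) {
  y_fit <- if (model_type == "disjunction") 1L - y else y

  neg_state <- y_fit == 0L
  pos_state <- y_fit == 1L
  rules <- list()
  trace <- list()
  repeat {
    if (!any(neg_state) || length(rules) >= max_rules) break
    best <- scm_best_rule_cpp(x, ord, neg_state, pos_state, penalty)
    if (best$attr == 0L || best$U <= 0) break
    dir <- if (best$direction == 0L) "leq" else "gt"
    rule <- data.frame(attribute_id = colnames(x)[best$attr],
                       direction = dir, threshold = best$threshold,
                       stringsAsFactors = FALSE)
    truth <- eval_rule(rule, x)
    rules[[length(rules) + 1L]] <- rule
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(rules), attribute_id = rule$attribute_id,
      direction = dir, threshold = best$threshold,
      U = best$U, n_covered = best$Nh, n_mistakes = best$Pbar,
      stringsAsFactors = FALSE
    )
    neg_state <- neg_state & truth   # covered negatives (rule false) drop out
    pos_state <- pos_state & truth   # sacrificed positives drop out
  }

  rules <- if (length(rules)) do.call(rbind, rules) else
    data.frame(attribute_id = character(), direction = character(),
               threshold = numeric(), stringsAsFactors = FALSE)
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), attribute_id = character(),
               direction = character(), threshold = numeric(), U = numeric(),
               n_covered = integer(), n_mistakes = integer(),
               stringsAsFactors = FALSE)

  if (model_type == "disjunction" && nrow(rules)) {
    # De Morgan: negate each rule of the complementary conjunction
    rules$direction <- ifelse(rules$direction == "leq", "gt", "leq")
  }

  structure(list(model_type = model_type, rules = rules, penalty = penalty,
                 max_rules = max_rules, trace = trace,
                 n_train = nrow(x)),
            class = "scm")
}

#' Predict TNBC status with a fitted Set Covering Machine
#'
#' A conjunction predicts positive (TNBC) iff every rule is true; an empty
#' conjunction is vacuously true everywhere. A disjunction predicts positive
#' iff any rule is true; an empty disjunction predicts negative everywhere.
#'
#' @param object an `"scm"` fit.
#' @param newdata numeric matrix or feature space; must contain every
#'   attribute referenced by the rules.
#' @param n_rules evaluate only the first `n_rules` rules (the greedy prefix);
#'   default all. Used by cross-validation over the early-stopping point.
#' @param ... unused.
#' @return integer vector of 0/1 predictions, 1 = TNBC.
#' @export
predict.scm <- function(object, newdata, n_rules = NULL, ...) {
  x <- as_values_matrix(newdata)
  rules <- object$rules
  if (!is.null(n_rules)) rules <- rules[seq_len(min(n_rules, nrow(rules))), ,
                                        drop = FALSE]
  missing_attr <- setdiff(rules$attribute_id, colnames(x))
  if (length(missing_attr)) {
    stop("attributes absent from newdata: ",
         paste(missing_attr, collapse = ", "))
  }
  if (nrow(rules) == 0L) {
    base <- if (object$model_type == "conjunction") 1L else 0L
    return(rep(base, nrow(x)))
  }
  hits <- vapply(seq_len(nrow(rules)),
                 function(i) eval_rule(rules[i, ], x), logical(nrow(x)))
  hits <- matrix(hits, nrow = nrow(x))
  if (object$model_type == "conjunction") {
    as.integer(rowSums(hits) == ncol(hits))
  } else {
    as.integer(rowSums(hits) > 0)
  }
}

#' @export
print.scm <- function(x, ...) {
  cat(sprintf("Set Covering Machine (%s of %d rule%s; p = %g, s = %d)\n",
              x$model_type, nrow(x$rules), if (nrow(x$rules) == 1) "" else "s",
              x$penalty, x$max_rules))
  if (nrow(x$rules)) {
    op <- ifelse(x$rules$direction == "leq", "<=", ">")
    cat(paste0("  ", format(seq_len(nrow(x$rules))), ": ",
               x$rules$attribute_id, " ", op, " ",
               signif(x$rules$threshold, 6), collapse = "\n"), "\n")
  } else {
    cat("  <no rules: vacuous model>\n")
  }
  invisible(x)
}

#' @export
summary.scm <- function(object, ...) {
  structure(list(model = object), class = "summary.scm")
}

#' @export
print.summary.scm <- function(x, ...) {
  print(x$model)
  cat("\nGreedy selection trace:\n")
  print(x$model$trace, row.names = FALSE)
  invisible(x)
}

#' @export
coef.scm <- function(object, ...) object$rules

#' Serialize / restore a Set Covering Machine
#'
#' `write_scm()` writes a human-readable rule listing (one rule per line:
#' attribute, direction, threshold at full precision) and a machine-readable
#' JSON sidecar at `<path>.json`. `read_scm()` restores the model from the
#' sidecar; the round trip is exact.
#'
#' @param model an `"scm"` fit.
#' @param path output path for the text listing.
#' @return `write_scm()` returns `path` invisibly; `read_scm()` returns the
#'   restored `"scm"` object.
#' @export
write_scm <- function(model, path) {
  stopifnot(inherits(model, "scm"))
  op <- ifelse(model$rules$direction == "leq", "<=", ">")
  lines <- c(
    sprintf("# set covering machine: %s", model$model_type),
    sprintf("# penalty p = %s, early stopping s = %d",
            format(model$penalty), model$max_rules),
    if (nrow(model$rules)) {
      sprintf("%s\t%s\t%s", model$rules$attribute_id, op,
              sprintf("%.17g", model$rules$threshold))
    } else "# <no rules>"
  )
  writeLines(lines, path)
  # thresholds are serialized as %.17g strings so doubles round-trip exactly
  rules_s <- model$rules
  rules_s$threshold <- sprintf("%.17g", rules_s$threshold)
  trace_s <- model$trace
  trace_s$threshold <- sprintf("%.17g", trace_s$threshold)
  side <- list(model_type = model$model_type, penalty = model$penalty,
               max_rules = model$max_rules,
               rules = rules_s, trace = trace_s,
               n_train = model$n_train)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_scm
#' @export
read_scm <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rules <- as.data.frame(side$rules, stringsAsFactors = FALSE)
  if (nrow(rules) == 0L) {
    rules <- data.frame(attribute_id = character(), direction = character(),
                        threshold = numeric(), stringsAsFactors = FALSE)
  } else {
    rules$threshold <- as.numeric(rules$threshold)
  }
  trace <- as.data.frame(side$trace, stringsAsFactors = FALSE)
  if (nrow(trace)) trace$threshold <- as.numeric(trace$threshold)
  structure(list(model_type = side$model_type, rules = rules,
                 penalty = side$penalty, max_rules = side$max_rules,
                 trace = trace, n_train = side$n_train),
            class = "scm")
}

#' Choose SCM hyperparameters by stratified cross-validation
#'
#' Grid search over the penalty `p` and early-stopping point `s`, scored by
#' micro-averaged validation F1 (or accuracy): confusion counts are pooled
#' over stratified folds of the training data before the score is computed,
#' which is far more stable than per-fold F1 when positives are scarce.
#' For each fold and each `p` the conjunction is fitted once at the
#' largest `s`; smaller stopping points are scored on the greedy prefix, which
#' is identical to refitting with that `s`. Ties prefer the sparser model
#' (smaller `s`), then the smaller penalty.
#'
#' @param x training matrix or feature space.
#' @param y binary labels (1 = TNBC).
#' @param p_grid penalties to try.
#' @param s_grid early-stopping points to try.
#' @param folds number of stratified folds (reduced if a class is smaller).
#' @param metric `"f1"` or `"accuracy"`.
#' @param seed integer seed for the fold assignment.
#' @param model_type passed to [scm()].
#' @return list with `penalty`, `max_rules`, and the full `cv_table` of mean
#'   scores.
#' @export
scm_tune <- function(x, y, p_grid = c(0.1, 0.316, 1, 3.16, 10),
                     s_grid = 1:5, folds = 5, metric = c("f1", "accuracy"),
                     seed = 1, model_type = "conjunction") {
  metric <- match.arg(metric)
  x <- as_values_matrix(x)
  y <- check_binary_labels(y, nrow(x))
  folds <- max(2L, min(folds, min(table(y))))
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  s_max <- max(s_grid)
  # validation confusion counts are pooled over folds before computing the
  # score (micro-averaging): with few positives per fold, per-fold F1 is too
  # noisy to rank hyperparameters reliably
  counts <- array(0, dim = c(length(p_grid), length(s_grid), 4),
                  dimnames = list(NULL, NULL, c("tp", "tn", "fp", "fn")))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    va <- !tr
    if (length(unique(y[tr])) < 2L) next
    x_tr <- x[tr, , drop = FALSE]
    ord_tr <- ord_matrix(x_tr)
    for (pi in seq_along(p_grid)) {
      fit <- scm_fit_core(x_tr, y[tr], penalty = p_grid[pi],
                          max_rules = s_max, model_type = model_type,
                          ord = ord_tr)
      for (si in seq_along(s_grid)) {
        pred <- predict(fit, x[va, , drop = FALSE], n_rules = s_grid[si])
        counts[pi, si, ] <- counts[pi, si, ] + confusion_counts(y[va], pred)
      }
    }
  }
  cv_table <- expand.grid(penalty = p_grid, max_rules = s_grid,
                          KEEP.OUT.ATTRS = FALSE)
  cv_table$score <- mapply(function(pi, si) {
    compute_metrics(counts[pi, si, ])[[metric]]
  }, rep(seq_along(p_grid), length(s_grid)),
     rep(seq_along(s_grid), each = length(p_grid)))
  best <- cv_table[order(-cv_table$score, cv_table$max_rules,
                         cv_table$penalty), ][1, ]
  list(penalty = best$penalty, max_rules = best$max_rules,
       cv_table = cv_table, metric = metric)
}

# Accept a plain matrix, a data.frame, or a feature_space/omics_view and
# return the numeric values matrix.
as_values_matrix <- function(x) {
  if (inherits(x, "feature_space") || inherits(x, "omics_view")) {
    return(x$values)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix, data frame, omics view or feature space")
  }
  x
}
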