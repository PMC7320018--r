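#' Stratified train/test split
#'
#' Splits samples into a training and a held-out test set, stratified by the
#' TNBC label so the class imbalance is preserved: each class contributes
#' `floor(fraction * n_class)` samples to the training set, and the leftover
#' slots needed to reach a global training size of `round(fraction * n)` are
#' assigned to classes in decreasing order of the fractional remainder of
#' `fraction * n_class` (ties to the larger class, then label 0 first). Which
#' samples fill the per-class quotas is drawn from the seeded RNG.
#'
#' @param labels binary labels (1 = TNBC).
#' @param train_fraction fraction of samples assigned to training (default
#'   0.8, the 80/20 protocol).
#' @param seed integer seed making the split deterministic.
#' @return list with integer index vectors `train` and `test`; disjoint and
#'   exhaustive.
#' @export
split_train_test <- function(labels, train_fraction = 0.8, seed = 1) {
  labels <- check_binary_labels(labels)
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(labels)
  cls_sizes <- c(`0` = sum(labels == 0L), `1` = sum(labels == 1L))
  if (any(cls_sizes < 2L)) {
    stop("each class needs at least 2 samples to split")
  }
  raw <- train_fraction * cls_sizes
  quota <- floor(raw)
  target <- round(train_fraction * n)
  left <- target - sum(quota)
  if (left > 0) {
    rem <- raw - quota
    take <- order(-rem, -cls_sizes, as.integer(names(cls_sizes)))[seq_len(left)]
    quota[take] <- quota[take] + 1
  } else if (left < 0) {
    rem <- raw - quota
    give <- order(rem, cls_sizes)[seq_len(-left)]
    quota[give] <- quota[give] - 1
  }
  train <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cls) {
      idx <- which(labels == cls)
      idx[sample.int(length(idx), quota[[as.character(cls)]])]
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Configuration for the repeated-split learning experiment
#'
#' The protocol: `n_repeats` independent stratified 80/20 splits; on each
#' training set the selected algorithms are tuned and fitted and then scored
#' on both splits; the `k_best` models per algorithm by held-out
#' `selection_metric` feed the feature count table.
#'
#' @param n_repeats number of repeated splits (the study design uses 100).
#' @param train_fraction training fraction per split.
#' @param algorithms subset of `"scm"`, `"dt"`, `"rf"`.
#' @param selection_metric `"f1"` (default, the headline metric on this
#'   unbalanced problem) or `"accuracy"`.
#' @param k_best number of best models retained per algorithm (default 10).
#' @param master_seed master seed; split, tuning and learner seeds are derived
#'   substreams.
#' @param scm_p_grid,scm_s_grid,cv_folds SCM hyperparameter grid and the
#'   number of stratified cross-validation folds used on each training set.
#' @param rf_ntree number of trees per random forest.
#' @return a list of class `"repeat_config"`.
#' @export
repeat_config <- function(n_repeats = 100, train_fraction = 0.8,
                          algorithms = c("scm", "dt", "rf"),
                          selection_metric = c("f1", "accuracy"),
                          k_best = 10, master_seed = 1,
                          scm_p_grid = c(0.1, 0.316, 1, 3.16, 10),
                          scm_s_grid = 1:5, cv_folds = 5, rf_ntree = 100) {
  selection_metric <- match.arg(selection_metric)
  algorithms <- match.arg(algorithms, c("scm", "dt", "rf"),
                          several.ok = TRUE)
  stopifnot(n_repeats >= 1, k_best >= 1, k_best <= n_repeats,
            train_fraction > 0, train_fraction < 1)
  structure(list(n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction, algorithms = algorithms,
                 selection_metric = selection_metric,
                 k_best = as.integer(k_best),
                 master_seed = as.integer(master_seed),
                 scm_p_grid = scm_p_grid, scm_s_grid = scm_s_grid,
                 cv_folds = as.integer(cv_folds),
                 rf_ntree = as.integer(rf_ntree)),
            class = "repeat_config")
}

fit_one_learner <- function(algorithm, x_train, y_train, config, seed) {
  switch(algorithm,
    scm = {
      tuned <- scm_tune(x_train, y_train, p_grid = config$scm_p_grid,
                        s_grid = config$scm_s_grid, folds = config$cv_folds,
                        metric = config$selection_metric, seed = seed)
      fit <- scm(x_train, y_train, penalty = tuned$penalty,
                 max_rules = tuned$max_rules)
      list(model = fit,
           hyperparameters = list(penalty = tuned$penalty,
                                  max_rules = tuned$max_rules),
           predict = function(newx) predict(fit, newx))
    },
    dt = {
      # rpart needs syntactic column names; map and keep the inverse
      df <- as.data.frame(x_train)
      id_map <- colnames(x_train)
      names(df) <- paste0("V", seq_along(id_map))
      df$.y <- factor(y_train, levels = c(0, 1))
      fit <- with_seed(seed, rpart::rpart(
        .y ~ ., data = df, method = "class",
        control = rpart::rpart.control(xval = 0)))
      list(model = fit,
           hyperparameters = list(method = "class", xval = 0),
           id_map = id_map,
           predict = function(newx) {
             nd <- as.data.frame(newx)
             names(nd) <- paste0("V", seq_along(id_map))
             as.integer(as.character(predict(fit, nd, type = "class")))
           })
    },
    rf = {
      fit <- with_seed(seed, randomForest::randomForest(
        x = x_train, y = factor(y_train, levels = c(0, 1)),
        ntree = config$rf_ntree))
      list(model = fit, hyperparameters = list(ntree = config$rf_ntree),
           predict = function(newx) {
             as.integer(as.character(predict(fit, newx)))
           })
    },
    stop("unknown algorithm: ", algorithm)
  )
}

#' Run the repeated stratified train/test experiment
#'
#' For each repeat, the cohort is split with a seed derived from the master
#' seed and the repeat index, each requested algorithm is tuned and fitted on
#' the training split only, and performance is measured on both splits. The
#' whole experiment is a pure function of the data and the configuration.
#'
#' @param fs a [assemble_feature_space()] result, or a plain numeric matrix
#'   with column names.
#' @param labels binary labels (1 = TNBC) aligned to the rows.
#' @param config a [repeat_config()].
#' @return object of class `"tnbc_experiment"`: list of per-(repeat,
#'   algorithm) results, each with `repeat_index`, `algorithm`, `model`,
#'   `hyperparameters`, `train_metrics`, `test_metrics` and `model_features`
#'   (see [extract_model_features()]), plus the `config`.
#' @export
run_experiment <- function(fs, labels, config = repeat_config()) {
  stopifnot(inherits(config, "repeat_config"))
  x <- as_values_matrix(fs)
  labels <- check_binary_labels(labels, nrow(x))
  results <- vector("list", config$n_repeats * length(config$algorithms))
  k <- 0L
  for (r in seq_len(config$n_repeats)) {
    split <- split_train_test(labels, config$train_fraction,
                              seed = derive_seed(config$master_seed,
                                                 paste0("split:", r)))
    x_tr <- x[split$train, , drop = FALSE]
    y_tr <- labels[split$train]
    x_te <- x[split$test, , drop = FALSE]
    y_te <- labels[split$test]
    for (alg in config$algorithms) {
      seed_alg <- derive_seed(config$master_seed, paste0(alg, ":", r))
      fitted <- tryCatch(
        fit_one_learner(alg, x_tr, y_tr, config, seed_alg),
        error = function(e) {
          stop(sprintf("repeat %d, algorithm %s: %s", r, alg,
                       conditionMessage(e)), call. = FALSE)
        })
      res <- list(
        repeat_index = r, algorithm = alg, model = fitted$model,
        hyperparameters = fitted$hyperparameters,
        train_metrics = compute_metrics(
          confusion_counts(y_tr, fitted$predict(x_tr))),
        test_metrics = compute_metrics(
          confusion_counts(y_te, fitted$predict(x_te)))
      )
      if (!is.null(fitted$id_map)) res$id_map <- fitted$id_map
      res$model_features <- extract_model_features(res)
      k <- k + 1L
      results[[k]] <- res
    }
  }
  structure(list(results = results, config = config),
            class = "tnbc_experiment")
}

#' @export
print.tnbc_experiment <- function(x, ...) {
  mt <- metrics_table(x)
  cat(sprintf("Repeated-split experiment: %d repeats x {%s}\n",
              x$config$n_repeats, paste(x$config$algorithms, collapse = ", ")))
  agg <- stats::aggregate(cbind(test_f1, test_accuracy) ~ algorithm, mt, mean)
  cat("  mean held-out performance:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Per-repeat metrics as a data frame
#'
#' @param experiment a [run_experiment()] result.
#' @return data frame with one row per (repeat, algorithm): hyperparameters
#'   and train/test accuracy, precision, recall and F1.
#' @export
metrics_table <- function(experiment) {
  stopifnot(inherits(experiment, "tnbc_experiment"))
  do.call(rbind, lapply(experiment$results, function(r) {
    data.frame(repeat_index = r$repeat_index, algorithm = r$algorithm,
               train_accuracy = r$train_metrics[["accuracy"]],
               train_f1 = r$train_metrics[["f1"]],
               test_accuracy = r$test_metrics[["accuracy"]],
               test_precision = r$test_metrics[["precision"]],
               test_recall = r$test_metrics[["recall"]],
               test_f1 = r$test_metrics[["f1"]],
               n_features = length(r$model_features),
               stringsAsFactors = FALSE)
  }))
}

#' Select the best models per algorithm
#'
#' Ranks each algorithm's repeats by the held-out selection metric (ties by
#' held-out accuracy, then by lower repeat index) and keeps the top `k_best`.
#'
#' @param experiment a [run_experiment()] result (or its `results` list).
#' @param k_best models kept per algorithm.
#' @param selection_metric `"f1"` or `"accuracy"`.
#' @return list of selected result objects.
#' @export
select_best_models <- function(experiment, k_best = 10,
                               selection_metric = c("f1", "accuracy")) {
  selection_metric <- match.arg(selection_metric)
  results <- if (inherits(experiment, "tnbc_experiment")) {
    experiment$results
  } else experiment
  algs <- unique(vapply(results, `[[`, character(1), "algorithm"))
  selected <- list()
  for (alg in algs) {
    sub <- Filter(function(r) r$algorithm == alg, results)
    if (length(sub) < k_best) {
      stop(sprintf("algorithm %s has %d results; %d requested", alg,
                   length(sub), k_best))
    }
    score <- vapply(sub, function(r) r$test_metrics[[selection_metric]],
                    numeric(1))
    acc <- vapply(sub, function(r) r$test_metrics[["accuracy"]], numeric(1))
    idx <- vapply(sub, `[[`, numeric(1), "repeat_index")
    sel <- order(-score, -acc, idx)[seq_len(k_best)]
    selected <- c(selected, sub[sel])
  }
  selected
}

# Breadth-first walk of an rpart frame: node numbers (row names) follow the
# usual binary heap numbering, so increasing node number is level order.
rpart_features_bfs <- function(fit, id_map, k = 3) {
  frame <- fit$frame
  ord <- order(as.integer(rownames(frame)))
  vars <- as.character(frame$var[ord])
  vars <- vars[vars != "<leaf>"]
  vars <- unique(vars)[seq_len(min(k, length(unique(vars))))]
  id_map[as.integer(sub("^V", "", vars))]
}

# Breadth-first walk of one randomForest tree (getTree output): traverse from
# the root with a FIFO queue of daughter row indices.
rf_tree_features_bfs <- function(tree, k = 3) {
  vars <- character(0)
  queue <- 1L
  while (length(queue) && length(vars) < k) {
    node <- queue[1L]
    queue <- queue[-1L]
    if (tree[node, "status"] == -1) next  # terminal
    v <- as.character(tree[node, "split var"])
    if (!v %in% vars) vars <- c(vars, v)
    queue <- c(queue, tree[node, "left daughter"],
               tree[node, "right daughter"])
  }
  vars
}

#' Attributes a fitted model depends on
#'
#' The features counted towards the stability analysis. For the SCM the
#' answer is direct: every attribute appearing in the conjunction, in greedy
#' selection order. Trees are summarised by their root-proximal splits: a
#' decision tree contributes its first three distinct split attributes in
#' breadth-first order from the root, and a random forest contributes the
#' union over its trees of each tree's first three distinct split attributes.
#'
#' @param result one element of [run_experiment()]'s results.
#' @param k number of root-proximal features per tree (default 3).
#' @return character vector of attribute ids.
#' @export
extract_model_features <- function(result, k = 3) {
  model <- result$model
  if (is.null(model)) stop("unfitted model")
  if (inherits(model, "scm")) {
    unique(model$rules$attribute_id)
  } else if (inherits(model, "rpart")) {
    rpart_features_bfs(model, result$id_map, k = k)
  } else if (inherits(model, "randomForest")) {
    feats <- character(0)
    for (t in seq_len(model$ntree)) {
      tr <- randomForest::getTree(model, t, labelVar = TRUE)
      feats <- union(feats, rf_tree_features_bfs(tr, k = k))
    }
    feats
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
}

#' Direction of regulation of an attribute in TNBC
#'
#' Compares the attribute's class means: higher mean in TNBC than in non-TNBC
#' is `up_in_tnbc`, lower is `down_in_tnbc`, equal is `unchanged`.
#'
#' @param attribute a global attribute id (a column of the feature space).
#' @param fs feature space or matrix.
#' @param labels binary labels (1 = TNBC).
#' @return list with `direction`, `mean_tnbc`, `mean_non_tnbc`.
#' @export
direction_of_regulation <- function(attribute, fs, labels) {
  x <- as_values_matrix(fs)
  labels <- check_binary_labels(labels, nrow(x))
  if (!attribute %in% colnames(x)) stop("unknown attribute: ", attribute)
  if (length(unique(labels)) < 2L) {
    stop("both classes are required to call a direction")
  }
  v <- x[, attribute]
  m1 <- mean(v[labels == 1L])
  m0 <- mean(v[labels == 0L])
  dir <- if (m1 > m0) "up_in_tnbc" else if (m1 < m0) "down_in_tnbc" else
    "unchanged"
  list(direction = dir, mean_tnbc = m1, mean_non_tnbc = m0)
}

#' Count features over the selected best models
#'
#' Each selected model contributes each of its distinct features once; counts
#' are aggregated per attribute. With a registry and the data, each attribute
#' row is annotated with its view, gene symbol, direction of regulation and
#' class means.
#'
#' @param selected list of results from [select_best_models()].
#' @param registry attribute registry of the feature space (optional).
#' @param fs,labels feature space and labels for direction calls (optional).
#' @return data frame of class `"feature_count_table"` with columns
#'   `attribute_id`, `gene_symbol`, `view`, `count`, `direction`,
#'   `mean_tnbc`, `mean_non_tnbc`, sorted by decreasing count then gene
#'   symbol.
#' @export
count_features <- function(selected, registry = NULL, fs = NULL,
                           labels = NULL) {
  stopifnot(length(selected) >= 1L)
  feats <- unlist(lapply(selected, function(r) unique(r$model_features)))
  tab <- table(feats)
  out <- data.frame(attribute_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (!is.null(registry)) {
    m <- match(out$attribute_id, registry$global_id)
    if (all(is.na(m))) m <- match(out$attribute_id, registry$attribute_id)
    out$gene_symbol <- registry$gene_symbol[m]
    out$view <- registry$view[m]
  } else {
    out$gene_symbol <- NA_character_
    out$view <- NA_character_
  }
  # an attribute without a gene annotation stands for itself
  out$gene_symbol <- ifelse(is.na(out$gene_symbol), out$attribute_id,
                            out$gene_symbol)
  if (!is.null(fs) && !is.null(labels)) {
    dirs <- lapply(out$attribute_id, direction_of_regulation, fs = fs,
                   labels = labels)
    out$direction <- vapply(dirs, `[[`, character(1), "direction")
    out$mean_tnbc <- vapply(dirs, `[[`, numeric(1), "mean_tnbc")
    out$mean_non_tnbc <- vapply(dirs, `[[`, numeric(1), "mean_non_tnbc")
  } else {
    out$direction <- NA_character_
    out$mean_tnbc <- NA_real_
    out$mean_non_tnbc <- NA_real_
  }
  out <- out[order(-out$count, out$gene_symbol),
             c("attribute_id", "gene_symbol", "view", "count", "direction",
               "mean_tnbc", "mean_non_tnbc")]
  rownames(out) <- NULL
  class(out) <- c("feature_count_table", "data.frame")
  out
}

#' Roll attribute counts up to genes
#'
#' A gene is as supported as its best isoform: the gene-level count is the
#' maximum count over the gene's attributes, and the direction and class
#' means are taken from that top attribute.
#'
#' @param counts a [count_features()] table.
#' @return data frame with one row per gene (`gene_symbol`, `view`, `count`,
#'   `direction`, `mean_tnbc`, `mean_non_tnbc`, `top_attribute`), sorted by
#'   decreasing count then gene symbol.
#' @export
gene_count_table <- function(counts) {
  stopifnot(inherits(counts, "feature_count_table"))
  split_idx <- split(seq_len(nrow(counts)), counts$gene_symbol)
  rows <- vapply(split_idx, function(ix) ix[which.max(counts$count[ix])],
                 integer(1))
  out <- data.frame(gene_symbol = names(split_idx),
                    view = counts$view[rows],
                    count = counts$count[rows],
                    direction = counts$direction[rows],
                    mean_tnbc = counts$mean_tnbc[rows],
                    mean_non_tnbc = counts$mean_non_tnbc[rows],
                    top_attribute = counts$attribute_id[rows],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene_symbol), ]
  rownames(out) <- NULL
  out
}

#' End-to-end feature stability analysis
#'
#' Convenience wrapper over the full protocol: run the repeated experiment,
#' keep the `k_best` models per algorithm, count features over them (pooled
#' across algorithms and, separately, per algorithm), and roll counts up to
#' genes with direction calls.
#'
#' @param fs feature space (with registry) from [assemble_feature_space()].
#' @param labels binary labels (1 = TNBC).
#' @param config a [repeat_config()].
#' @return list with `experiment`, `selected`, `counts` (pooled attribute
#'   table), `gene_counts` (pooled gene table) and `per_algorithm` (named list
#'   of gene tables).
#' @export
feature_stability <- function(fs, labels, config = repeat_config()) {
  exp <- run_experiment(fs, labels, config)
  selected <- select_best_models(exp, k_best = config$k_best,
                                 selection_metric = config$selection_metric)
  registry <- if (inherits(fs, "feature_space")) fs$registry else NULL
  counts <- count_features(selected, registry, fs, labels)
  per_alg <- lapply(stats::setNames(config$algorithms, config$algorithms),
                    function(alg) {
    sub <- Filter(function(r) r$algorithm == alg, selected)
    gene_count_table(count_features(sub, registry, fs, labels))
  })
  list(experiment = exp, selected = selected, counts = counts,
       gene_counts = gene_count_table(counts), per_algorithm = per_alg)
}

#' Write a feature count table as delimited text
#'
#' @param counts a [count_features()] or [gene_count_table()] data frame.
#' @param path output path (tab-delimited).
#' @export
write_count_table <- function(counts, path) {
  df <- as.data.frame(counts)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
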