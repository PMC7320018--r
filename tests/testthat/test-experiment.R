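test_that("stratified splitting honours per-class quotas and remainders", {
  # 2 positives + 8 negatives at 0.8: positives have the larger remainder
  labs <- rep(c(1, 0), c(2, 8))
  sp <- split_train_test(labs, 0.8, seed = 4)
  expect_equal(length(sp$train), 8)
  expect_equal(sum(labs[sp$train]), 2)
  expect_equal(sum(labs[sp$test]), 0)
  # 4 + 4 at 0.5
  sp2 <- split_train_test(rep(c(1, 0), 4), 0.5, seed = 1)
  expect_equal(sum(rep(c(1, 0), 4)[sp2$train]), 2)
  expect_equal(length(sp2$train), 4)
  expect_error(split_train_test(c(1, 0, 0, 0), 0.5), "at least 2")
})

test_that("splits are disjoint, exhaustive and deterministic", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    labs <- rbinom(n, 1, runif(1, 0.15, 0.5))
    if (min(table(factor(labs, levels = 0:1))) < 2) next
    frac <- sample(c(0.5, 0.7, 0.8), 1)
    sp <- split_train_test(labs, frac, seed = i)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_len(n))
    expect_equal(length(sp$train), round(frac * n))
    sp_again <- split_train_test(labs, frac, seed = i)
    expect_identical(sp, sp_again)
  }
})

test_that("the repeated experiment yields one result per repeat and algorithm", {
  coh <- small_cohort(n = 60, width = 40, delta = 3, seed = 17)
  fs <- assemble_feature_space(list(coh$views$isoform))
  cfg <- repeat_config(n_repeats = 5, algorithms = "scm", k_best = 2,
                       master_seed = 8, cv_folds = 3)
  res <- run_experiment(fs, coh$clinical$label, cfg)
  expect_length(res$results, 5)
  expect_true(all(vapply(res$results, `[[`, character(1), "algorithm") == "scm"))
  # determinism: same master seed, same held-out F1 vector
  res2 <- run_experiment(fs, coh$clinical$label, cfg)
  expect_identical(metrics_table(res)$test_f1, metrics_table(res2)$test_f1)
})

test_that("best-model selection ranks by held-out metric with documented tie-breaks", {
  fake <- function(i, f1, acc = 0.5, alg = "scm") {
    list(repeat_index = i, algorithm = alg,
         model = structure(list(), class = "scm"),
         test_metrics = c(accuracy = acc, precision = 0, recall = 0, f1 = f1),
         model_features = "a")
  }
  results <- c(lapply(1:6, function(i) fake(i, f1 = i / 10)),
               lapply(1:6, function(i) fake(i, f1 = 0.5, alg = "dt")))
  sel <- select_best_models(results, k_best = 3, selection_metric = "f1")
  scm_sel <- Filter(function(r) r$algorithm == "scm", sel)
  expect_equal(sort(vapply(scm_sel, `[[`, numeric(1), "repeat_index")),
               c(4, 5, 6))
  # all-equal scores: the lowest repeat indices win
  dt_sel <- Filter(function(r) r$algorithm == "dt", sel)
  expect_equal(sort(vapply(dt_sel, `[[`, numeric(1), "repeat_index")),
               c(1, 2, 3))
  # k = |results| is the identity selection
  all_sel <- select_best_models(lapply(1:4, function(i) fake(i, i / 10)),
                                k_best = 4)
  expect_length(all_sel, 4)
  expect_error(select_best_models(results, k_best = 7), "requested")
})

test_that("model features come from rules, root-proximal tree splits and forest unions", {
  # SCM: attributes in selection order
  fit <- structure(list(model_type = "conjunction",
                        rules = data.frame(attribute_id = c("b", "a", "b"),
                                           direction = "leq", threshold = 1),
                        penalty = 1, max_rules = 3), class = "scm")
  expect_equal(extract_model_features(list(model = fit)), c("b", "a"))

  # decision tree: first three distinct attributes breadth-first from the root
  coh <- small_cohort(n = 200, width = 30, delta = 3, n_down = 2, n_up = 1,
                      seed = 19)
  fs <- assemble_feature_space(list(coh$views$isoform))
  df <- as.data.frame(fs$values)
  id_map <- colnames(fs$values)
  names(df) <- paste0("V", seq_along(id_map))
  df$.y <- factor(coh$clinical$label)
  tree <- rpart::rpart(.y ~ ., df, method = "class",
                       control = rpart::rpart.control(xval = 0, cp = 0,
                                                      minsplit = 4))
  feats <- extract_model_features(list(model = tree, id_map = id_map))
  expect_lte(length(feats), 3)
  root_var <- as.character(tree$frame$var[1])
  expect_equal(feats[1], id_map[as.integer(sub("V", "", root_var))])
  used <- id_map[as.integer(sub("V", "",
    setdiff(unique(as.character(tree$frame$var)), "<leaf>")))]
  expect_true(all(feats %in% used))

  # random forest: union over trees of each tree's first three splits
  rf <- randomForest::randomForest(x = fs$values,
                                   y = factor(coh$clinical$label), ntree = 15)
  rf_feats <- extract_model_features(list(model = rf))
  expect_true(all(rf_feats %in% colnames(fs$values)))
  expect_lte(length(rf_feats), 3 * 15)
  one_tree <- tnbcscm:::rf_tree_features_bfs(
    randomForest::getTree(rf, 1, labelVar = TRUE))
  expect_lte(length(one_tree), 3)
  expect_true(all(one_tree %in% rf_feats))
})

test_that("feature counting is once per model with gene-level max roll-up", {
  mk <- function(i, feats) list(repeat_index = i, algorithm = "scm",
                                model_features = feats)
  registry <- data.frame(
    global_id = c("v::a1", "v::a2", "v::b1"),
    attribute_id = c("a1", "a2", "b1"),
    view = "v", gene_symbol = c("gA", "gA", "gB"),
    stringsAsFactors = FALSE)
  selected <- list(mk(1, c("v::a1", "v::a1", "v::b1")),  # duplicate counts once
                   mk(2, c("v::a1", "v::a2")),
                   mk(3, "v::a2"))
  counts <- count_features(selected, registry)
  expect_equal(counts$count[counts$attribute_id == "v::a1"], 2L)
  expect_equal(counts$count[counts$attribute_id == "v::a2"], 2L)
  expect_equal(counts$count[counts$attribute_id == "v::b1"], 1L)
  genes <- gene_count_table(counts)
  expect_equal(genes$count[genes$gene_symbol == "gA"], 2L)  # max, not sum
  expect_equal(genes$count[genes$gene_symbol == "gB"], 1L)
  # sorted by count descending, then gene symbol
  expect_equal(genes$gene_symbol, c("gA", "gB"))
})

test_that("direction of regulation compares class means", {
  x <- cbind(g = c(2, 2, 5, 5, 5, 5))
  lab <- c(1, 1, 0, 0, 0, 0)
  d <- direction_of_regulation("g", x, lab)
  expect_equal(d$direction, "down_in_tnbc")
  expect_equal(d$mean_tnbc, 2)
  expect_equal(d$mean_non_tnbc, 5)
  x2 <- cbind(g = c(3, 3, 3, 3))
  expect_equal(direction_of_regulation("g", x2, c(1, 1, 0, 0))$direction,
               "unchanged")
  expect_error(direction_of_regulation("g", x2, c(1, 1, 1, 1)), "both classes")
})

test_that("planted directions are recalled from the data at moderate effect size", {
  hits <- 0L
  total <- 0L
  for (seed in 1:20) {
    coh <- small_cohort(n = 400, width = 40, delta = 2, n_down = 3, n_up = 3,
                        seed = 100 + seed)
    fs <- assemble_feature_space(list(coh$views$isoform))
    for (i in seq_len(nrow(coh$planted))) {
      gid <- paste0("isoform::", coh$planted$attribute_id[i])
      d <- direction_of_regulation(gid, fs, coh$clinical$label)
      total <- total + 1L
      if (d$direction == coh$planted$direction[i]) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("held-out F1 is high on a planted separable cohort", {
  coh <- small_cohort(n = 300, width = 500, delta = 2.5, n_down = 6, n_up = 4,
                      seed = 23)
  fs <- assemble_feature_space(list(coh$views$isoform))
  cfg <- repeat_config(n_repeats = 20, algorithms = "scm", k_best = 10,
                       master_seed = 31)
  res <- run_experiment(fs, coh$clinical$label, cfg)
  # frozen from a pilot over five master seeds (20-repeat means 0.87-0.93)
  expect_gte(mean(metrics_table(res)$test_f1), 0.85)
})

test_that("fitting never sees held-out labels", {
  coh <- small_cohort(n = 100, width = 60, delta = 2.5, seed = 29)
  fs <- assemble_feature_space(list(coh$views$isoform))
  y <- coh$clinical$label
  sp <- split_train_test(y, 0.8, seed = 3)
  y_mut <- y
  y_mut[sp$test] <- 1L - y_mut[sp$test]
  cfg <- repeat_config(n_repeats = 1, k_best = 1, master_seed = 7,
                       cv_folds = 3)
  for (alg in c("scm", "dt", "rf")) {
    f1 <- tnbcscm:::fit_one_learner(alg, fs$values[sp$train, ], y[sp$train],
                                    cfg, seed = 41)
    f2 <- tnbcscm:::fit_one_learner(alg, fs$values[sp$train, ],
                                    y_mut[sp$train], cfg, seed = 41)
    expect_identical(f1$predict(fs$values), f2$predict(fs$values))
  }
})
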