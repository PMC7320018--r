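test_that("candidate rays are midpoints between distinct sorted values, both directions", {
  rays <- build_rays(cbind(a = c(1, 3, 5)))
  expect_equal(nrow(rays), 4)
  expect_setequal(rays$threshold, c(2, 2, 4, 4))
  expect_setequal(unique(rays$direction), c("leq", "gt"))
  # constant attribute yields no rules
  expect_equal(nrow(build_rays(cbind(a = c(7, 7, 7)))), 0)
  # 2 attributes with 4 distinct values each: 2 * 2 * (4 - 1) = 12 rules
  x <- cbind(a = c(1, 2, 3, 4), b = c(10, 20, 30, 40))
  expect_equal(nrow(build_rays(x)), 12)
  expect_error(build_rays(cbind(a = numeric(0))), "empty")
})

test_that("rule utility is covered negatives minus penalised positive mistakes", {
  x <- cbind(a = c(1, 2, 3, 7, 8, 9))
  # positives rows 1:3, negatives 4:6
  r_all <- list(attribute_id = "a", direction = "leq", threshold = 5)
  u <- rule_utility(r_all, x, negatives = 4:6, positives = 1:3, penalty = 1)
  expect_equal(u$U, 3)          # correct on all of N, no positive mistakes
  expect_equal(u$n_mistakes, 0)
  # p = 1, |N_h| = 3, |Pbar_h| = 2 -> U = 1
  r_low <- list(attribute_id = "a", direction = "leq", threshold = 1.5)
  u2 <- rule_utility(r_low, x, negatives = 4:6, positives = 1:3, penalty = 1)
  expect_equal(c(u2$n_covered, u2$n_mistakes, u2$U), c(3, 2, 1))
  # p = 0 ignores positive mistakes
  u3 <- rule_utility(r_low, x, negatives = 4:6, positives = 1:3, penalty = 0)
  expect_equal(u3$U, 3)
})

test_that("a separable threshold problem is solved by a single rule", {
  x <- cbind(a = c(1, 2, 3, 7, 8, 9))
  y <- c(1, 1, 1, 0, 0, 0)
  fit <- scm(x, y, penalty = 1, max_rules = 2)
  expect_equal(nrow(fit$rules), 1)
  expect_equal(fit$rules$direction, "leq")
  expect_gt(fit$rules$threshold, 3)
  expect_lt(fit$rules$threshold, 7)
  expect_equal(predict(fit, x), y)
  # brute force confirms a single ray attains U = |N| with no mistakes
  best <- oracle_best_rule(x, y, penalty = 1)
  expect_equal(best$U, 3)
  expect_equal(best$Pbar, 0)
})

test_that("early stopping bounds the number of rules", {
  set.seed(1)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(0L, 1L), 25)
  for (s in 1:3) {
    fit <- scm(x, y, penalty = 1, max_rules = s)
    expect_lte(nrow(fit$rules), s)
  }
})

test_that("a two-rule conjunction solves a box layout no single ray separates", {
  x <- cbind(x1 = c(2, 2, 3, 3, 1, 5, 5, 1),
             x2 = c(2, 3, 2, 3, 5, 1, 5, 1))
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  # exhaustive search: no single ray is consistent, but a pair is
  rays <- oracle_enumerate_rays(x)
  single_ok <- any(vapply(rays, function(r) {
    truth <- if (r$dir == "leq") x[, r$j] <= r$thr else x[, r$j] > r$thr
    all(as.integer(truth) == y)
  }, logical(1)))
  expect_false(single_ok)
  expect_true(oracle_pair_separates(x, y))
  fit <- scm(x, y, penalty = 1, max_rules = 2)
  expect_equal(nrow(fit$rules), 2)
  expect_equal(predict(fit, x), y)
})

test_that("greedy rule selection matches brute-force utility maximisation", {
  set.seed(7)
  for (i in 1:150) {
    inst <- random_small_instance()
    p <- sample(c(0, 0.1, 0.5, 1, 3.16, 10), 1)
    best <- oracle_best_rule(inst$x, inst$y, penalty = p)
    fit <- scm(inst$x, inst$y, penalty = p, max_rules = 1)
    if (is.null(best) || best$U <= 0) {
      expect_equal(nrow(fit$rules), 0)
    } else {
      expect_equal(fit$trace$attribute_id, colnames(inst$x)[best$j])
      expect_equal(fit$trace$direction, best$dir)
      expect_equal(fit$trace$threshold, best$thr)
      expect_equal(fit$trace$U, best$U)
      expect_equal(fit$trace$n_covered, best$Nh)
    }
  }
})

test_that("each selected rule covers at least one new negative", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    fit <- scm(x, y, penalty = sample(c(0.5, 1, 2), 1), max_rules = 5)
    if (nrow(fit$trace)) expect_true(all(fit$trace$n_covered >= 1))
  }
})

test_that("rules are equivariant under positive rescaling of an attribute", {
  set.seed(5)
  x <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- as.integer(x[, 2] < 0.3)
  fit <- scm(x, y, penalty = 1, max_rules = 3)
  xs <- x
  xs[, 2] <- xs[, 2] * 10
  fit_s <- scm(xs, y, penalty = 1, max_rules = 3)
  expect_equal(fit_s$rules$attribute_id, fit$rules$attribute_id)
  expect_equal(fit_s$rules$direction, fit$rules$direction)
  scale <- ifelse(fit$rules$attribute_id == "f2", 10, 1)
  expect_equal(fit_s$rules$threshold, fit$rules$threshold * scale)
})

test_that("a disjunction is the De Morgan dual of a conjunction on complemented labels", {
  set.seed(23)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rbinom(20, 1, 0.5)
  y[1:2] <- c(0L, 1L)
  dis <- scm(x, y, penalty = 1, max_rules = 3, model_type = "disjunction")
  con <- scm(x, 1L - y, penalty = 1, max_rules = 3)
  expect_equal(predict(dis, x), 1L - predict(con, x))
  # rule-level duality: same attributes/thresholds, flipped orientation
  expect_equal(dis$rules$attribute_id, con$rules$attribute_id)
  expect_equal(dis$rules$threshold, con$rules$threshold)
  expect_true(all(dis$rules$direction != con$rules$direction))
})

test_that("conjunction prediction semantics", {
  fit <- structure(list(
    model_type = "conjunction",
    rules = data.frame(attribute_id = c("x1", "x2"),
                       direction = c("leq", "gt"), threshold = c(5, 3),
                       stringsAsFactors = FALSE),
    penalty = 1, max_rules = 2), class = "scm")
  nd <- cbind(x1 = c(4, 4), x2 = c(7, 2))
  expect_equal(predict(fit, nd), c(1L, 0L))
  expect_error(predict(fit, cbind(x1 = 1)), "x2")
  # vacuous conjunction (no candidate rule has positive utility)
  empty <- scm(cbind(a = c(1, 1)), c(1, 0), penalty = 1, max_rules = 2)
  expect_equal(nrow(empty$rules), 0)
  expect_equal(predict(empty, cbind(a = c(0, 100))), c(1L, 1L))
})

test_that("single-class training data are rejected", {
  x <- cbind(a = rnorm(5))
  expect_error(scm(x, rep(1, 5), 1, 2), "single class")
})

test_that("planted separable cohorts are solved with high training F1 and few rules", {
  # a high penalty forbids sacrificing positives, which perfect training F1
  # requires; at this effect size a consistent two-ray conjunction exists
  ok <- 0L
  for (seed in 1:20) {
    coh <- small_cohort(n = 100, width = 50, delta = 4, n_down = 1, n_up = 1,
                        seed = seed)
    fs <- assemble_feature_space(list(coh$views$isoform))
    fit <- scm(fs, coh$clinical$label, penalty = 10, max_rules = 2)
    m <- compute_metrics(confusion_counts(coh$clinical$label,
                                          predict(fit, fs)))
    if (m[["f1"]] == 1 && nrow(fit$rules) <= 2) ok <- ok + 1L
  }
  expect_gte(ok, 19)
})

test_that("models round-trip exactly through serialization", {
  set.seed(31)
  x <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, paste0("g", 1:3)))
  y <- as.integer(x[, 1] + 0.3 * rnorm(50) > 0.2)
  fit <- scm(x, y, penalty = 0.316, max_rules = 4)
  path <- tempfile()
  write_scm(fit, path)
  back <- read_scm(path)
  expect_identical(back$rules$threshold, fit$rules$threshold)
  expect_equal(back$rules, fit$rules)
  expect_equal(back$model_type, fit$model_type)
  expect_equal(back$penalty, fit$penalty)
  expect_equal(predict(back, x), predict(fit, x))
  # the human-readable listing carries one rule per line
  txt <- readLines(path)
  expect_equal(sum(!startsWith(txt, "#")), nrow(fit$rules))
})

test_that("cross-validated tuning returns a grid member and respects ties", {
  coh <- small_cohort(n = 80, width = 30, delta = 3, n_down = 1, n_up = 0,
                      seed = 13)
  fs <- assemble_feature_space(list(coh$views$isoform))
  tuned <- scm_tune(fs, coh$clinical$label, folds = 3, seed = 2)
  expect_true(tuned$penalty %in% c(0.1, 0.316, 1, 3.16, 10))
  expect_true(tuned$max_rules %in% 1:5)
  # a strongly separable problem needs only one rule: sparsity tie-break
  expect_equal(tuned$max_rules, 1)
})
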