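# Independent brute-force reference for the greedy SCM step: enumerate every
# midpoint threshold rule by hand and pick the utility maximiser under the
# documented tie-break (larger U, larger |N_h|, smaller attribute index,
# smaller threshold, "leq" before "gt"). Deliberately written from first
# principles, sharing no code with the package's scan.
oracle_enumerate_rays <- function(x) {
  rays <- list()
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      rays[[length(rays) + 1]] <- list(j = j, thr = thr, dir = "leq")
      rays[[length(rays) + 1]] <- list(j = j, thr = thr, dir = "gt")
    }
  }
  rays
}

oracle_best_rule <- function(x, y, penalty,
                             neg_idx = which(y == 0), pos_idx = which(y == 1)) {
  best <- NULL
  for (ray in oracle_enumerate_rays(x)) {
    truth <- if (ray$dir == "leq") x[, ray$j] <= ray$thr else x[, ray$j] > ray$thr
    nh <- sum(!truth[neg_idx])
    pb <- sum(!truth[pos_idx])
    u <- nh - penalty * pb
    key_new <- c(-u, -nh, ray$j, ray$thr, if (ray$dir == "leq") 0 else 1)
    if (is.null(best)) {
      best <- c(ray, list(U = u, Nh = nh, Pbar = pb, key = key_new))
      next
    }
    for (k in seq_along(key_new)) {
      if (key_new[k] < best$key[k]) {
        best <- c(ray, list(U = u, Nh = nh, Pbar = pb, key = key_new))
        break
      }
      if (key_new[k] > best$key[k]) break
    }
  }
  best
}

# Exhaustive search over pairs of rays for a zero-error conjunction.
oracle_pair_separates <- function(x, y) {
  rays <- oracle_enumerate_rays(x)
  ev <- function(ray) {
    if (ray$dir == "leq") x[, ray$j] <= ray$thr else x[, ray$j] > ray$thr
  }
  for (a in seq_along(rays)) {
    ta <- ev(rays[[a]])
    for (b in a:length(rays)) {
      pred <- as.integer(ta & ev(rays[[b]]))
      if (all(pred == y)) return(TRUE)
    }
  }
  FALSE
}

# Random small instance with both classes present and a bounded value grid.
random_small_instance <- function(n_max = 12, p_max = 3, v_max = 6) {
  n <- sample(4:n_max, 1)
  p <- sample(seq_len(p_max), 1)
  x <- matrix(sample(seq_len(v_max), n * p, replace = TRUE), n, p)
  colnames(x) <- paste0("a", seq_len(p))
  y <- sample(c(0L, 1L), n, replace = TRUE)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(x = x, y = y)
}
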