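# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or closed form, separately from the package code
# paths they check.

# Ward (D2 convention) agglomeration by direct Lance-Williams recursion on
# squared dissimilarities; merges the lowest-index pair on exact ties.
# Returns merge steps as lists of member sets plus merge heights.
brute_ward <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  d2 <- d^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1L, n)
  steps <- list()
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      i <- active[a]; j <- active[b]
      if (d2[i, j] < best_d - 1e-15) { best_d <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(best_d))
    new_members <- sort(c(members[[i]], members[[j]]))
    steps[[length(steps) + 1L]] <- new_members
    for (k in active) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((sizes[i] + sizes[k]) * d2[k, i] + (sizes[j] + sizes[k]) * d2[k, j] -
           sizes[k] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    members[[i]] <- new_members
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  list(steps = steps, heights = heights)
}

# Merge steps of an hclust tree as leaf-member sets, for comparison with
# brute_ward.
hclust_steps <- function(hc) {
  n <- nrow(hc$merge) + 1L
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    kids <- hc$merge[s, ]
    grab <- function(k) if (k < 0) -k else sets[[k]]
    sets[[s]] <- sort(c(grab(kids[1]), grab(kids[2])))
  }
  sets
}

# Exhaustive best 2-partition by within-cluster sum of squares.
best_two_partition_ss <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 12)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!any(g) || all(g)) next
    ss <- function(m) { if (sum(m) == 1) return(0)
      sum(sweep(x[m, , drop = FALSE], 2, colMeans(x[m, , drop = FALSE]))^2) }
    best <- min(best, ss(g) + ss(!g))
  }
  best
}

# Closed-form Fisher discriminant: w ~ S_w^{-1}(mu1 - mu0) (unit norm,
# positive class projects positive), offset at the midpoint of projected
# class means.
fisher_oracle <- function(x, positive) {
  x <- as.matrix(x)
  mu1 <- colMeans(x[positive, , drop = FALSE])
  mu0 <- colMeans(x[!positive, , drop = FALSE])
  sw <- crossprod(sweep(x[positive, , drop = FALSE], 2, mu1)) +
    crossprod(sweep(x[!positive, , drop = FALSE], 2, mu0))
  w <- solve(sw) %*% (mu1 - mu0)
  w <- w / sqrt(sum(w^2))
  cc <- as.numeric((t(w) %*% (mu1 + mu0)) / 2)
  list(w = as.numeric(w), c = cc, index = as.numeric(x %*% w - cc))
}

# Greedy one-to-one matching of detected vs true spike times within a
# tolerance; returns sensitivity and precision counts.
match_spike_times <- function(true_s, detected_s, tol_s) {
  used <- logical(length(detected_s))
  tp <- 0L
  for (t in true_s) {
    d <- abs(detected_s - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) { tp <- tp + 1L; used[j] <- TRUE }
  }
  c(tp = tp, fn = length(true_s) - tp, fp = sum(!used))
}

# Small cohort of ISI vectors with known classes, built from simulated
# spike trains at study-regime rates.
make_isi_cohort <- function(n_bursty, n_nonbursty, duration_s = 600, seed = 1) {
  with_seed(seed, {
    classes <- c(rep("bursty", n_bursty), rep("non_bursty", n_nonbursty))
    rates <- exp(runif(length(classes), log(0.019), log(1.87)))
    ivs <- t(mapply(function(cl, r) {
      tr <- simulate_spike_train(cl, r, duration_s)
      while (tr$n_spikes < 2) tr <- simulate_spike_train(cl, r, duration_s)
      isi_vector(tr)
    }, classes, rates))
    rownames(ivs) <- sprintf("cell_%03d", seq_along(classes))
    list(isi = ivs, classes = classes, rates = rates)
  })
}
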