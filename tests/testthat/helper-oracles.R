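# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations (flood fill instead of igraph components,
# exhaustive partition search instead of the DP, per-cell loops instead of
# vectorised algebra).

# flood-fill patch count (stack-based BFS)
bfs_np <- function(mask, queen = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (queen)
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1),
         c(1, 0), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  np <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    np <- np + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (o in offs) {
        r <- cur[1] + o[1]; c_ <- cur[2] + o[2]
        if (r >= 1 && r <= nr && c_ >= 1 && c_ <= nc &&
            mask[r, c_] && !seen[r, c_]) {
          seen[r, c_] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c_)
        }
      }
    }
  }
  np
}

# exhaustive optimal contiguous partition of sorted x into k classes
# (minimum total within-class SSQ); returns the total SSQ and the class
# assignment of each sorted element
brute_jenks <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssq <- function(v) sum((v - mean(v))^2)
  best <- list(val = Inf, assign = NULL)
  # choose k-1 break positions among n-1 gaps
  combs <- utils::combn(n - 1L, k - 1L)
  for (ci in seq_len(ncol(combs))) {
    cuts <- c(0L, combs[, ci], n)
    tot <- 0
    asg <- integer(n)
    for (cl in seq_len(k)) {
      idx <- (cuts[cl] + 1L):cuts[cl + 1L]
      tot <- tot + ssq(x[idx])
      asg[idx] <- cl
    }
    if (tot < best$val - 1e-12) best <- list(val = tot, assign = asg)
  }
  best
}

# total within-class SSQ of a jenks_breaks result applied to sorted x
breaks_ssq <- function(x, brk) {
  x <- sort(x)
  idx <- findInterval(x, brk$edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > brk$k] <- brk$k
  sum(vapply(split(x, idx), function(v) sum((v - mean(v))^2), numeric(1)))
}

# random planning-unit instance for annealer tests (built directly; only
# the fields objective()/anneal() use)
random_instance <- function(n_units, n_features, seed,
                            reserve_one = FALSE) {
  set.seed(seed)
  units <- data.frame(id = seq_len(n_units),
                      cost = round(stats::runif(n_units, 0.1, 1), 3),
                      status = "available")
  if (reserve_one) units$status[sample.int(n_units, 1L)] <- "reserved"
  amounts <- matrix(0, n_units, n_features,
                    dimnames = list(NULL, paste0("f", seq_len(n_features))))
  for (f in seq_len(n_features)) {
    hit <- sample.int(n_units, max(2L, rbinom(1, n_units, 0.5)))
    amounts[hit, f] <- round(stats::runif(length(hit), 0.5, 2), 3)
  }
  n_edges <- min(2L * n_units, n_units * (n_units - 1L) %/% 2L)
  pairs <- unique(t(apply(
    cbind(sample.int(n_units, n_edges, TRUE),
          sample.int(n_units, n_edges, TRUE)), 1L, sort)))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  edges <- data.frame(id1 = pairs[, 1L], id2 = pairs[, 2L],
                      length_km = round(stats::runif(nrow(pairs), 0.5, 2), 3))
  pu <- structure(list(units = units, amounts = amounts, edges = edges,
                       outer_len = round(stats::runif(n_units, 1, 4), 3)),
                  class = "planning_units")
  tot <- colSums(amounts)
  ft <- structure(data.frame(feature = colnames(amounts),
                             target = round(stats::runif(n_features, 0.3, 0.6), 3) * tot,
                             spf = sample(c(1, 3, 5, 10), n_features, TRUE),
                             base_penalty = NA_real_,
                             attainable = TRUE),
                  class = c("feature_targets", "data.frame"))
  # package greedy base-penalty rule, reproduced for the instance
  for (f in seq_len(n_features)) {
    amt <- amounts[, f]
    has <- which(amt > 0)
    ord <- has[order(units$cost[has] / amt[has])]
    cum <- cumsum(amt[ord])
    need <- which(cum >= ft$target[f])[1L]
    if (is.na(need)) need <- length(ord)
    ft$base_penalty[f] <- sum(units$cost[ord[seq_len(need)]])
  }
  list(pu = pu, ft = ft)
}

# exhaustive optimum over all subsets (reserved forced) using the package
# objective()
enumerate_optimum <- function(pu, ft, blm) {
  n <- nrow(pu$units)
  S <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  res_idx <- which(pu$units$status == "reserved")
  if (length(res_idx))
    S <- S[rowSums(S[, res_idx, drop = FALSE]) == length(res_idx), ,
           drop = FALSE]
  vals <- apply(S, 1L, function(s) objective(s, pu, ft, blm)$value)
  list(value = min(vals), selection = S[which.min(vals), ])
}

# tiny aligned grid factory
gridm <- function(v, nr, nc, cell = 1000) grid(matrix(v, nr, nc), cell_size = cell)
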