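# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# --- DBSCAN oracle -----------------------------------------------------------
# Full eps-neighborhood graph; cores from neighbor counts (self included);
# clusters = connected components of the core subgraph (igraph); border points
# join the cluster of their first core neighbor in input order. Clusters are
# renumbered by their earliest member so labels are comparable.
oracle_dbscan <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  d <- as.matrix(dist(x))
  adj <- d <= eps
  core <- which(rowSums(adj) >= min_pts)
  assign <- integer(n)
  if (length(core)) {
    sub <- adj[core, core, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    assign[core] <- comp
    for (p in setdiff(seq_len(n), core)) {
      nb <- intersect(which(adj[p, ]), core)
      if (length(nb)) assign[p] <- assign[min(nb)]
    }
    # canonical numbering: clusters ordered by their earliest core point
    seen <- unique(assign[core])  # core is ascending (from which())
    assign <- ifelse(assign > 0L, match(assign, seen), 0L)
  }
  assign
}

# --- microsatellite scanner oracle ------------------------------------------
# Tests every (start, period) candidate by explicit greedy extension, then
# applies the declared filters (length bounds, N-free, non-periodic unit,
# left-maximality) and the same declared overlap-resolution rule via its own
# quadratic scan. Returns 0-based half-open loci sorted by start.
oracle_msat <- function(seq, min_tract = 7L, max_tract = 60L, max_unit = 4L) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(s)
  cand <- list()
  for (p in seq_len(max_unit)) {
    for (i in seq_len(n)) {
      if (i + p - 1L > n) break
      unit <- paste(s[i:(i + p - 1L)], collapse = "")
      if (grepl("N", unit, fixed = TRUE)) next
      # left-maximal: extending one base left must break the period
      if (i > 1L && s[i - 1L] != "N" && s[i - 1L] == s[i - 1L + p]) next
      # greedy right extension
      m <- p
      while (i + m <= n && s[i + m] != "N" && s[i + m] == s[i + m - p]) {
        m <- m + 1L
      }
      if (m == p) next                     # no repetition at all
      if (m < min_tract || m > max_tract) next
      # unit must not itself be a repetition of a shorter string
      periodic <- FALSE
      for (q in seq_len(p - 1L)) {
        if (p %% q == 0L &&
            unit == strrep(substr(unit, 1L, q), p %/% q)) periodic <- TRUE
      }
      if (periodic) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + m, p = p, tract_length = m,
        unit_raw = unit, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), tract_length = integer(0)))
  cand <- do.call(rbind, cand)
  ord <- order(cand$p, -cand$tract_length, cand$start)
  cand <- cand[ord, , drop = FALSE]
  kept <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    overlaps <- FALSE
    for (j in which(kept)) {
      if (cand$start[i] < cand$end[j] && cand$start[j] < cand$end[i]) {
        overlaps <- TRUE
        break
      }
    }
    kept[i] <- !overlaps
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  rot_min <- vapply(cand$unit_raw, function(u) {
    k <- nchar(u)
    min(vapply(seq_len(k), function(r)
      paste0(substr(u, r, k), substr(u, 1, r - 1L)), ""))
  }, "", USE.NAMES = FALSE)
  data.frame(start = cand$start, end = cand$end, unit = rot_min,
             tract_length = cand$tract_length, stringsAsFactors = FALSE,
             row.names = NULL)
}

# --- Fisher oracle -----------------------------------------------------------
# Two-sided p by enumerating every table with the observed margins and summing
# hypergeometric probabilities <= that of the observed table (with the
# conventional 1 + 1e-7 relative tolerance).
oracle_fisher <- function(a, b, c_, d) {
  m <- a + b          # row 1 margin
  n2 <- c_ + d        # row 2 margin
  k <- a + c_         # column 1 margin
  lo <- max(0L, k - n2)
  hi <- min(m, k)
  probs <- dhyper(lo:hi, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- KS statistic oracle -----------------------------------------------------
# Sup over a dense evaluation set of |F_x - F_y| built from both samples.
oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
}

# Exact permutation distribution of D for tiny samples: all assignments of
# the pooled values into groups of the original sizes.
oracle_ks_perm_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pool), nx)
  d_obs <- oracle_ks_D(x, y)
  d_all <- apply(idx, 2L, function(ii)
    oracle_ks_D(pool[ii], pool[-ii]))
  mean(d_all >= d_obs - 1e-12)
}
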