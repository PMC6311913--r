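## Independent brute-force oracles used to verify the implementation.
## Everything here works from first principles (adjacency matrices, explicit
## enumeration) and never calls the code paths it checks.

adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

## all-pairs shortest-path distances by Floyd-Warshall
o_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

## enumerate every shortest path between s and t (lists of vertex sequences)
o_all_shortest_paths <- function(A, D, s, t) {
  if (s == t) {
    return(list(s))
  }
  out <- list()
  for (u in which(A[s, ] > 0)) {
    if (D[u, t] == D[s, t] - 1) {
      for (tail in o_all_shortest_paths(A, D, u, t)) {
        out[[length(out) + 1L]] <- c(s, tail)
      }
    }
  }
  out
}

o_node_betweenness <- function(A) {
  n <- nrow(A)
  D <- o_distances(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- o_all_shortest_paths(A, D, s, t)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        b[interior] <- b[interior] + 1 / length(paths)
      }
    }
  }
  b
}

o_edge_betweenness <- function(A, edgelist) {
  n <- nrow(A)
  D <- o_distances(A)
  eb <- numeric(nrow(edgelist))
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- o_all_shortest_paths(A, D, s, t)
      for (p in paths) {
        if (length(p) < 2) next
        for (k in seq_len(length(p) - 1)) {
          u <- min(p[k], p[k + 1])
          v <- max(p[k], p[k + 1])
          e <- which(edgelist[, 1] == u & edgelist[, 2] == v)
          eb[e] <- eb[e] + 1 / length(paths)
        }
      }
    }
  }
  eb
}

o_coreness <- function(A) {
  n <- nrow(A)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])[alive]
      low <- which(deg <= k)
      if (length(low) == 0L) break
      idx <- which(alive)[low]
      core[idx] <- k
      alive[idx] <- FALSE
      if (!any(alive)) break
    }
    k <- k + 1L
  }
  core
}

o_constraint <- function(A) {
  n <- nrow(A)
  P <- A / pmax(rowSums(A), 1)
  vapply(seq_len(n), function(i) {
    js <- which(A[i, ] > 0)
    sum(vapply(js, function(j) {
      (P[i, j] + sum(P[i, ] * P[, j] * (seq_len(n) != i & seq_len(n) != j)))^2
    }, numeric(1)))
  }, numeric(1))
}

## bipartite test by BFS 2-coloring: on bipartite graphs the dominant
## eigenspace of A %*% t(A) is degenerate and the hub vector is only defined
## up to that subspace, so mean hub scores are compared via the fixed-point
## property instead of the eigen oracle
o_is_bipartite <- function(A) {
  n <- nrow(A)
  color <- rep(NA_integer_, n)
  color[1] <- 0L
  queue <- 1L
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (u in which(A[v, ] > 0)) {
      if (is.na(color[u])) {
        color[u] <- 1L - color[v]
        queue <- c(queue, u)
      } else if (color[u] == color[v]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

o_hub_score <- function(A) {
  ev <- eigen(A %*% t(A), symmetric = TRUE)$vectors[, 1]
  ev <- abs(ev)
  ev / max(ev)
}

o_cocitation <- function(A) {
  M <- A %*% A
  diag(M) <- 0
  M
}

o_local_transitivity <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) {
      return(0)
    }
    links <- sum(A[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
}

o_global_transitivity <- function(A) {
  triangles <- sum(diag(A %*% A %*% A)) / 6
  deg <- rowSums(A)
  open <- sum(choose(deg, 2))
  if (open == 0) 0 else 3 * triangles / open
}

o_girth <- function(A, edgelist) {
  best <- Inf
  for (e in seq_len(nrow(edgelist))) {
    u <- edgelist[e, 1]
    v <- edgelist[e, 2]
    B <- A
    B[u, v] <- B[v, u] <- 0
    d <- o_distances(B)[u, v]
    if (is.finite(d)) best <- min(best, d + 1)
  }
  if (is.finite(best)) best else 0
}

o_connected <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(A[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

o_articulation_count <- function(A) {
  n <- nrow(A)
  sum(vapply(seq_len(n), function(v) {
    B <- A[-v, -v, drop = FALSE]
    if (nrow(B) <= 1) {
      return(FALSE)
    }
    !o_connected(B)
  }, logical(1)))
}

o_motif_count <- function(A, size) {
  n <- nrow(A)
  if (n < size) {
    return(0)
  }
  sum(utils::combn(n, size, FUN = function(s) {
    o_connected(A[s, s, drop = FALSE])
  }))
}

## modularity of a membership vector from the defining formula
o_modularity <- function(A, membership) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(A[idx, idx]) / 2
    q <- q + e_c / m - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

## the full 24-descriptor oracle, mirroring network_feature_names() order;
## Modularity (16) is checked separately via o_modularity
o_network_features <- function(g) {
  A <- adjacency_of(g)
  el <- igraph::as_edgelist(g)
  el <- t(apply(el, 1, sort))
  deg <- rowSums(A)
  btw <- o_node_betweenness(A)
  D <- o_distances(A)
  core <- o_coreness(A)
  n <- nrow(A)
  ecc <- apply(D, 1, max)
  c(
    mean(deg), stats::var(deg), mean(1 / rowSums(D)),
    mean(btw), stats::var(btw), mean(o_edge_betweenness(A, el)),
    mean(core), stats::var(core), mean(o_constraint(A)), mean(o_hub_score(A)),
    mean(o_cocitation(A)[row(A) != col(A)]), mean(o_cocitation(A)[row(A) != col(A)]),
    mean(o_local_transitivity(A)), o_global_transitivity(A),
    sum(A) / 2 / choose(n, 2), NA,
    max(D), o_girth(A, el), mean(D[upper.tri(D)]),
    o_articulation_count(A), o_motif_count(A, 3), o_motif_count(A, 4),
    mean(ecc), max(core)
  )
}

## exhaustive maximum base-pair count over all valid structures (tiny L)
o_max_pairs <- function(sequence, min_loop = 3) {
  chars <- strsplit(sequence, "")[[1]]
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  best <- function(i, j) {
    if (j - i <= min_loop) {
      return(0)
    }
    res <- best(i + 1, j)
    for (k in seq(i + min_loop + 1, j)) {
      if (can_pair(chars[i], chars[k])) {
        inner <- if (k - i >= 2) best(i + 1, k - 1) else 0
        rest <- if (k < j) best(k + 1, j) else 0
        res <- max(res, 1 + inner + rest)
      }
    }
    res
  }
  best(1, length(chars))
}

## extrema / zero-crossing counts for the IMF admissibility check
local_extrema_counts <- function(x) {
  d <- sign(diff(x))
  d <- d[d != 0]
  extrema <- sum(d[-1] != d[-length(d)])
  s <- sign(x)
  s <- s[s != 0]
  zc <- sum(s[-1] != s[-length(s)])
  list(extrema = extrema, zero_crossings = zc)
}

## independent MI oracle via entropies of count tables
o_mi <- function(a, b) {
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  ent(a) + ent(b) - ent(paste(a, b))
}

## dinucleotide count vector of a sequence
o_dinuc_counts <- function(s) {
  L <- nchar(s)
  table(substring(s, 1:(L - 1), 2:L))
}

## shared small corpus for the expensive end-to-end tests (built once)
.test_cache <- new.env(parent = emptyenv())
test_corpus_features <- function() {
  if (is.null(.test_cache$feats)) {
    corpus <- synth_corpus(n_pos = 50, n_neg = 50, seed = 1)
    .test_cache$corpus <- corpus
    .test_cache$feats <- suppressMessages(extract_features(corpus))
  }
  .test_cache$feats
}
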