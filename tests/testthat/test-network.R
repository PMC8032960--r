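test_that("phi matches the contingency-table formula", {
  a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
  expect_equal(phi_coef(a, b), 0)
  set.seed(41)
  x <- as.integer(runif(50) < 0.4)
  expect_equal(phi_coef(x, x), 1)
  expect_equal(phi_coef(x, 1L - x), -1)
  # random series vs direct formula and cor()
  for (i in 1:10) {
    u <- as.integer(runif(60) < 0.5); v <- as.integer(runif(60) < 0.3)
    n11 <- sum(u & v); n10 <- sum(u & !v); n01 <- sum(!u & v); n00 <- sum(!u & !v)
    want <- (n11 * n00 - n10 * n01) /
      sqrt(n11 + n10) / sqrt(n01 + n00) / sqrt(n11 + n01) / sqrt(n10 + n00)
    expect_equal(phi_coef(u, v), want)
    if (sd(u) > 0 && sd(v) > 0) expect_equal(phi_coef(u, v), cor(u, v))
  }
  # zero marginal -> 0 by convention
  expect_equal(phi_coef(rep(1L, 10), as.integer(runif(10) < 0.5)), 0)
  expect_error(phi_coef(c(1, 0), c(1, 0, 1)), class = "calwave_invalid")
})

test_that("network construction thresholds at phi >= 0.2", {
  r <- as.integer(runif(100) < 0.3)
  net <- build_network(list(r, r, r))
  expect_equal(sum(net$adjacency), 6L)            # complete K3
  expect_equal(diag(net$adjacency), rep(0L, 3))

  # boundary: phi exactly at the threshold keeps the edge
  a <- c(1, 1, 0, 0, 1, 0, 0, 0, 1, 1)
  b <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  net2 <- build_network(cbind(a, b), threshold = phi_coef(a, b))
  expect_equal(net2$adjacency["a", "b"], 1L)

  # independent long rasters give a near-empty graph
  set.seed(52)
  m <- matrix(as.integer(runif(3000 * 8) < 0.2), ncol = 8)
  net3 <- build_network(m)
  expect_lt(sum(net3$adjacency) / 2, 2)
  expect_error(build_network(m[, 1, drop = FALSE]), class = "calwave_invalid")
})

test_that("graph measures match closed forms on canonical graphs", {
  k4 <- matrix(1L, 4, 4); diag(k4) <- 0L
  m <- graph_measures(k4)
  expect_equal(m$density, 1)
  expect_equal(m$global_clustering, 1)
  expect_equal(m$characteristic_path_length, 1)
  expect_equal(m$global_efficiency, 1)
  expect_equal(m$disconnected_pairs, 0L)

  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(graph_measures(path3)$characteristic_path_length, 4 / 3)

  e5 <- matrix(0L, 5, 5)
  m5 <- graph_measures(e5)
  expect_equal(m5$density, 0)
  expect_equal(m5$global_efficiency, 0)
  expect_equal(m5$global_clustering, 0)
  expect_true(is.na(m5$assortativity))

  expect_error(graph_measures(matrix(0, 1, 1)), class = "calwave_invalid")
})

test_that("measures agree with brute-force oracles on random small graphs", {
  bfs_dist <- function(a) {
    n <- nrow(a); d <- matrix(Inf, n, n); diag(d) <- 0
    for (s in 1:n) {
      q <- s; seen <- rep(FALSE, n); seen[s] <- TRUE; depth <- 0
      while (length(q)) {
        nxt <- integer(0)
        for (u in q) for (v in which(a[u, ] == 1)) if (!seen[v]) {
          seen[v] <- TRUE; d[s, v] <- depth + 1; nxt <- c(nxt, v)
        }
        q <- unique(nxt); depth <- depth + 1
      }
    }
    d
  }
  set.seed(61)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.7))
    m <- graph_measures(a)
    # density and degrees
    expect_equal(m$density, sum(a) / (n * (n - 1)))
    # clustering: exhaustive triangles per node
    deg <- rowSums(a)
    loc <- sapply(1:n, function(i) {
      if (deg[i] < 2) return(0)
      nb <- which(a[i, ] == 1)
      sum(a[nb, nb]) / (deg[i] * (deg[i] - 1))
    })
    expect_equal(m$global_clustering, mean(loc))
    # path length / efficiency via BFS
    d <- bfs_dist(a)
    off <- d[row(d) != col(d)]
    fin <- is.finite(off)
    if (any(fin)) expect_equal(m$characteristic_path_length, mean(off[fin]))
    expect_equal(m$global_efficiency, mean(ifelse(fin, 1 / off, 0)))
    expect_equal(m$disconnected_pairs, sum(!fin))
    # assortativity: Pearson correlation of end degrees over directed edges
    ed <- which(a == 1, arr.ind = TRUE)
    if (nrow(ed) > 0 && sd(deg[ed[, 1]]) > 0) {
      expect_equal(m$assortativity, cor(deg[ed[, 1]], deg[ed[, 2]]))
    }
  }
})

test_that("modularity is deterministic and exact on separable graphs", {
  # two disjoint triangles: the optimal partition is the two cliques
  a <- matrix(0L, 6, 6)
  a[1:3, 1:3] <- 1L; a[4:6, 4:6] <- 1L; diag(a) <- 0L
  m <- graph_measures(a)
  # Q for the two-clique partition: 2 * (3/12 - (9/24)^2)... compute directly
  deg <- rowSums(a); E <- sum(a) / 2
  Q <- sum(sapply(list(1:3, 4:6), function(cm)
    sum(a[cm, cm]) / (2 * E) - (sum(deg[cm]) / (2 * E))^2))
  expect_equal(m$modularity, Q)
  # exhaustive bipartition oracle confirms no better two-way split exists
  best <- -Inf
  for (mask in 0:(2^6 - 1)) {
    g1 <- which(bitwAnd(mask, 2^(0:5)) > 0); g2 <- setdiff(1:6, g1)
    q <- sum(sapply(Filter(length, list(g1, g2)), function(cm)
      sum(a[cm, cm]) / (2 * E) - (sum(deg[cm]) / (2 * E))^2))
    best <- max(best, q)
  }
  expect_gte(m$modularity + 1e-12, best)

  m2 <- graph_measures(a)
  expect_identical(m$modularity, m2$modularity)
  # adding an edge never decreases density or efficiency
  a2 <- a; a2[1, 4] <- a2[4, 1] <- 1L
  m3 <- graph_measures(a2)
  expect_gte(m3$density, m$density)
  expect_gte(m3$global_efficiency, m$global_efficiency)
})
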