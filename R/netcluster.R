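as_weight_matrix <- function(graph, year = NULL) {
  if (inherits(graph, "trade_tensor")) {
    if (is.null(year)) stop("specify a year to extract from a trade tensor")
    t <- match(as.integer(year), graph$years)
    if (is.na(t)) stop("year ", year, " not in tensor")
    W <- graph$flows[, , t]
    dimnames(W) <- list(graph$countries, graph$countries)
    return(W)
  }
  W <- as.matrix(graph)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (any(!is.finite(W)) || any(W < 0)) stop("weights must be finite and >= 0")
  diag(W) <- 0
  if (is.null(rownames(W))) {
    rownames(W) <- colnames(W) <- paste0("n", seq_len(nrow(W)))
  }
  W
}

new_partition <- function(assignment, modularity, method, year = NA_integer_) {
  # canonical labels: clusters numbered by first appearance
  nms <- names(assignment)
  assignment <- match(assignment, unique(assignment))
  names(assignment) <- nms
  structure(list(assignment = assignment, modularity = modularity,
                 method = method, year = year),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes, %d clusters, Q = %.4f (%s)\n",
              length(x$assignment), length(unique(x$assignment)),
              x$modularity, x$method))
  invisible(x)
}

#' Directed weighted modularity
#'
#' \deqn{Q = \frac{1}{w}\sum_{ij:\,c_i=c_j}\left(w_{ij} -
#'   \frac{w_i^{out} w_j^{in}}{w}\right)}
#' where `w` is the total edge weight, the directed weighted form of the
#' modularity score. Self-loops are excluded (the trade tensor has none).
#'
#' @param graph square non-negative weight matrix (rows = senders), or a
#'   [trade_tensor()] with `year`.
#' @param membership integer/character cluster label per node, or a
#'   `partition` object.
#' @param year year to extract when `graph` is a tensor.
#' @return Modularity score in \[-1, 1\].
#' @export
directed_modularity <- function(graph, membership, year = NULL) {
  W <- as_weight_matrix(graph, year)
  if (inherits(membership, "partition")) membership <- membership$assignment
  if (length(membership) != nrow(W)) {
    stop("membership length must equal the number of nodes")
  }
  w <- sum(W)
  if (w <= 0) stop("zero-weight graph: modularity undefined")
  wout <- rowSums(W)
  win <- colSums(W)
  same <- outer(membership, membership, "==")
  sum((W - outer(wout, win) / w)[same]) / w
}

# per-cluster contribution table used by the exact search and greedy merge:
# e[a,b] = sum of weights from cluster a to cluster b / w;
# modularity = sum_a (e[a,a] - aout[a]*ain[a])

#' Exact modularity-maximizing partition
#'
#' Globally maximal directed weighted modularity over all set partitions,
#' by depth-first search over restricted-growth assignments with a
#' branch-and-bound pruning rule (each undecided pair can contribute at
#' most `max(0, w_ij + w_ji - (wout_i win_j + wout_j win_i)/w)/w`). Ties
#' are broken by fewest clusters, then lexicographically smallest canonical
#' assignment.
#'
#' @param graph square weight matrix or [trade_tensor()] (+ `year`).
#' @param year tensor year.
#' @param exact_limit refuse graphs with more nodes than this (default 16).
#' @return A `partition` with `method = "exact"`.
#' @export
exact_modularity_partition <- function(graph, year = NULL, exact_limit = 16L) {
  W <- as_weight_matrix(graph, year)
  n <- nrow(W)
  w <- sum(W)
  if (w <= 0) stop("zero-weight graph: modularity undefined")
  if (n > exact_limit) {
    stop("exact search limited to ", exact_limit,
         " nodes; use greedy_modularity_partition() for larger graphs")
  }
  wout <- rowSums(W) / w
  win <- colSums(W) / w
  Wn <- W / w
  # pairwise gain if i and j share a cluster (both directions)
  gain <- Wn + t(Wn) - outer(wout, win) - t(outer(wout, win))
  diag(gain) <- 0
  # fixed diagonal term: every node pays -wout_i*win_i regardless of labels
  base <- -sum(wout * win)
  # bound after deciding nodes 1..k: every pair with an undecided endpoint
  # can at best contribute its positive gain (undecided i pairs with all
  # j < i, covering decided-undecided and undecided-undecided pairs once)
  suffix_bound <- numeric(n + 1)
  for (k in n:0) {
    b <- 0
    if (k < n) {
      for (i in (k + 1):n) {
        if (i > 1) b <- b + sum(pmax(gain[i, seq_len(i - 1)], 0))
      }
    }
    suffix_bound[k + 1] <- b
  }

  best_q <- -Inf
  best_assign <- NULL
  assign <- integer(n)
  lex_less <- function(a, b) {
    i <- which(a != b)[1]
    !is.na(i) && a[i] < b[i]
  }

  recurse <- function(k, n_clusters, q_now) {
    if (q_now + suffix_bound[k] < best_q - 1e-12) return()
    if (k > n) {
      better <- q_now > best_q + 1e-12
      tie <- !better && q_now >= best_q - 1e-12
      if (better ||
          (tie && (n_clusters < length(unique(best_assign)) ||
                     (n_clusters == length(unique(best_assign)) &&
                        lex_less(assign, best_assign))))) {
        best_q <<- max(best_q, q_now)
        best_assign <<- assign[seq_len(n)]
      }
      return()
    }
    for (c in seq_len(n_clusters + 1L)) {
      assign[k] <<- c
      dq <- if (k == 1L) 0 else sum(gain[k, which(assign[seq_len(k - 1)] == c)])
      recurse(k + 1L, max(n_clusters, c), q_now + dq)
    }
    assign[k] <<- 0L
  }
  recurse(1L, 0L, base)

  p <- new_partition(stats::setNames(best_assign, rownames(W)),
                     best_q, "exact", if (is.null(year)) NA_integer_ else year)
  p$modularity <- directed_modularity(W, p$assignment)
  p
}

#' Greedy agglomerative modularity partition
#'
#' Deterministic scalable stand-in for the exact optimizer: start from
#' singletons and repeatedly merge the cluster pair with the largest
#' directed-modularity gain while a strictly positive gain exists; ties go
#' to the lexicographically smallest cluster-label pair.
#'
#' @param graph square weight matrix or [trade_tensor()] (+ `year`).
#' @param year tensor year.
#' @param seed unused (the algorithm is deterministic); kept so callers can
#'   treat all partition methods uniformly.
#' @return A `partition` with `method = "greedy"`.
#' @export
greedy_modularity_partition <- function(graph, year = NULL, seed = NULL) {
  W <- as_weight_matrix(graph, year)
  n <- nrow(W)
  w <- sum(W)
  if (w <= 0) stop("zero-weight graph: modularity undefined")
  wout <- rowSums(W) / w
  win <- colSums(W) / w
  Wn <- W / w
  gain <- Wn + t(Wn) - outer(wout, win) - t(outer(wout, win))
  diag(gain) <- 0
  member <- as.list(seq_len(n))  # clusters as node index sets
  labels <- seq_len(n)
  active <- rep(TRUE, n)
  # gain between clusters = sum of pairwise node gains
  G <- gain
  repeat {
    Gm <- G
    Gm[!active, ] <- -Inf
    Gm[, !active] <- -Inf
    diag(Gm) <- -Inf
    mx <- max(Gm)
    if (!is.finite(mx) || mx <= 1e-12) break
    hits <- which(Gm >= mx - 1e-15, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pick <- hits[order(hits[, 1], hits[, 2])[1], ]
    a <- pick[1]; b <- pick[2]
    member[[a]] <- c(member[[a]], member[[b]])
    active[b] <- FALSE
    G[a, ] <- G[a, ] + G[b, ]
    G[, a] <- G[, a] + G[, b]
    G[a, a] <- 0
  }
  assign <- integer(n)
  for (c in which(active)) assign[member[[c]]] <- c
  p <- new_partition(stats::setNames(assign, rownames(W)),
                     0, "greedy", if (is.null(year)) NA_integer_ else year)
  p$modularity <- directed_modularity(W, p$assignment)
  p
}

#' Random-walk (walktrap-style) partition
#'
#' Symmetrizes the weights (`w_ij + w_ji`; random walks on a directed trade
#' graph can be absorbing), computes `steps`-step random-walk profile
#' distances between nodes, agglomerates them by Ward-linkage hierarchical
#' clustering, and cuts the dendrogram at the level maximizing the
#' *directed* modularity of the original graph. Disconnected components
#' separate naturally through infinite-profile distances.
#'
#' @param graph square weight matrix or [trade_tensor()] (+ `year`).
#' @param steps random-walk length (default 4).
#' @param year tensor year.
#' @return A `partition` with `method = "walktrap"`.
#' @export
walktrap_partition <- function(graph, steps = 4L, year = NULL) {
  if (!is.numeric(steps) || steps < 1) stop("steps must be a positive integer")
  W <- as_weight_matrix(graph, year)
  n <- nrow(W)
  w <- sum(W)
  if (w <= 0) stop("zero-weight graph: modularity undefined")
  S <- W + t(W)
  deg <- rowSums(S)
  P <- S / ifelse(deg > 0, deg, 1)
  P[deg == 0, ] <- 0
  diag(P)[deg == 0] <- 1  # isolated nodes stay put
  Pk <- diag(n)
  for (k in seq_len(round(steps))) Pk <- Pk %*% P
  # Pons-Latapy profile distance, degree-scaled
  scale <- 1 / sqrt(pmax(deg, min(deg[deg > 0])))
  Z <- Pk * rep(scale, each = n)
  D <- stats::dist(Z)
  hc <- stats::hclust(D, method = "ward.D2")
  best <- NULL
  for (k in seq_len(n)) {
    mem <- stats::cutree(hc, k = k)
    q <- directed_modularity(W, mem)
    if (is.null(best) || q > best$q + 1e-12) best <- list(q = q, mem = mem)
  }
  new_partition(stats::setNames(best$mem, rownames(W)), best$q, "walktrap",
                if (is.null(year)) NA_integer_ else year)
}

#' k-core decomposition
#'
#' Classic peeling on the binarized graph using total (in + out) degree:
#' the core number of a node is the largest `k` such that the node survives
#' in the subgraph where every node has total degree at least `k`.
#'
#' @param graph square weight matrix or [trade_tensor()] (+ `year`).
#' @param year tensor year.
#' @return Named integer vector of core numbers.
#' @export
k_core_levels <- function(graph, year = NULL) {
  W <- as_weight_matrix(graph, year)
  A <- (W > 0) * 1L
  n <- nrow(A)
  core <- stats::setNames(integer(n), rownames(W))
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    repeat {
      sub <- A[alive, alive, drop = FALSE]
      deg <- rowSums(sub) + colSums(sub)
      drop_now <- which(alive)[deg < k + 1L]
      if (length(drop_now) == 0) break
      core[drop_now] <- k
      alive[drop_now] <- FALSE
    }
    k <- k + 1L
    if (k > n) break
  }
  core
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster assignments over the same
#' node set: 1 for identical partitions, about 0 for independent ones.
#'
#' @param p1,p2 `partition` objects or named label vectors over the same
#'   nodes.
#' @return Adjusted Rand index in \[-1, 1\].
#' @export
compare_partitions <- function(p1, p2) {
  lab <- function(p) if (inherits(p, "partition")) p$assignment else p
  a <- lab(p1); b <- lab(p2)
  if (length(a) != length(b)) stop("partitions cover different node counts")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("partitions cover different node sets")
    }
    b <- b[names(a)]
  }
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)  # both trivial partitions
  (sum_ij - expected) / (mx - expected)
}

#' Cluster every year of a trade tensor
#'
#' @param tensor a [trade_tensor()].
#' @param method one of `"greedy"`, `"exact"`, `"walktrap"`.
#' @param major_threshold clusters with more countries than this are
#'   labelled "major" (default 10).
#' @param ... passed to the method.
#' @return A list with `partitions` (one `partition` per year) and
#'   `summary` (data frame: year, method, n_clusters, n_major, modularity).
#' @export
cluster_years <- function(tensor, method = c("greedy", "exact", "walktrap"),
                          major_threshold = 10L, ...) {
  stopifnot(inherits(tensor, "trade_tensor"))
  method <- match.arg(method)
  f <- switch(method,
              greedy = greedy_modularity_partition,
              exact = exact_modularity_partition,
              walktrap = walktrap_partition)
  parts <- lapply(tensor$years, function(yr) f(tensor, year = yr, ...))
  names(parts) <- tensor$years
  summary <- do.call(rbind, lapply(parts, function(p) {
    sizes <- table(p$assignment)
    data.frame(year = p$year, method = p$method,
               n_clusters = length(sizes),
               n_major = sum(sizes > major_threshold),
               modularity = p$modularity)
  }))
  rownames(summary) <- NULL
  list(partitions = parts, summary = summary)
}
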