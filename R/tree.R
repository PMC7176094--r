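# Recursive-partitioning tree learner on a numeric design matrix.
#
# One grower serves three roles: classification trees for direct
# propensity estimation (gini ~ CART, entropy ~ C4.5/C5.0), unpruned
# classification trees as random-forest base learners, and
# depth-limited regression trees as gradient-boosting base learners.
# All covariates arrive one-hot encoded or numeric, so every split is a
# threshold split "x_j <= s".
#
# The tree is stored as a flat data frame of nodes (var, split, left,
# right, value, n, n1); leaves have var = 0. Prediction routes all rows
# iteratively, no recursion at predict time.

node_impurity <- function(n1, n, criterion) {
  p <- n1 / n
  switch(criterion,
    gini = 2 * p * (1 - p),
    entropy = ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p)),
    stop("unknown criterion"))
}

# Best threshold split of (x, y) for one node. Returns NULL or
# list(var, split, gain). y is binary for classification criteria and
# real for criterion = "variance".
best_split <- function(x, y, criterion, min_node) {
  n <- length(y)
  best <- NULL
  best_gain <- 1e-12 # require strictly positive improvement
  parent <- if (criterion == "variance") {
    sum((y - mean(y))^2)
  } else {
    n * node_impurity(sum(y), n, criterion)
  }
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    ord <- order(xj)
    xs <- xj[ord]
    ys <- y[ord]
    # candidate cut after position i where the covariate changes value
    cut_ok <- which(diff(xs) > 0)
    if (!length(cut_ok)) next
    nl <- seq_len(n - 1)
    if (criterion == "variance") {
      cl <- cumsum(ys)[-n]
      cr <- sum(ys) - cl
      sl <- cumsum(ys^2)[-n]
      sr <- sum(ys^2) - sl
      child <- (sl - cl^2 / nl) + (sr - cr^2 / (n - nl))
    } else {
      c1l <- cumsum(ys)[-n]
      c1r <- sum(ys) - c1l
      child <- nl * node_impurity(c1l, nl, criterion) +
        (n - nl) * node_impurity(c1r, n - nl, criterion)
    }
    ok <- cut_ok[cut_ok >= min_node & (n - cut_ok) >= min_node]
    if (!length(ok)) next
    gains <- parent - child[ok]
    i <- which.max(gains)
    if (gains[i] > best_gain) {
      best_gain <- gains[i]
      pos <- ok[i]
      best <- list(var = j, split = (xs[pos] + xs[pos + 1]) / 2,
                   gain = gains[i])
    }
  }
  best
}

# Grow a tree. For classification y in {0,1} and value = mean(y) in the
# leaf (the volunteer fraction); for regression value = mean(y).
grow_tree <- function(x, y, criterion = "gini", min_node = 1L,
                      max_depth = Inf) {
  nodes <- list()
  # each entry: c(var, split, left, right, value, n, n1)
  build <- function(idx, depth) {
    n <- length(idx)
    yv <- y[idx]
    id <- length(nodes) + 1L
    nodes[[id]] <<- c(var = 0, split = NA_real_, left = 0, right = 0,
                      value = mean(yv), n = n,
                      n1 = if (criterion == "variance") NA_real_ else sum(yv))
    pure <- if (criterion == "variance") var(yv) == 0 || n < 2
            else sum(yv) %in% c(0L, n)
    if (depth >= max_depth || n < 2 * min_node || isTRUE(pure)) return(id)
    sp <- best_split(x[idx, , drop = FALSE], yv, criterion, min_node)
    if (is.null(sp)) return(id)
    go_left <- x[idx, sp$var] <= sp$split
    lid <- build(idx[go_left], depth + 1L)
    rid <- build(idx[!go_left], depth + 1L)
    node <- nodes[[id]]
    node[c("var", "split", "left", "right")] <- c(sp$var, sp$split, lid, rid)
    nodes[[id]] <<- node
    id
  }
  build(seq_along(y), 0L)
  tree <- as.data.frame(do.call(rbind, nodes))
  structure(list(nodes = tree, criterion = criterion, p = ncol(x)),
            class = "psa_tree")
}

# Route rows of x to their terminal node; returns node ids.
tree_leaf_of <- function(tree, x) {
  nodes <- tree$nodes
  at <- rep(1L, nrow(x))
  repeat {
    internal <- nodes$var[at] > 0
    if (!any(internal)) return(at)
    i <- which(internal)
    v <- nodes$var[at[i]]
    s <- nodes$split[at[i]]
    go_left <- x[cbind(i, v)] <= s
    at[i] <- ifelse(go_left, nodes$left[at[i]], nodes$right[at[i]])
  }
}

predict_tree <- function(tree, x) {
  tree$nodes$value[tree_leaf_of(tree, x)]
}

# Pessimistic (confidence-bound) pruning in the C4.5 style: a subtree
# is collapsed when the upper confidence bound of its leaf error counts
# is no better than the bound at the node itself. Smaller `confidence`
# inflates the bound more and prunes harder. Uses the exact
# Clopper-Pearson upper bound of a binomial error rate.
prune_tree <- function(tree, confidence = 0.25) {
  nodes <- tree$nodes
  ucb_errors <- function(n, n1) {
    e <- pmin(n1, n - n1) # misclassified count under majority vote
    n * qbeta(1 - confidence, e + 1, pmax(n - e, 0) + 1e-9)
  }
  # estimated error of the subtree rooted at each node (bottom-up: node
  # ids of children are always larger than the parent's)
  est <- numeric(nrow(nodes))
  for (id in rev(seq_len(nrow(nodes)))) {
    if (nodes$var[id] == 0) {
      est[id] <- ucb_errors(nodes$n[id], nodes$n1[id])
    } else {
      sub <- est[nodes$left[id]] + est[nodes$right[id]]
      here <- ucb_errors(nodes$n[id], nodes$n1[id])
      if (here <= sub) {
        nodes$var[id] <- 0
        nodes$left[id] <- nodes$right[id] <- 0
        est[id] <- here
      } else {
        est[id] <- sub
      }
    }
  }
  tree$nodes <- nodes
  tree
}
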