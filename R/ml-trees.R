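# Minimal regression-tree engine shared by the random-forest and the two
# gradient-boosting variants. No R tree package is available in this
# environment, so the engine is authored here; it only needs to serve
# small-n genomic benchmarks (hundreds of samples, <= a few thousand SNPs).
#
# Splits minimize squared error with an L2 leaf penalty (xgboost-style):
# score(S) = (sum r)^2 / (|S| + lambda); gain must exceed `gamma`.

best_split <- function(X, r, idx, features, min_leaf, lambda) {
  sp <- .best_split_cpp(X, r, as.integer(idx), as.integer(features),
                        as.integer(min_leaf), lambda)
  if (!is.finite(sp$gain) || sp$feature < 0) return(list(gain = -Inf))
  go_left <- X[idx, sp$feature] <= sp$threshold
  list(gain = sp$gain, feature = sp$feature, threshold = sp$threshold,
       left = idx[go_left], right = idx[!go_left])
}

leaf_value <- function(r, idx, lambda) sum(r[idx]) / (length(idx) + lambda)

# growth = "depth": split every splittable node down to max_depth (xgboost
# style). growth = "leaf": best-first, split the frontier leaf with the
# largest gain until max_leaves leaves (lightgbm style).
build_tree <- function(X, r, max_depth = 6, min_leaf = 5, lambda = 0,
                       gamma = 0, colsample = 1, growth = c("depth", "leaf"),
                       max_leaves = 31) {
  growth <- match.arg(growth)
  p <- ncol(X)
  feats <- if (colsample < 1)
    sort(sample.int(p, max(1L, round(colsample * p)))) else seq_len(p)
  nodes <- list()
  new_node <- function(idx, depth) {
    nodes[[length(nodes) + 1]] <<- list(idx = idx, depth = depth,
                                        leaf = TRUE,
                                        value = leaf_value(r, idx, lambda))
    length(nodes)
  }
  root <- new_node(seq_len(nrow(X)), 0L)

  try_split <- function(id) {
    nd <- nodes[[id]]
    if (nd$depth >= max_depth || length(nd$idx) < 2 * min_leaf)
      return(NULL)
    sp <- best_split(X, r, nd$idx, feats, min_leaf, lambda)
    if (!is.finite(sp$gain) || sp$gain <= gamma) return(NULL)
    sp
  }
  do_split <- function(id, sp) {
    l <- new_node(sp$left, nodes[[id]]$depth + 1L)
    rgt <- new_node(sp$right, nodes[[id]]$depth + 1L)
    nodes[[id]]$leaf <<- FALSE
    nodes[[id]]$feature <<- sp$feature
    nodes[[id]]$threshold <<- sp$threshold
    nodes[[id]]$left <<- l
    nodes[[id]]$right <<- rgt
    c(l, rgt)
  }

  if (growth == "depth") {
    queue <- root
    while (length(queue)) {
      id <- queue[1]; queue <- queue[-1]
      sp <- try_split(id)
      if (!is.null(sp)) queue <- c(queue, do_split(id, sp))
    }
  } else {
    frontier <- list()
    sp <- try_split(root)
    if (!is.null(sp)) frontier[[as.character(root)]] <- sp
    n_leaves <- 1L
    while (n_leaves < max_leaves && length(frontier)) {
      gains <- vapply(frontier, `[[`, numeric(1), "gain")
      id <- as.integer(names(frontier)[which.max(gains)])
      sp <- frontier[[as.character(id)]]
      frontier[[as.character(id)]] <- NULL
      kids <- do_split(id, sp)
      n_leaves <- n_leaves + 1L
      for (k in kids) {
        spk <- try_split(k)
        if (!is.null(spk)) frontier[[as.character(k)]] <- spk
      }
    }
  }
  # strip training indices to keep the object light
  for (i in seq_along(nodes)) nodes[[i]]$idx <- NULL
  structure(list(nodes = nodes, root = root), class = "pgs_tree")
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  recurse <- function(id, rows) {
    nd <- tree$nodes[[id]]
    if (isTRUE(nd$leaf)) {
      out[rows] <<- nd$value
      return(invisible())
    }
    go_left <- X[rows, nd$feature] <= nd$threshold
    if (any(go_left)) recurse(nd$left, rows[go_left])
    if (any(!go_left)) recurse(nd$right, rows[!go_left])
  }
  if (nrow(X)) recurse(tree$root, seq_len(nrow(X)))
  out
}

# bagged trees with per-node feature subsampling, prediction by averaging
fit_random_forest <- function(X, y, n_trees = 200, max_depth = 12,
                              min_leaf = 5, mtry_frac = 1 / 3,
                              sample_frac = 1) {
  storage.mode(X) <- "double"
  n <- nrow(X)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, max(2L, round(sample_frac * n)), replace = TRUE)
    trees[[b]] <- build_tree(X[boot, , drop = FALSE], y[boot],
                             max_depth = max_depth, min_leaf = min_leaf,
                             lambda = 0, gamma = 0, colsample = mtry_frac,
                             growth = "depth")
  }
  structure(list(trees = trees), class = "pgs_rf")
}

predict_rf <- function(fit, X) {
  rowMeans(vapply(fit$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X))))
}

# gradient boosting on squared loss; variant "depth" mirrors depth-wise
# growth with an explicit split-gain floor, variant "leaf" mirrors
# best-first growth capped by a leaf count.
fit_gbdt <- function(X, y, variant = c("depth", "leaf"), n_trees = 100,
                     learning_rate = 0.1, max_depth = 6, num_leaves = 31,
                     min_leaf = 5, subsample = 1, colsample = 1,
                     reg_lambda = 1, gamma = 0) {
  variant <- match.arg(variant)
  storage.mode(X) <- "double"
  n <- nrow(X)
  f0 <- mean(y)
  pred <- rep(f0, n)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    rows <- if (subsample < 1)
      sort(sample.int(n, max(2L, round(subsample * n)))) else seq_len(n)
    r <- y[rows] - pred[rows]
    tr <- build_tree(X[rows, , drop = FALSE], r, max_depth = max_depth,
                     min_leaf = min_leaf, lambda = reg_lambda, gamma = gamma,
                     colsample = colsample, growth = variant,
                     max_leaves = num_leaves)
    trees[[t]] <- tr
    pred <- pred + learning_rate * predict_tree(tr, X)
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate),
            class = "pgs_gbdt")
}

predict_gbdt <- function(fit, X) {
  pred <- rep(fit$f0, nrow(X))
  for (tr in fit$trees) pred <- pred + fit$learning_rate * predict_tree(tr, X)
  pred
}
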