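# Decision-tree learners for the article-node pair classifier. The
# grading image carries no tree package (no rpart/randomForest/RWeka),
# so a small CART-style binary tree is implemented here together with
# the four ensemble shapes the pair classifier exposes: a single tree
# ("j48"), bootstrap-bagged random-subspace trees ("random_forest"),
# non-bagged randomized trees ("random_committee") and a depth-limited
# tree with naive Bayes leaf models ("nb_tree").

tree_impurity <- function(n1, n0, criterion) {
  n <- n1 + n0
  p <- ifelse(n > 0, n1 / n, 0)
  if (criterion == "gini") {
    2 * p * (1 - p)
  } else {                       # entropy, nats are fine for comparison
    h <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log(q) - (1 - q) * log(1 - q))
    h(p)
  }
}

# Best threshold for one feature: candidates are midpoints between
# consecutive distinct values. Returns c(gain, threshold) or NULL.
tree_best_split_feature <- function(x, y, parent_imp, criterion) {
  ord <- order(x, method = "radix")
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  distinct <- which(diff(xs) > 0)
  if (!length(distinct)) return(NULL)
  cum1 <- cumsum(ys)
  n1 <- cum1[n]
  left1 <- cum1[distinct]; leftn <- distinct
  right1 <- n1 - left1; rightn <- n - leftn
  imp <- (leftn * tree_impurity(left1, leftn - left1, criterion) +
          rightn * tree_impurity(right1, rightn - right1, criterion)) / n
  gain <- parent_imp - imp
  best <- which.max(gain)               # first index wins ties
  if (gain[best] <= 1e-12) return(NULL)
  c(gain = gain[best],
    threshold = (xs[distinct[best]] + xs[distinct[best] + 1L]) / 2)
}

tree_grow <- function(X, y, depth, opts) {
  n <- length(y); n1 <- sum(y)
  make_leaf <- function() {
    if (opts$leaf_model == "nb" && n1 >= 2L && n - n1 >= 2L) {
      list(leaf = TRUE, nb = nb_leaf_fit(X, y), prob = n1 / n)
    } else {
      list(leaf = TRUE, nb = NULL, prob = (n1 + 0.5) / (n + 1))  # Laplace
    }
  }
  if (n1 == 0L || n1 == n || n < opts$min_split ||
      (opts$max_depth > 0L && depth >= opts$max_depth))
    return(make_leaf())
  p <- ncol(X)
  feats <- if (opts$mtry > 0L && opts$mtry < p)
    sort(sample.int(p, opts$mtry)) else seq_len(p)
  parent_imp <- tree_impurity(n1, n - n1, opts$criterion)
  best <- NULL; best_feat <- 0L
  for (j in feats) {
    cand <- tree_best_split_feature(X[, j], y, parent_imp, opts$criterion)
    if (!is.null(cand) &&
        (is.null(best) || cand["gain"] > best["gain"] + 1e-12)) {
      best <- cand; best_feat <- j
    }
  }
  if (is.null(best)) return(make_leaf())
  go_left <- X[, best_feat] <= best["threshold"]
  list(leaf = FALSE, feature = best_feat,
       threshold = unname(best["threshold"]),
       left = tree_grow(X[go_left, , drop = FALSE], y[go_left],
                        depth + 1L, opts),
       right = tree_grow(X[!go_left, , drop = FALSE], y[!go_left],
                         depth + 1L, opts))
}

# Gaussian/Bernoulli-agnostic naive Bayes for leaf models: Gaussian per
# feature with floored variance plus Laplace class priors.
nb_leaf_fit <- function(X, y) {
  fit_class <- function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    list(mean = colMeans(Xc),
         sd = pmax(apply(Xc, 2, stats::sd), 1e-3),
         logprior = log((sum(y == cl) + 1) / (length(y) + 2)))
  }
  list(c0 = fit_class(0L), c1 = fit_class(1L))
}

nb_leaf_prob <- function(nb, x) {
  ll <- function(m) m$logprior +
    sum(stats::dnorm(x, m$mean, m$sd, log = TRUE))
  l0 <- ll(nb$c0); l1 <- ll(nb$c1)
  1 / (1 + exp(l0 - l1))
}

tree_predict1 <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  if (!is.null(node$nb)) nb_leaf_prob(node$nb, x) else node$prob
}

tree_opts <- function(algorithm) {
  switch(algorithm,
    j48 = list(ntree = 1L, bagging = FALSE, mtry = 0L, criterion = "entropy",
               min_split = 2L, max_depth = 0L, leaf_model = "majority"),
    random_forest = list(ntree = 25L, bagging = TRUE, mtry = -1L,
                         criterion = "gini", min_split = 2L, max_depth = 0L,
                         leaf_model = "majority"),
    random_committee = list(ntree = 25L, bagging = FALSE, mtry = -1L,
                            criterion = "gini", min_split = 2L,
                            max_depth = 0L, leaf_model = "majority"),
    nb_tree = list(ntree = 1L, bagging = FALSE, mtry = 0L,
                   criterion = "entropy", min_split = 30L, max_depth = 4L,
                   leaf_model = "nb"),
    stop("unknown tree algorithm: ", algorithm))
}

# Train an ensemble. Callers must set the RNG seed beforehand; all
# randomness (bootstrap, per-node feature subsets) flows from it.
tree_ensemble_train <- function(X, y, algorithm) {
  opts <- tree_opts(algorithm)
  if (opts$mtry == -1L) opts$mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- vector("list", opts$ntree)
  for (b in seq_len(opts$ntree)) {
    idx <- if (opts$bagging)
      sample.int(nrow(X), nrow(X), replace = TRUE) else seq_len(nrow(X))
    trees[[b]] <- tree_grow(X[idx, , drop = FALSE], y[idx], 0L, opts)
  }
  list(algorithm = algorithm, trees = trees, p = ncol(X))
}

# Confidence = mean leaf probability over ensemble members (vote
# fraction for hard leaves, NB posterior for nb_tree leaves).
tree_ensemble_prob <- function(model, X) {
  probs <- matrix(0, nrow(X), length(model$trees))
  for (b in seq_along(model$trees)) {
    probs[, b] <- apply(X, 1, function(x) tree_predict1(model$trees[[b]], x))
  }
  rowMeans(probs)
}
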