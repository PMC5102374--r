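# Test helpers: random instance generators and a brute-force parsimony
# oracle that enumerates every ancestral assignment.  The oracle shares no
# code with the package's dynamic programmes: costs are summed edge by edge
# over an explicit assignment grid.

# random rooted tree, possibly multifurcating (collapse ~30% of internal
# edges of a random binary tree)
random_poly_tree <- function(n_tips, p_collapse = 0.3) {
  tr <- ape::rtree(n_tips)
  internal <- tr$edge[, 2L] > n_tips
  zap <- internal & stats::runif(nrow(tr$edge)) < p_collapse
  tr$edge.length[zap] <- 0
  tr <- ape::di2multi(tr, tol = 1e-9)
  tr$edge.length <- NULL
  tr
}

# random character column over k states, optionally with missing and
# polymorphic cells; returns a char_matrix for the tree's tips
random_char_column <- function(tree, k = 3, p_missing = 0, p_poly = 0,
                               name = "trait") {
  states <- paste0("s", seq_len(k))
  tips <- tree$tip.label
  cells <- vapply(tips, function(t) {
    u <- stats::runif(1)
    if (u < p_missing) return("?")
    if (u < p_missing + p_poly && k >= 2) {
      pick <- sample(states, 2L)
      return(paste(sort(pick), collapse = "|"))
    }
    sample(states, 1L)
  }, character(1))
  m <- matrix(cells, ncol = 1L, dimnames = list(tips, name))
  char_matrix(m, characters = list(char_def(name, states)))
}

# tiny constructor: one named character column -> char_matrix with declared
# state space
tiny_cm <- function(values, states, name = "trait") {
  m <- matrix(values, ncol = 1L, dimnames = list(names(values), name))
  char_matrix(m, characters = list(char_def(name, states)))
}

# Brute-force oracle: enumerate every assignment of states to free nodes
# (internal nodes plus tips with more than one allowed state), score each
# by summed edge costs, and keep the optima.
oracle_enumerate <- function(tree, data, character, cost = NULL,
                             max_comb = 2e5) {
  def <- data$characters[[character]]
  states <- def$states
  k <- length(states)
  if (is.null(cost)) cost <- def$cost
  if (is.null(cost)) cost <- matrix(1, k, k) - diag(k)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  allowed_tips <- euplotia:::.allowed_states(data, tree, character)
  opts <- vector("list", n_all)
  for (v in seq_len(n_all)) {
    opts[[v]] <- if (v <= n_tip) which(allowed_tips[v, ]) else seq_len(k)
  }
  n_comb <- prod(lengths(opts))
  stopifnot(n_comb <= max_comb)
  grid <- as.matrix(expand.grid(opts, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- NULL
  E <- tree$edge
  total <- numeric(nrow(grid))
  for (e in seq_len(nrow(E)))
    total <- total + cost[cbind(grid[, E[e, 1L]], grid[, E[e, 2L]])]
  mn <- min(total)
  opt <- grid[total == mn, , drop = FALSE]
  root <- setdiff(E[, 1L], E[, 2L])[1L]
  list(min = mn, states = states, opt = opt, root = root, edge = E,
       node_sets = lapply(seq_len(n_all),
                          function(v) sort(unique(states[opt[, v]]))))
}

oracle_transition_interval <- function(or, from, to) {
  fi <- match(from, or$states); ti <- match(to, or$states)
  cnt <- apply(or$opt, 1L, function(a)
    sum(a[or$edge[, 1L]] == fi & a[or$edge[, 2L]] == ti))
  c(min(cnt), max(cnt))
}

oracle_origin_interval <- function(or, state) {
  si <- match(state, or$states)
  cnt <- apply(or$opt, 1L, function(a)
    sum(a[or$edge[, 2L]] == si & a[or$edge[, 1L]] != si) + (a[or$root] == si))
  c(min(cnt), max(cnt))
}

# full MPR-machinery-vs-oracle comparison for one instance
expect_matches_oracle <- function(tree, cm, char = "trait", cost = NULL) {
  or <- oracle_enumerate(tree, cm, char, cost = cost)
  fit <- ancestral_parsimony(tree, cm, char, cost = cost)
  expect_equal(min_changes(fit), or$min)
  expect_equal(lapply(unname(node_states(fit)), sort), or$node_sets)
  sts <- fit$character$states
  for (s in sts)
    expect_equal(unname(count_origins(fit, s)), oracle_origin_interval(or, s))
  pair <- expand.grid(from = sts, to = sts, stringsAsFactors = FALSE)
  pair <- pair[pair$from != pair$to, ]
  for (i in seq_len(nrow(pair)))
    expect_equal(unname(count_transitions(fit, pair$from[i], pair$to[i])),
                 oracle_transition_interval(or, pair$from[i], pair$to[i]))
  # MPR sets identical (as sets of full assignments)
  mp <- enumerate_mprs(fit, limit = 100000L)
  expect_false(mp$truncated)
  mine <- sort(apply(mp$assignments, 1L, paste, collapse = "\r"))
  theirs <- sort(apply(matrix(or$states[or$opt], nrow(or$opt)), 1L,
                       paste, collapse = "\r"))
  expect_equal(mine, theirs)
  invisible(fit)
}
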