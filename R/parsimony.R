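#' Parsimony ancestral-state reconstruction
#'
#' Fits a minimum-change (maximum parsimony) reconstruction of a categorical
#' character on a rooted, possibly multifurcating tree.  Unordered characters
#' use unit change costs; a custom cost matrix (e.g. a loss-biased model for
#' cirral counts) switches the dynamic programme to general Sankoff costs.
#' Polytomies are treated as hard multifurcations and handled exactly by the
#' DP; under unit costs the result is cross-checked internally against a
#' Hartigan-style set computation, the generalization of Fitch's algorithm
#' to multifurcating trees.
#'
#' Missing tips ("?" cells) are allowed every state at zero cost and so
#' contribute no constraint.  Polymorphic tips (state sets) behave as tips
#' whose allowed set is the given set.  The root carries no state prior: the
#' reconstruction cost is the minimum over root states.
#'
#' @param tree a rooted \code{phylo} (polytomies allowed).
#' @param data a \code{\link{char_matrix}} covering the tree's tips.
#' @param character name of the character to reconstruct.
#' @param cost optional cost matrix overriding the character's cost model.
#' @return an object of class \code{ancestral_parsimony} with elements
#'   \code{min_changes}, \code{root_states}, \code{node_states} (per-node
#'   state sets appearing in at least one most-parsimonious reconstruction),
#'   plus the DP tables reused by \code{\link{count_transitions}},
#'   \code{\link{count_origins}} and \code{\link{enumerate_mprs}}.
#' @seealso \code{\link{event_summary}}, \code{\link{count_min_changes}}
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' m <- char_matrix(matrix(c("0","0","1","1"), 4, 1,
#'                         dimnames = list(c("A","B","C","D"), "trait")))
#' fit <- ancestral_parsimony(tr, m, "trait")
#' min_changes(fit)       # 1
#' root_states(fit)       # both states optimal at the root
#' @export
ancestral_parsimony <- function(tree, data, character, cost = NULL) {
  validate_tree(tree)
  stopifnot(inherits(data, "char_matrix"))
  def <- data$characters[[character]]
  if (is.null(def)) stop("character not found: ", character)
  allowed <- .allowed_states(data, tree, character)
  k <- length(def$states)
  if (is.null(cost)) cost <- def$cost
  unit <- is.null(cost)
  if (unit) {
    cost <- matrix(1, k, k) - diag(k)
    dimnames(cost) <- list(def$states, def$states)
  } else {
    cost <- as.matrix(cost)
    if (nrow(cost) != k || ncol(cost) != k)
      stop("cost matrix must be ", k, "x", k)
  }

  eng <- .sankoff_down(tree, allowed, cost)
  min_changes <- min(eng$M[eng$root, ])
  if (unit) {
    hart <- .hartigan_count(tree, allowed)
    if (hart != min_changes)
      stop("internal error: Hartigan/Fitch count (", hart,
           ") disagrees with Sankoff minimum (", min_changes, ")")
  }
  reach <- .mpr_reachable(tree, eng, cost)
  states <- def$states
  node_states <- lapply(seq_len(eng$n_all), function(v) states[reach[v, ]])
  names(node_states) <- .node_ids(tree)

  structure(list(
    character = def, tree = tree, cost = cost, unit_cost = unit,
    allowed = allowed, min_changes = min_changes,
    root = eng$root, n_tip = length(tree$tip.label),
    M = eng$M, postorder = eng$post,
    reachable = reach,
    root_states = states[reach[eng$root, ]],
    node_states = node_states,
    call = match.call()), class = "ancestral_parsimony")
}

# node identifiers: tip labels for tips, "node<k>" (ape numbering) otherwise
.node_ids <- function(tree) {
  n_tip <- length(tree$tip.label)
  c(tree$tip.label, paste0("node", (n_tip + 1L):(n_tip + tree$Nnode)))
}

# Sankoff down-pass: M[v, s] = minimal cost of the subtree rooted at v
# given v is assigned state s.
.sankoff_down <- function(tree, allowed, cost) {
  n_tip <- nrow(allowed)
  n_all <- n_tip + tree$Nnode
  k <- ncol(cost)
  M <- matrix(0, n_all, k)
  M[seq_len(n_tip), ] <- ifelse(allowed, 0, Inf)
  post <- ape::reorder.phylo(tree, "postorder")
  E <- post$edge
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    # contribution of child ch to parent state s: min_t cost[s,t] + M[ch,t]
    tot <- cost + matrix(M[ch, ], k, k, byrow = TRUE)
    M[p, ] <- M[p, ] + apply(tot, 1L, min)
  }
  root <- .tree_root(tree)
  list(M = M, post = post, root = root, n_all = n_all, n_tip = n_tip)
}

# Hartigan (1973) bottom-up count for unit costs on multifurcating trees;
# leaves may carry allowed-state sets (polymorphic or missing tips).
.hartigan_count <- function(tree, allowed) {
  n_tip <- nrow(allowed)
  n_all <- n_tip + tree$Nnode
  k <- ncol(allowed)
  V <- matrix(FALSE, n_all, k)
  V[seq_len(n_tip), ] <- allowed
  post <- ape::reorder.phylo(tree, "postorder")
  E <- post$edge
  votes <- matrix(0L, n_all, k)
  nkids <- integer(n_all)
  changes <- 0L
  # postorder guarantees all children of p are seen before any edge with
  # p as a child; accumulate votes, then finalize p when it first appears
  # as a child (or at the root, after the loop)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    if (ch > n_tip && nkids[ch] > 0L) {
      kmax <- max(votes[ch, ])
      V[ch, ] <- votes[ch, ] == kmax
      changes <- changes + nkids[ch] - kmax
    }
    votes[p, ] <- votes[p, ] + V[ch, ]
    nkids[p] <- nkids[p] + 1L
  }
  root <- .tree_root(tree)
  kmax <- max(votes[root, ])
  changes + nkids[root] - kmax
}

# Top-down reachability: state s is reachable at node v iff v is assigned s
# in at least one most-parsimonious reconstruction.
.mpr_reachable <- function(tree, eng, cost) {
  k <- ncol(cost)
  reach <- matrix(FALSE, eng$n_all, k)
  rootcosts <- eng$M[eng$root, ]
  reach[eng$root, ] <- rootcosts == min(rootcosts)
  E <- eng$post$edge[rev(seq_len(nrow(eng$post$edge))), , drop = FALSE]  # preorder
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    for (s in which(reach[p, ])) {
      vals <- cost[s, ] + eng$M[ch, ]
      reach[ch, vals == min(vals)] <- TRUE
    }
  }
  reach
}

#' @export
print.ancestral_parsimony <- function(x, ...) {
  cat("Parsimony ancestral-state reconstruction\n")
  cat(sprintf("  character : %s (%s)\n", x$character$name,
              paste(x$character$states, collapse = ", ")))
  cat(sprintf("  cost model: %s\n",
              if (x$unit_cost) "unordered (unit costs)" else "custom cost matrix"))
  cat(sprintf("  tips      : %d   minimum changes: %g\n",
              x$n_tip, x$min_changes))
  cat(sprintf("  root state set: {%s}\n", paste(x$root_states, collapse = ", ")))
  invisible(x)
}

#' @export
summary.ancestral_parsimony <- function(object, ...) {
  print(object)
  amb <- sum(vapply(object$node_states[-seq_len(object$n_tip)],
                    function(s) length(s) > 1L, logical(1)))
  cat(sprintf("  internal nodes with ambiguous optimal state: %d of %d\n",
              amb, length(object$node_states) - object$n_tip))
  ev <- event_summary(object)
  cat("  transition occurrence intervals over all MPRs (max > 0 only):\n")
  tr <- ev$transitions[ev$transitions$max > 0, , drop = FALSE]
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr)))
      cat(sprintf("    %s -> %s : [%d, %d]\n", tr$from[i], tr$to[i],
                  tr$min[i], tr$max[i]))
  } else cat("    (none)\n")
  invisible(ev)
}

#' Minimum number of changes of a fitted reconstruction
#' @param fit an \code{ancestral_parsimony} object.
#' @return non-negative number (integer under unit costs).
#' @export
min_changes <- function(fit) {
  stopifnot(inherits(fit, "ancestral_parsimony"))
  fit$min_changes
}

#' One-call minimum change count
#'
#' Convenience wrapper: fit and return the minimum number of character
#' change events on the tree.
#'
#' @inheritParams ancestral_parsimony
#' @return the minimum change count.
#' @export
count_min_changes <- function(tree, data, character, cost = NULL) {
  min_changes(ancestral_parsimony(tree, data, character, cost = cost))
}

#' States optimal at the root
#' @param fit an \code{ancestral_parsimony} object.
#' @return character vector of states achieving the minimum at the root.
#' @export
root_states <- function(fit) {
  stopifnot(inherits(fit, "ancestral_parsimony"))
  fit$root_states
}

#' Per-node optimal state sets
#' @param fit an \code{ancestral_parsimony} object.
#' @return named list: for every node (tip labels, then \code{node<k>}),
#'   the states it takes in at least one most-parsimonious reconstruction.
#' @export
node_states <- function(fit) {
  stopifnot(inherits(fit, "ancestral_parsimony"))
  fit$node_states
}

# Conditional-optimum DP over edge weights: given a 0/1 (or any numeric)
# weight w[s, t] per parent->child state pair and an optional per-root-state
# weight, returns the min and max total weight over all MPRs.
.mpr_weight_interval <- function(fit, w, root_w = NULL) {
  k <- ncol(fit$cost)
  M <- fit$M
  E <- fit$postorder$edge
  fmin <- matrix(0, nrow(M), k)
  fmax <- matrix(0, nrow(M), k)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    for (s in seq_len(k)) {
      vals <- fit$cost[s, ] + M[ch, ]
      best <- which(vals == min(vals))
      fmin[p, s] <- fmin[p, s] + min(w[s, best] + fmin[ch, best])
      fmax[p, s] <- fmax[p, s] + max(w[s, best] + fmax[ch, best])
    }
  }
  rootcosts <- M[fit$root, ]
  opt <- which(rootcosts == min(rootcosts))
  if (is.null(root_w)) root_w <- numeric(k)
  c(min = min(fmin[fit$root, opt] + root_w[opt]),
    max = max(fmax[fit$root, opt] + root_w[opt]))
}

#' Occurrence interval of a specific state-to-state transition
#'
#' Counts, over all most-parsimonious reconstructions, the edges whose
#' parent state is \code{from} and child state is \code{to}, and returns the
#' minimum and maximum count.  Reporting both endpoints mirrors the usual
#' reading of ambiguous reconstructions ("five or six independent
#' occurrences") instead of privileging one arbitrary MPR.
#'
#' @param fit an \code{ancestral_parsimony} object.
#' @param from,to state labels.
#' @return integer vector \code{c(min, max)}.
#' @export
count_transitions <- function(fit, from, to) {
  stopifnot(inherits(fit, "ancestral_parsimony"))
  states <- fit$character$states
  if (!from %in% states) stop("unknown state label: ", from)
  if (!to %in% states) stop("unknown state label: ", to)
  k <- length(states)
  w <- matrix(0, k, k)
  w[match(from, states), match(to, states)] <- 1
  .mpr_weight_interval(fit, w)
}

#' Interval of independent origins of a state
#'
#' An independent origin is a maximal connected set of nodes assigned the
#' state whose parent lineage (or absence of one, at the root) lacks it.
#' Equivalently: the number of edges entering the state from a different
#' state, plus one if the root itself is assigned the state.  The minimum
#' and maximum are taken over all most-parsimonious reconstructions.
#' Missing tips never open a region of their own: at optimum they always
#' copy the parental state.
#'
#' @param fit an \code{ancestral_parsimony} object.
#' @param state a state label.
#' @return integer vector \code{c(min, max)}.
#' @export
count_origins <- function(fit, state) {
  stopifnot(inherits(fit, "ancestral_parsimony"))
  states <- fit$character$states
  if (!state %in% states) stop("unknown state label: ", state)
  k <- length(states)
  idx <- match(state, states)
  w <- matrix(0, k, k)
  w[-idx, idx] <- 1
  root_w <- numeric(k); root_w[idx] <- 1
  .mpr_weight_interval(fit, w, root_w)
}

#' Summarize change events of a reconstruction
#'
#' Tabulates, for every ordered state pair, the interval of occurrence
#' counts over all MPRs, and for every state the interval of independent
#' origins.  Under unit costs the per-MPR transition counts always sum to
#' the minimum change count.
#'
#' @param fit an \code{ancestral_parsimony} object.
#' @return list with \code{character}, \code{total_changes},
#'   \code{transitions} (data.frame from, to, min, max) and \code{origins}
#'   (data.frame state, min, max).
#' @export
event_summary <- function(fit) {
  stopifnot(inherits(fit, "ancestral_parsimony"))
  states <- fit$character$states
  pairs <- expand.grid(to = states, from = states,
                       stringsAsFactors = FALSE)[, c("from", "to")]
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  iv <- t(vapply(seq_len(nrow(pairs)), function(i)
    count_transitions(fit, pairs$from[i], pairs$to[i]), numeric(2)))
  transitions <- data.frame(pairs, min = iv[, 1L], max = iv[, 2L],
                            row.names = NULL, stringsAsFactors = FALSE)
  ov <- t(vapply(states, function(s) count_origins(fit, s), numeric(2)))
  origins <- data.frame(state = states, min = ov[, 1L], max = ov[, 2L],
                        row.names = NULL, stringsAsFactors = FALSE)
  list(character = fit$character$name, total_changes = fit$min_changes,
       transitions = transitions, origins = origins)
}

#' Enumerate most-parsimonious reconstructions
#'
#' Backtracks through the dynamic-programming tables and yields full
#' ancestral assignments (every node, tips included -- ambiguous tips are
#' resolved too) realizing the minimum cost.  Enumeration order is
#' deterministic and lexicographic in (preorder node position, state order).
#' When more than \code{limit} MPRs exist the result is truncated and
#' flagged.
#'
#' @param fit an \code{ancestral_parsimony} object.
#' @param limit maximum number of assignments to return (default 10000).
#' @return list with \code{assignments} (character matrix, one row per MPR,
#'   columns named by node ids), \code{cost}, \code{truncated}.
#' @export
enumerate_mprs <- function(fit, limit = 10000L) {
  stopifnot(inherits(fit, "ancestral_parsimony"))
  if (limit < 1L) stop("limit must be >= 1")
  k <- ncol(fit$cost)
  M <- fit$M
  n_all <- nrow(M)
  E <- fit$postorder$edge[rev(seq_len(nrow(fit$postorder$edge))), ,
                          drop = FALSE]  # preorder
  rootcosts <- M[fit$root, ]
  root_opts <- which(rootcosts == min(rootcosts))
  A <- matrix(NA_integer_, nrow = length(root_opts), ncol = n_all)
  A[, fit$root] <- root_opts
  truncated <- FALSE
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    # per distinct parent state, child options achieving the optimum
    opts_by_s <- lapply(seq_len(k), function(s) {
      vals <- fit$cost[s, ] + M[ch, ]
      which(vals == min(vals))
    })
    reps <- lengths(opts_by_s)[A[, p]]
    newA <- A[rep(seq_len(nrow(A)), times = reps), , drop = FALSE]
    newA[, ch] <- unlist(opts_by_s[A[, p]])
    if (nrow(newA) > limit) {
      newA <- newA[seq_len(limit), , drop = FALSE]
      truncated <- TRUE
    }
    A <- newA
  }
  states <- fit$character$states
  out <- matrix(states[A], nrow(A), n_all,
                dimnames = list(NULL, .node_ids(fit$tree)))
  list(assignments = out, cost = fit$min_changes, truncated = truncated)
}
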