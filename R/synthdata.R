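# Seeded generators used to test the reconstruction, biogeography and
# identification machinery without any external data.  All generators are
# pure functions of (arguments, seed): the RNG state of the session is
# saved and restored around every call.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a per-replicate seed from a master seed
#'
#' Fixed arithmetic (documented so ports in other languages can reproduce
#' the replicate structure, though not the R streams):
#' \code{(master * 7919 + 1009 * i) mod (2^31 - 1)}.
#'
#' @param master master seed (integer).
#' @param i replicate index (1-based).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + 1009 * as.numeric(i)) %% 2147483647)
}

#' Simulate a Yule (pure-birth) tree
#'
#' Binary rooted tree with \code{n_tips} labelled tips (\code{t1..tn}),
#' exponential branch lengths under a constant birth rate.  Byte-identical
#' output under a fixed seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per unit time (default 1).
#' @param seed integer seed, or \code{NULL} to use the session RNG.
#' @return a \code{phylo} object.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  .with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    validate_tree(tr)
    tr
  })
}

#' Evolve a categorical character along a tree with a known true history
#'
#' Starting from a root state, the character changes along each branch
#' either with a fixed per-edge probability (\code{mode = "per-edge"}: at
#' most one switch to a uniformly chosen different state -- simple and
#' sufficient for parsimony lower-bound checks) or as a continuous-time
#' Markov jump process with rate \code{rate} per unit branch length
#' (\code{mode = "ctmc"}).  Both the observable tip states and the latent
#' true event list are returned, so the number of true events can be
#' compared with the parsimony minimum (which can never exceed it).
#'
#' @param tree a rooted \code{phylo}.
#' @param states character vector of state labels (>= 2).
#' @param p_change per-edge change probability (per-edge mode).
#' @param seed integer seed or \code{NULL}.
#' @param root_state starting state (default: first of \code{states}).
#' @param mode \code{"per-edge"} (default) or \code{"ctmc"}.
#' @param rate jump rate for ctmc mode (events per unit branch length).
#' @return list with \code{tip_states} (named character vector),
#'   \code{node_states} (all nodes, ape numbering), \code{events}
#'   (data.frame parent, child, from, to), \code{n_events},
#'   \code{root_state}.
#' @export
evolve_character <- function(tree, states, p_change = 0.1, seed = NULL,
                             root_state = NULL, mode = c("per-edge", "ctmc"),
                             rate = 1) {
  mode <- match.arg(mode)
  validate_tree(tree)
  states <- as.character(states)
  if (length(states) < 2L) stop("need >= 2 states")
  if (p_change < 0 || p_change > 1) stop("p_change must be in [0, 1]")
  if (is.null(root_state)) root_state <- states[1L]
  if (!root_state %in% states) stop("root_state not in states")
  .with_seed(seed, {
    n_tip <- length(tree$tip.label)
    n_all <- n_tip + tree$Nnode
    node_states <- character(n_all)
    root <- .tree_root(tree)
    node_states[root] <- root_state
    E <- ape::reorder.phylo(tree, "postorder")$edge
    E <- E[rev(seq_len(nrow(E))), , drop = FALSE]  # preorder
    blen <- if (!is.null(tree$edge.length)) {
      bl <- numeric(n_all); bl[tree$edge[, 2L]] <- tree$edge.length; bl
    } else rep(1, n_all)
    ev <- list()
    for (e in seq_len(nrow(E))) {
      p <- E[e, 1L]; ch <- E[e, 2L]
      cur <- node_states[p]
      n_jump <- if (mode == "per-edge") as.integer(stats::runif(1) < p_change)
                else stats::rpois(1, rate * blen[ch])
      for (j in seq_len(n_jump)) {
        nxt <- sample(setdiff(states, cur), 1L)
        ev[[length(ev) + 1L]] <- data.frame(parent = p, child = ch,
                                            from = cur, to = nxt,
                                            stringsAsFactors = FALSE)
        cur <- nxt
      }
      node_states[ch] <- cur
    }
    events <- if (length(ev)) do.call(rbind, ev)
              else data.frame(parent = integer(0), child = integer(0),
                              from = character(0), to = character(0),
                              stringsAsFactors = FALSE)
    tips <- node_states[seq_len(n_tip)]
    names(tips) <- tree$tip.label
    list(tip_states = tips, node_states = node_states, events = events,
         n_events = nrow(events), root_state = root_state)
  })
}

#' Simulate a measured specimen from a species profile
#'
#' Emulates morphometric measurement of a cell: numeric traits are drawn
#' uniformly within the profile's interval and jittered with multiplicative
#' Gaussian noise of relative standard deviation \code{noise}; categorical
#' traits are sampled from the profile's state set.  At \code{noise = 0}
#' every numeric value lies inside the interval.
#'
#' @param profile a \code{\link{species_profile}}.
#' @param noise relative standard deviation of measurement noise
#'   (default 0).
#' @param seed integer seed or \code{NULL}.
#' @return named list of measured values (a specimen, as accepted by
#'   \code{\link{identify_specimen}}).
#' @export
simulate_specimen <- function(profile, noise = 0, seed = NULL) {
  stopifnot(inherits(profile, "species_profile"))
  num <- Filter(function(t) is.numeric(t), profile$traits)
  if (!length(num)) stop("profile has no numeric trait")
  .with_seed(seed, {
    out <- list()
    for (tn in names(profile$traits)) {
      tr <- profile$traits[[tn]]
      if (is.null(tr)) next
      if (is.numeric(tr)) {
        v <- stats::runif(1, tr[1L], tr[2L])
        if (noise > 0) v <- v * (1 + stats::rnorm(1, 0, noise))
        out[[tn]] <- max(v, 0)
      } else {
        out[[tn]] <- if (length(tr) == 1L) tr else sample(tr, 1L)
      }
    }
    out
  })
}
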