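quartet <- function() read_newick("((A,B),(C,D));")

test_that("uniform characters need zero changes and a single MPR", {
  tr <- quartet()
  cm <- tiny_cm(c(A = "x", B = "x", C = "x", D = "x"), c("x", "y"))
  fit <- ancestral_parsimony(tr, cm, "trait")
  expect_equal(min_changes(fit), 0)
  expect_true(all(vapply(node_states(fit), identical, logical(1), "x")))
  mp <- enumerate_mprs(fit)
  expect_equal(nrow(mp$assignments), 1L)
  ev <- event_summary(fit)
  expect_true(all(ev$transitions$max == 0))
})

test_that("the (0,0,1,1) quartet has one change, ambiguous root, two MPRs", {
  tr <- quartet()
  cm <- tiny_cm(c(A = "0", B = "0", C = "1", D = "1"), c("0", "1"))
  fit <- ancestral_parsimony(tr, cm, "trait")
  expect_equal(min_changes(fit), 1)
  expect_equal(sort(root_states(fit)), c("0", "1"))
  mp <- enumerate_mprs(fit)
  expect_equal(nrow(mp$assignments), 2L)
  expect_equal(unname(count_transitions(fit, "0", "1")), c(0, 1))
  expect_equal(unname(count_transitions(fit, "1", "0")), c(0, 1))
})

test_that("a two-state cherry admits exactly two MPRs", {
  tr <- read_newick("(A,B);")
  cm <- tiny_cm(c(A = "0", B = "1"), c("0", "1"))
  fit <- ancestral_parsimony(tr, cm, "trait")
  expect_equal(min_changes(fit), 1)
  expect_equal(nrow(enumerate_mprs(fit)$assignments), 2L)
})

test_that("cherries separated along a backbone originate independently", {
  # two derived cherries at opposite ends of an 8-tip pectinate backbone:
  # joining them through the spine would cost four extra changes, so every
  # MPR keeps two separate origins
  tr <- read_newick("((((((A,B),X1),X2),X3),X4),(G,H));")
  st <- c(A = "1", B = "1", X1 = "0", X2 = "0", X3 = "0", X4 = "0",
          G = "1", H = "1")
  cm <- tiny_cm(st, c("0", "1"))
  fit <- ancestral_parsimony(tr, cm, "trait")
  or <- oracle_enumerate(tr, cm, "trait")
  expect_equal(unname(count_origins(fit, "1")),
               oracle_origin_interval(or, "1"))
  expect_gte(count_origins(fit, "1")[1L], 2)
  # a state observed at no tip never originates
  cm2 <- tiny_cm(setNames(rep("0", 8), names(st)), c("0", "1"))
  fit2 <- ancestral_parsimony(tr, cm2, "trait")
  expect_equal(unname(count_origins(fit2, "1")), c(0, 0))
})

test_that("DP machinery equals exhaustive enumeration on random instances", {
  set.seed(101)
  for (i in 1:60) {
    k <- sample(2:3, 1)
    tr <- random_poly_tree(sample(4:6, 1))
    cm <- random_char_column(tr, k = k,
                             p_missing = ifelse(i %% 3 == 0, 0.2, 0),
                             p_poly = ifelse(i %% 4 == 0, 0.2, 0))
    expect_matches_oracle(tr, cm)
  }
})

test_that("custom (Sankoff) cost matrices are honoured and match the oracle", {
  set.seed(55)
  cost <- matrix(c(0, 1, 3,
                   2, 0, 1,
                   5, 2, 0), 3, 3, byrow = TRUE)
  for (i in 1:20) {
    tr <- random_poly_tree(sample(4:6, 1))
    cm <- random_char_column(tr, k = 3)
    or <- oracle_enumerate(tr, cm, "trait", cost = cost)
    fit <- ancestral_parsimony(tr, cm, "trait", cost = cost)
    expect_equal(min_changes(fit), or$min)
    expect_equal(lapply(unname(node_states(fit)), sort), or$node_sets)
  }
  # loss-only model forbids cheap regains
  tr <- read_newick("((A,B),(C,D));")
  cm <- tiny_cm(c(A = "10", B = "8", C = "10", D = "10"), c("8", "10"))
  fit <- ancestral_parsimony(tr, cm, "trait",
                             cost = loss_cost_matrix(c("8", "10")))
  expect_equal(min_changes(fit), 1)
  expect_equal(root_states(fit), "10")
})

test_that("Sankoff with unit costs reproduces the Hartigan/Fitch count", {
  # the fit itself cross-checks internally (it errors on disagreement);
  # run it across many random multifurcating instances
  set.seed(202)
  for (i in 1:1000) {
    tr <- random_poly_tree(sample(3:15, 1))
    cm <- random_char_column(tr, k = sample(2:4, 1),
                             p_missing = 0.1, p_poly = 0.1)
    fit <- ancestral_parsimony(tr, cm, "trait")
    expect_gte(min_changes(fit), 0)
  }
})

test_that("parsimony score agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(77)
  for (i in 1:40) {
    tr <- ape::rtree(sample(4:12, 1))
    cm <- random_char_column(tr, k = sample(2:4, 1))
    states <- cm$characters$trait$states
    vec <- vapply(tr$tip.label, function(t)
      cm$cells[[match(t, cm$taxa), 1L]], character(1))
    pd <- phangorn::phyDat(matrix(vec, ncol = 1,
                                  dimnames = list(tr$tip.label, NULL)),
                           type = "USER", levels = states)
    expect_equal(count_min_changes(tr, cm, "trait"),
                 as.numeric(phangorn::parsimony(tr, pd, method = "fitch")))
  }
  # and on the multifurcating fixture, via the sankoff variant
  ftr <- load_fixture("species_tree")
  fcm <- load_fixture("characters")
  for (ch in c("dargyrome_type", "FVC_count")) {
    def <- fcm$characters[[ch]]
    vec <- vapply(ftr$tip.label, function(t) {
      s <- fcm$cells[[match(t, fcm$taxa), match(ch, names(fcm$characters))]]
      if (is.null(s)) "?" else s[1L]  # phangorn has no set cells; use first
    }, character(1))
    pd <- phangorn::phyDat(matrix(vec, ncol = 1,
                                  dimnames = list(ftr$tip.label, NULL)),
                           type = "USER", levels = def$states,
                           ambiguity = "?")
    k <- length(def$states)
    ps <- phangorn::parsimony(ftr, pd, method = "sankoff",
                              cost = matrix(1, k, k) - diag(k))
    expect_equal(count_min_changes(ftr, fcm, ch), as.numeric(ps))
  }
})

test_that("adding a tip never decreases the minimum change count", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:9, 1)
    tr <- ape::rtree(n)
    cm <- random_char_column(tr, k = 3)
    base <- count_min_changes(tr, cm, "trait")
    # graft one new tip next to a random existing tip, with a random state
    tr$edge.length <- NULL
    tip <- sample(tr$tip.label, 1)
    nwk2 <- sub(paste0("([(,])", tip, "([:,)])"),
                paste0("\\1(", tip, ",NEW)\\2"), write_newick(tr))
    tr2 <- read_newick(nwk2)
    states <- cm$characters$trait$states
    enc <- vapply(tr$tip.label, function(t)
      paste(cm$cells[[match(t, cm$taxa), 1L]], collapse = "|"), character(1))
    enc <- c(enc, NEW = sample(states, 1))
    m <- matrix(enc[tr2$tip.label], ncol = 1,
                dimnames = list(tr2$tip.label, "trait"))
    cm2 <- char_matrix(m, characters = cm$characters)
    expect_gte(count_min_changes(tr2, cm2, "trait"), base)
  }
})

test_that("enumeration respects the cap and flags truncation", {
  tr <- quartet()
  cm <- tiny_cm(c(A = "0", B = "0", C = "1", D = "1"), c("0", "1"))
  fit <- ancestral_parsimony(tr, cm, "trait")
  full <- enumerate_mprs(fit, limit = 100000L)
  expect_false(full$truncated)
  expect_gt(nrow(full$assignments), 1L)
  cap <- nrow(full$assignments) - 1L
  capped <- enumerate_mprs(fit, limit = cap)
  expect_true(capped$truncated)
  expect_equal(nrow(capped$assignments), cap)
  expect_error(enumerate_mprs(fit, limit = 0L), "limit")
  # enumeration is deterministic
  again <- enumerate_mprs(fit, limit = cap)
  expect_identical(capped$assignments, again$assignments)
})

test_that("errors name the offending character, state or taxa", {
  tr <- quartet()
  cm <- tiny_cm(c(A = "0", B = "0", C = "1", D = "1"), c("0", "1"))
  expect_error(ancestral_parsimony(tr, cm, "nope"), "character not found")
  fit <- ancestral_parsimony(tr, cm, "trait")
  expect_error(count_transitions(fit, "0", "2"), "unknown state")
  expect_error(count_origins(fit, "2"), "unknown state")
  cm3 <- tiny_cm(c(A = "0", B = "0", C = "1"), c("0", "1"))
  expect_error(ancestral_parsimony(tr, cm3, "trait"),
               "validate_against_tree")
})

test_that("print and summary surface the fit in readable form", {
  tr <- quartet()
  cm <- tiny_cm(c(A = "0", B = "0", C = "1", D = "1"), c("0", "1"))
  fit <- ancestral_parsimony(tr, cm, "trait")
  expect_output(print(fit), "minimum changes: 1")
  expect_output(print(fit), "root state set: \\{0, 1\\}")
  ev <- expect_output(summary(fit), "transition occurrence intervals")
  expect_equal(ev$total_changes, 1)
})
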