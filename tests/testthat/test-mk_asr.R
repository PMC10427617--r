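test_that("rate matrices honor each constraint pattern", {
  er <- rate_model_spec("ER", states = c("0", "1"))
  Q <- build_rate_matrix(er, 0.5)
  expect_equal(unname(Q), matrix(c(-0.5, 0.5, 0.5, -0.5), 2),
               ignore_attr = TRUE)

  ard3 <- rate_model_spec("ARD", states = c("a", "b", "c"))
  expect_identical(ard3$n_free, 6L)
  Qa <- build_rate_matrix(ard3, 1:6 / 10)
  expect_equal(unname(rowSums(Qa)), rep(0, 3))
  expect_identical(Qa["a", "b"], 0.1)
  expect_identical(Qa["c", "b"], 0.6)

  sym3 <- rate_model_spec("SYM", states = c("a", "b", "c"))
  Qs <- build_rate_matrix(sym3, c(0.1, 0.2, 0.3))
  expect_equal(Qs["a", "b"], Qs["b", "a"])
  expect_equal(Qs["b", "c"], Qs["c", "b"])

  prec <- rate_model_spec("PREC")
  Qp <- build_rate_matrix(prec, c(0.05, 0.02, 0.1, 0.05))
  expect_identical(Qp["absent", "used"], 0)
  expect_identical(Qp["used", "absent"], 0)
  expect_equal(unname(rowSums(Qp)), rep(0, 3))

  expect_error(build_rate_matrix(er, c(1, 2)), "expected 1")
  expect_error(build_rate_matrix(er, -1), "non-negative")
})

test_that("transition matrix matches closed forms and limits", {
  er <- rate_model_spec("ER", states = c("0", "1"))
  Q <- build_rate_matrix(er, 0.3)
  expect_equal(transition_matrix(Q, 0), diag(2), ignore_attr = TRUE)
  # 2-state ER: P_stay(t) = 1/2 + 1/2 exp(-2qt)
  for (t in c(0.1, 1, 5)) {
    P <- transition_matrix(Q, t)
    expect_equal(P[1, 1], 0.5 + 0.5 * exp(-2 * 0.3 * t), tolerance = 1e-12)
    expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-12)
  }
  # long-run ER limit is uniform
  ard <- rate_model_spec("ER", states = letters[1:4])
  Q4 <- build_rate_matrix(ard, 1)
  P_inf <- transition_matrix(Q4, 50)
  expect_equal(unname(P_inf), matrix(0.25, 4, 4), tolerance = 1e-9)
})

test_that("pruning equals brute-force enumeration on all patterns, <= 6 tips", {
  set.seed(10)
  for (n in c(3, 5, 6)) {
    tree <- ape::rphylo(n, 1, 0)
    for (pat in c("ER", "SYM", "ARD", "PREC")) {
      spec <- if (pat == "PREC") prec_spec()
              else rate_model_spec(pat, states = c("x", "y", "z"))
      Q <- build_rate_matrix(spec, runif(spec$n_free, 0.05, 0.6))
      syms <- names(spec$observation_map)
      tips <- setNames(sample(syms, n, replace = TRUE), tree$tip.label)
      for (rp in c("flat", "stationary")) {
        expect_equal(
          pruning_loglik(tree, tips, Q, spec, root_prior = rp),
          brute_force_loglik(tree, tips, Q, spec, root_prior = rp),
          tolerance = 1e-10)
      }
    }
  }
})

test_that("all-ambiguous tips give likelihood exactly 1", {
  tree <- random_yule(12, seed = 3)
  spec <- prec_spec()
  Q <- build_rate_matrix(spec, c(0.4, 0.1, 0.2, 0.3))
  tips <- setNames(rep("?", 12), tree$tip.label)
  expect_equal(pruning_loglik(tree, tips, Q, spec), 0, tolerance = 1e-12)
})

test_that("two-tip likelihood matches the direct analytic sum", {
  tree <- ape::read.tree(text = "(A:0.7,B:1.3);")
  spec <- rate_model_spec("ARD", states = c("0", "1"))
  Q <- build_rate_matrix(spec, c(0.4, 0.9))
  tips <- c(A = "0", B = "1")
  P1 <- transition_matrix(Q, 0.7)
  P2 <- transition_matrix(Q, 1.3)
  direct <- log(sum(0.5 * P1[, "0"] * P2[, "1"]))
  expect_equal(pruning_loglik(tree, tips, Q, spec), direct,
               tolerance = 1e-12)
})

test_that("likelihood is invariant to tip order and zero-branch contraction", {
  tree <- random_yule(10, seed = 8)
  spec <- prec_spec()
  Q <- build_rate_matrix(spec, c(0.3, 0.1, 0.5, 0.2))
  set.seed(2)
  tips <- setNames(sample(c("0", "1"), 10, TRUE), tree$tip.label)
  ll <- pruning_loglik(tree, tips, Q, spec)
  # permuted storage order of the data
  expect_equal(pruning_loglik(tree, sample(tips), Q, spec), ll,
               tolerance = 1e-12)
  # rotating the tree (ladderize) relabels edges but not the likelihood
  expect_equal(pruning_loglik(ape::ladderize(tree), tips, Q, spec), ll,
               tolerance = 1e-12)
  # inserting a zero-length branch above a tip changes nothing
  tree0 <- tree
  i <- which(tree0$edge[, 2] == 1)
  tree0 <- phytools::bind.tip(tree0, "tmp", edge.length = 1e-9,
                              where = 1, position = 0)
  tree0 <- ape::drop.tip(tree0, "tmp")
  expect_equal(pruning_loglik(tree0, tips, Q, spec), ll, tolerance = 1e-8)
})

test_that("pruning likelihood agrees with phytools::fitMk machinery", {
  # independent implementation cross-check (custom rate-index matrix for
  # the precursor constraints)
  tree <- random_yule(40, seed = 12)
  set.seed(13)
  tips <- setNames(sample(c("0", "1"), 40, TRUE, prob = c(0.6, 0.4)),
                   tree$tip.label)
  spec <- prec_spec()
  rates <- c(0.07, 0.03, 0.12, 0.04)
  Q <- build_rate_matrix(spec, rates)
  ours <- pruning_loglik(tree, tips, Q, spec, root_prior = "flat")
  X <- pedex:::tip_likelihoods(tree, tips, spec)
  model <- matrix(c(0, 1, 0, 2, 0, 3, 0, 4, 0), 3, 3, byrow = TRUE)
  theirs <- phytools::fitMk(tree, X, model = model, fixedQ = Q, pi = "equal")
  expect_equal(ours, theirs$logLik, tolerance = 1e-8)
})

test_that("marginal posteriors equal brute-force conditionals", {
  set.seed(30)
  for (rep in 1:3) {
    tree <- ape::rphylo(4, 1, 0)
    spec <- prec_spec()
    Q <- build_rate_matrix(spec, runif(4, 0.05, 0.6))
    tips <- setNames(sample(c("0", "1", "?"), 4, TRUE, prob = c(.4, .4, .2)),
                     tree$tip.label)
    rec <- marginal_asr(tree, tips, Q, spec, root_prior = "flat")
    brute <- brute_force_marginals(tree, tips, Q, spec)
    expect_equal(unname(rec$posterior), unname(brute), tolerance = 1e-10)
    expect_equal(unname(rowSums(rec$posterior)),
                 rep(1, nrow(rec$posterior)), tolerance = 1e-9)
  }
})

test_that("tip posteriors respect unambiguous observations and root Bayes rule", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  spec <- rate_model_spec("ARD", states = c("0", "1"))
  Q <- build_rate_matrix(spec, c(0.3, 0.6))
  tips <- c(A = "1", B = "0", C = "0")
  rec <- marginal_asr(tree, tips, Q, spec, root_prior = "flat")
  expect_equal(unname(rec$posterior[match("A", tree$tip.label), "1"]), 1)
  expect_equal(unname(rec$posterior[match("B", tree$tip.label), "0"]), 1)
  # under a flat prior the root posterior is proportional to root partials
  Ltips <- pedex:::tip_likelihoods(tree, tips, spec)
  pr <- pedex:::pruning_pass(tree, Ltips, Q)
  expect_equal(unname(rec$posterior[4, ]),
               unname(pr$part[4, ] / sum(pr$part[4, ])), tolerance = 1e-12)
})

test_that("collapsed observation map sums hidden-state partials", {
  # a "0" tip under PREC contributes the sum of absent+precursor paths:
  # its likelihood must equal the sum of the two unambiguous versions
  tree <- random_yule(5, seed = 40)
  spec <- prec_spec()
  full <- rate_model_spec("PREC", observation_map = list(
    "A" = "absent", "P" = "precursor", "1" = "used"))
  Q <- build_rate_matrix(spec, c(0.2, 0.1, 0.4, 0.3))
  tips <- setNames(c("0", "1", "1", "0", "1"), tree$tip.label)
  tipsA <- tipsP <- setNames(c("A", "1", "1", "0", "1"), tree$tip.label)
  tipsA[1] <- "A"; tipsP[1] <- "P"
  # make tip 4 unambiguous in the comparison runs so only tip 1 collapses
  tipsA[4] <- tipsP[4] <- "0"
  full$observation_map[["0"]] <- c("absent", "precursor")
  lik_col <- exp(pruning_loglik(tree, tips, Q, spec))
  likA <- exp(pruning_loglik(tree, tipsA, Q, full))
  likP <- exp(pruning_loglik(tree, tipsP, Q, full))
  expect_equal(lik_col, likA + likP, tolerance = 1e-12)
})

test_that("fit_mk maximizes the likelihood and reports AIC by definition", {
  spec <- rate_model_spec("ER", states = c("0", "1"))
  q_true <- 0.1
  tree <- simulate_tree(300, seed = 50)
  Q <- build_rate_matrix(spec, q_true)
  h <- simulate_character(tree, Q, "0", seed = 51)
  tips <- observe_states(h$tip_states, spec)
  fit <- fit_mk(tree, tips, spec, restarts = 4, seed = 1)
  expect_gte(fit$loglik, pruning_loglik(tree, tips, Q, spec) - 1e-6)
  expect_identical(fit$aic, 2 * fit$n_free - 2 * fit$loglik)
  expect_true(fit$converged)

  # invariant data warn
  flat_tips <- setNames(rep("0", 300), tree$tip.label)
  expect_warning(fit_mk(tree, flat_tips, spec, restarts = 1, seed = 1),
                 "invariant")
})

test_that("ER rate recovery is within a factor of two most of the time", {
  spec <- rate_model_spec("ER", states = c("0", "1"))
  q_true <- 0.1
  ok <- 0L
  for (r in 1:10) {
    tree <- simulate_tree(300, seed = 500 + r)
    Q <- build_rate_matrix(spec, q_true)
    h <- simulate_character(tree, Q, sample(c("0", "1"), 1), seed = 600 + r)
    tips <- observe_states(h$tip_states, spec)
    fit <- fit_mk(tree, tips, spec, restarts = 3, seed = r)
    ok <- ok + (fit$rates >= q_true / 2 && fit$rates <= q_true * 2)
  }
  expect_gte(ok, 9L)
})

test_that("fitted ER rate matches phytools::fitMk estimate", {
  spec <- rate_model_spec("ER", states = c("0", "1"))
  tree <- simulate_tree(150, seed = 70)
  Q <- build_rate_matrix(spec, 0.08)
  h <- simulate_character(tree, Q, "0", seed = 71)
  tips <- observe_states(h$tip_states, spec)
  ours <- fit_mk(tree, tips, spec, restarts = 4, seed = 2)
  theirs <- phytools::fitMk(tree, tips[tree$tip.label], model = "ER",
                            pi = "equal")
  expect_equal(ours$loglik, theirs$logLik, tolerance = 1e-4)
  expect_equal(unname(ours$rates), theirs$rates, tolerance = 0.01)
})

test_that("compare_models ranks by AIC and rejects mismatched data", {
  tree <- simulate_tree(100, seed = 80)
  spec_er <- rate_model_spec("ER", states = c("0", "1"))
  Q <- build_rate_matrix(spec_er, 0.1)
  h <- simulate_character(tree, Q, "0", seed = 81)
  tips <- observe_states(h$tip_states, spec_er)
  f_er <- fit_mk(tree, tips, spec_er, restarts = 3, seed = 1)
  f_ard <- fit_mk(tree, tips, rate_model_spec("ARD", states = c("0", "1")),
                  restarts = 3, seed = 1)
  cmp <- compare_models(f_er, f_ard)
  expect_identical(cmp$delta_aic[1], 0)
  expect_true(all(diff(cmp$aic) >= 0))
  # with near-identical logL the 1-parameter model must win
  if (abs(f_er$loglik - f_ard$loglik) < 0.5) {
    expect_identical(cmp$model[1], "ER")
  }
  expect_identical(nrow(compare_models(list(f_er))), 1L)

  other <- tips
  other[1] <- if (other[1] == "0") "1" else "0"
  f_bad <- fit_mk(tree, other, spec_er, restarts = 2, seed = 1)
  expect_error(compare_models(f_er, f_bad), "identical tree")
})

test_that("transition counting matches event logs and handles chains", {
  # counting on true simulated node states reproduces logged P->U events
  spec <- prec_spec()
  Q <- build_rate_matrix(spec, c(0.05, 0.02, 0.1, 0.05))
  tree <- simulate_tree(200, seed = 90)
  h <- simulate_character(tree, Q, "precursor", seed = 91)
  truth <- pedex:::true_transition_counts(h, derived = "used")
  oc <- count_transitions(h$node_states, tree = h$tree, derived = "used")
  # node-state boundaries undercount multiple hits on one branch, never over
  expect_lte(oc$gains, truth$gains)
  expect_lte(oc$losses, truth$losses)
  # on branches with at most one event the counts are exact
  per_edge <- table(factor(h$events$edge, levels = seq_len(nrow(h$tree$edge))))
  if (all(per_edge <= 1)) {
    expect_identical(oc$gains, truth$gains)
    expect_identical(oc$losses, truth$losses)
  }

  # all-same states: nothing to count
  flat <- rep("used", ape::Ntip(tree) + tree$Nnode)
  oc0 <- count_transitions(flat, tree = tree, derived = "used")
  expect_identical(oc0$gains + oc0$losses, 0L)

  # A - P - U chain along a path: exactly one gain at the P->U boundary
  chain <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  st <- c("used", "used", "absent", "absent", "precursor")
  oc1 <- count_transitions(st, tree = chain, derived = "used")
  expect_identical(oc1$gains, 2L)  # both t1 and t2 branches cross P->U
  st2 <- c("used", "precursor", "absent", "absent", "precursor")
  oc2 <- count_transitions(st2, tree = chain, derived = "used")
  expect_identical(oc2$gains, 1L)
  expect_identical(oc2$losses, 0L)
  expect_identical(nrow(transition_table(oc2)), 1L)
})

test_that("posterior ties at one half resolve to the non-derived state", {
  rec <- structure(list(
    tree = ape::read.tree(text = "(A:1,B:1);"),
    posterior = rbind(c(0, 1), c(1, 0), c(0.5, 0.5)),
    states = c("absent", "used"),
    map_state = c("used", "absent", "absent"),
    loglik = 0, low_confidence = 3L), class = "ancestral_reconstruction")
  oc <- count_transitions(rec, derived = "used")
  # root tied -> absent; A observed used -> one gain on A's branch
  expect_identical(oc$gains, 1L)
  expect_identical(oc$losses, 0L)
})

test_that("annotated newick export carries per-node posteriors", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  spec <- rate_model_spec("ER", states = c("0", "1"))
  Q <- build_rate_matrix(spec, 0.3)
  rec <- marginal_asr(tree, c(A = "1", B = "0", C = "0"), Q, spec)
  s <- write_annotated_newick(rec)
  expect_match(s, "&&NHX:p_0=")
  expect_match(s, "^\\(")
  # every node annotated: 3 tips + 2 internal
  expect_identical(lengths(regmatches(s, gregexpr("&&NHX", s))), 5L)
})
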