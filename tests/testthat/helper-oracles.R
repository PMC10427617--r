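# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package's algorithms: likelihoods by exhaustive
# enumeration over node-state assignments, clade frequencies by hand
# counting, unions by element-wise OR.

# Exhaustive-enumeration tree likelihood: sums the joint probability over
# every assignment of states to internal nodes and to ambiguous tips.
brute_force_loglik <- function(tree, tip_states, Q, spec,
                               root_prior = "flat") {
  k <- nrow(Q)
  nt <- ape::Ntip(tree)
  N <- nt + tree$Nnode
  L <- pedex:::tip_likelihoods(tree, tip_states, spec)
  Ps <- lapply(seq_len(nrow(tree$edge)),
               function(e) transition_matrix(Q, tree$edge.length[e]))
  prior <- switch(root_prior,
                  flat = rep(1 / k, k),
                  stationary = pedex:::stationary_distribution(Q))
  tip_choices <- lapply(seq_len(nt), function(i) which(L[i, ] == 1))
  int_choices <- rep(list(seq_len(k)), N - nt)
  grid <- expand.grid(c(tip_choices, int_choices))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- unlist(grid[g, ])
    pr <- prior[st[nt + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Ps[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    total <- total + pr
  }
  as.numeric(log(total))
}

# Brute-force marginal posteriors: joint probability accumulated per
# (node, state), normalized row-wise.
brute_force_marginals <- function(tree, tip_states, Q, spec,
                                  root_prior = "flat") {
  k <- nrow(Q)
  nt <- ape::Ntip(tree)
  N <- nt + tree$Nnode
  L <- pedex:::tip_likelihoods(tree, tip_states, spec)
  Ps <- lapply(seq_len(nrow(tree$edge)),
               function(e) transition_matrix(Q, tree$edge.length[e]))
  prior <- switch(root_prior,
                  flat = rep(1 / k, k),
                  stationary = pedex:::stationary_distribution(Q))
  marg <- matrix(0, N, k)
  grid <- expand.grid(rep(list(seq_len(k)), N))
  for (g in seq_len(nrow(grid))) {
    st <- unlist(grid[g, ])
    pr <- prior[st[nt + 1]]
    for (i in seq_len(nt)) pr <- pr * L[i, st[i]]
    if (pr == 0) next
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Ps[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    for (nd in seq_len(N)) marg[nd, st[nd]] <- marg[nd, st[nd]] + pr
  }
  marg / rowSums(marg)
}

# Clade frequencies of a tree sample by direct tip-set counting.
brute_force_clade_freqs <- function(trees) {
  all_sigs <- lapply(trees, function(tr) {
    nt <- ape::Ntip(tr)
    vapply((nt + 1):(nt + tr$Nnode), function(nd) {
      tips <- ape::extract.clade(tr, nd)$tip.label
      paste(sort(tips), collapse = "|")
    }, character(1))
  })
  tab <- table(unlist(all_sigs))
  tab / length(trees)
}

# Small media-record data frame builder for trait-scoring tests.
media_rows <- function(species, ids, ...) {
  flags <- list(...)
  n <- length(ids)
  df <- data.frame(species = rep(species, n), media_id = ids,
                   source = rep("other", n), stringsAsFactors = FALSE)
  for (f in behavior_flags()) {
    df[[f]] <- if (f %in% names(flags)) flags[[f]] else rep(0L, n)
  }
  df
}

# Shared small fixtures for the mk tests.
prec_spec <- function() rate_model_spec("PREC")

random_yule <- function(n, seed) {
  set.seed(seed)
  ape::rphylo(n, birth = 1, death = 0)
}
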