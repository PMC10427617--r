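# Tip likelihood matrix (Ntip x k): row i has 1 on every state compatible
# with tip i's observed symbol under the spec's observation map.
tip_likelihoods <- function(tree, tip_states, spec,
                            missing_as_unknown = FALSE) {
  k <- spec$k
  nt <- ape::Ntip(tree)
  L <- matrix(0, nt, k, dimnames = list(tree$tip.label, spec$states))
  for (i in seq_len(nt)) {
    lab <- tree$tip.label[i]
    sym <- if (lab %in% names(tip_states)) tip_states[[lab]] else NA
    if (is.na(sym)) {
      if (!lab %in% names(tip_states) && !missing_as_unknown) {
        stop("tip ", lab, " has no observed state ",
             "(set missing_as_unknown = TRUE to treat it as ambiguous)")
      }
      sym <- "?"
    }
    sym <- as.character(sym)
    compat <- spec$observation_map[[sym]]
    if (is.null(compat)) {
      stop("symbol \"", sym, "\" at tip ", lab, " is not in the observation map")
    }
    L[i, match(compat, spec$states)] <- 1
  }
  L
}

# Felsenstein post-order pass. Returns scaled per-node partial likelihoods,
# per-node accumulated log scalers, the per-edge P(t) rows, the per-edge
# child-lifted vectors v_e = P_e %*% partial[child], and the postorder tree.
pruning_pass <- function(tree, Ltips, Q) {
  if (!identical(attr(tree, "order"), "postorder")) {
    tree <- ape::reorder.phylo(tree, "postorder")
  }
  nt <- ape::Ntip(tree)
  k <- nrow(Q)
  prop <- make_propagator(Q)
  Pm <- prop(tree$edge.length)           # nedge x k^2, rows vec(P)
  core <- pruning_core(tree$edge, Pm, Ltips, tree$Nnode)
  list(tree = tree, part = core$part, logsc = core$logsc, Pm = Pm,
       vmat = core$vmat, root = nt + 1L, k = k)
}

# Root prior vector under each policy. For "fitzjohn" the prior is the
# normalized root partial itself (each state weighted by its share of the
# data likelihood).
root_prior_vector <- function(policy, Q, root_partial) {
  k <- nrow(Q)
  switch(policy,
    flat = rep(1 / k, k),
    stationary = stationary_distribution(Q),
    fitzjohn = {
      s <- sum(root_partial)
      if (s <= 0) rep(1 / k, k) else root_partial / s
    },
    stop("unknown root prior policy: ", policy)
  )
}

#' Log-likelihood of a discrete character on a tree (Felsenstein pruning)
#'
#' Computes the probability of the observed tip symbols under a CTMC with
#' generator `Q`, by the post-order pruning algorithm with numerical
#' rescaling. Ambiguous tips (including hidden-state observation maps, and
#' the `"?"` symbol) contribute a likelihood of 1 on every compatible
#' state. The root partials are combined with the spec's root prior.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_states Named vector/list of observed symbols keyed by tip
#'   label.
#' @param Q Generator from [build_rate_matrix()].
#' @param spec The [rate_model_spec()] (supplies observation map, states,
#'   and default root prior).
#' @param root_prior Override of `spec$root_prior`.
#' @param missing_as_unknown Treat tips absent from `tip_states` as `"?"`.
#' @return The log-likelihood (a scalar; `-Inf` for impossible data).
#' @export
pruning_loglik <- function(tree, tip_states, Q, spec,
                           root_prior = spec$root_prior,
                           missing_as_unknown = FALSE) {
  Ltips <- tip_likelihoods(tree, tip_states, spec, missing_as_unknown)
  pr <- pruning_pass(tree, Ltips, Q)
  rp <- part_root <- pr$part[pr$root, ]
  prior <- root_prior_vector(root_prior, Q, part_root)
  lik <- sum(prior * part_root)
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logsc[pr$root]
}

#' Marginal ancestral state reconstruction
#'
#' Per-node marginal posterior probabilities of each state given all tip
#' data, computed by combining the post-order (below) partials with a
#' pre-order (above) pass, so each node's posterior integrates over every
#' other node. Tip rows reproduce the tips' compatible-state support:
#' an unambiguous tip has posterior 1 on its state, while a hidden-state
#' tip (e.g. "no foot use" under the precursor model) is apportioned
#' between its compatible states.
#'
#' @inheritParams pruning_loglik
#' @return Object of class `ancestral_reconstruction`: list with `tree`
#'   (postorder), `posterior` (`(Ntip + Nnode) x k` matrix, rows summing to
#'   1, in `ape` node numbering), `states`, `loglik`, `map_state`
#'   (max-posterior state per node, 0.5-ties resolved toward the first /
#'   non-derived state), and `low_confidence` (nodes with max posterior
#'   < 0.95).
#' @export
marginal_asr <- function(tree, tip_states, Q, spec,
                         root_prior = spec$root_prior,
                         missing_as_unknown = FALSE) {
  Ltips <- tip_likelihoods(tree, tip_states, spec, missing_as_unknown)
  pr <- pruning_pass(tree, Ltips, Q)
  tree <- pr$tree
  k <- pr$k
  N <- nrow(pr$part)
  ne <- nrow(tree$edge)
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  prior <- root_prior_vector(root_prior, Q, pr$part[pr$root, ])

  # pre-order (above) pass: A[v] is the likelihood flow into v from the
  # rest of the tree; rows normalized as only direction matters.
  A <- matrix(0, N, k)
  A[pr$root, ] <- prior
  edges_by_parent <- split(seq_len(ne), parent)
  for (e in rev(seq_len(ne))) {       # reverse postorder = preorder
    p <- parent[e]
    sibs <- setdiff(edges_by_parent[[as.character(p)]], e)
    except <- A[p, ]
    for (s in sibs) except <- except * pr$vmat[s, ]
    P <- matrix(pr$Pm[e, ], k, k)
    a <- as.vector(crossprod(P, except))
    ssum <- sum(a)
    A[child[e], ] <- if (ssum > 0) a / ssum else rep(1 / k, k)
  }
  post <- A * pr$part
  rs <- rowSums(post)
  bad <- rs <= 0
  if (any(bad)) post[bad, ] <- 1 / k  # unreachable under this Q; flat
  post <- post / rowSums(post)
  colnames(post) <- spec$states

  map_idx <- apply(post, 1L, function(p) {
    top <- which(p >= max(p) - 1e-12)
    top[1]                            # ties -> earliest (non-derived) state
  })
  lik <- sum(prior * pr$part[pr$root, ])
  structure(list(
    tree = tree, posterior = post, states = spec$states,
    loglik = if (lik > 0) log(lik) + pr$logsc[pr$root] else -Inf,
    map_state = spec$states[map_idx],
    low_confidence = which(apply(post, 1L, max) < 0.95)
  ), class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  nt <- ape::Ntip(x$tree)
  cat("Marginal ancestral reconstruction over", length(x$states), "states (",
      paste(x$states, collapse = ", "), ")\n")
  cat(" ", x$tree$Nnode, "internal nodes,", nt, "tips; logL =",
      format(x$loglik, digits = 6), "\n")
  tab <- table(factor(x$map_state[(nt + 1L):(nt + x$tree$Nnode)],
                      levels = x$states))
  cat("  internal MAP states:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a tree with per-node posteriors as an annotated Newick string
#'
#' Serializes node annotations as NHX-style comments
#' (`[&&NHX:p_absent=0.91:...]`) after each node, so reconstructions can be
#' exchanged with tree viewers.
#'
#' @param recon An [marginal_asr()] result.
#' @param file Optional path; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_annotated_newick <- function(recon, file = NULL) {
  tree <- recon$tree
  post <- recon$posterior
  states <- recon$states
  nt <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- setNames(tree$edge.length, tree$edge[, 2])
  ann <- function(i) {
    paste0("[&&NHX:", paste0("p_", states, "=",
                             formatC(post[i, ], format = "g", digits = 6),
                             collapse = ":"), "]")
  }
  rec <- function(i) {
    body <- if (i <= nt) {
      tree$tip.label[i]
    } else {
      paste0("(", paste(vapply(kids[[as.character(i)]], rec, character(1)),
                        collapse = ","), ")")
    }
    len <- if (!is.na(elen[as.character(i)])) {
      paste0(":", formatC(elen[as.character(i)], format = "g", digits = 10))
    } else ""
    paste0(body, ann(i), len)
  }
  s <- paste0(rec(nt + 1L), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}
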