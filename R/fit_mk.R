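# Stable digest of (tree, data) so model comparisons can verify all fits
# saw identical input without carrying the objects around.
data_digest <- function(tree, tip_states) {
  s <- paste(sort(paste0(names(tip_states), "=", unlist(tip_states))),
             collapse = ";")
  paste0(ape::write.tree(tree), "|", s)
}

#' Maximum-likelihood fit of a discrete-trait Markov model
#'
#' Estimates the free transition rates of an `ER`/`SYM`/`ARD`/`PREC` model
#' by maximizing the pruning log-likelihood. Hidden-state likelihood
#' surfaces are multimodal, so optimization is multi-start: bounded
#' quasi-Newton (`L-BFGS-B`) on log rates, from `restarts` seed-jittered
#' starting points spread over several orders of magnitude (scaled to the
#' tree height), keeping the best converged solution.
#'
#' @inheritParams pruning_loglik
#' @param spec A [rate_model_spec()].
#' @param restarts Number of optimizer restarts (default 10).
#' @param seed Optional integer seed for the start jitter.
#' @param lower,upper Rate bounds per unit branch length (defaults 1e-9 and
#'   1e3).
#' @return Object of class `mk_fit`: list with `spec`, `rates`, `Q`,
#'   `loglik`, `n_free`, `aic` (`2 * n_free - 2 * loglik`), `converged`,
#'   `restart_log` (data frame of every restart), and `digest`.
#' @export
fit_mk <- function(tree, tip_states, spec, restarts = 10, seed = NULL,
                   lower = 1e-9, upper = 1e3,
                   root_prior = spec$root_prior,
                   missing_as_unknown = FALSE) {
  stopifnot(inherits(spec, "rate_model_spec"))
  digest <- data_digest(tree, tip_states)
  tree <- ape::reorder.phylo(tree, "postorder")
  Ltips <- tip_likelihoods(tree, tip_states, spec, missing_as_unknown)
  syms <- unlist(tip_states[names(tip_states) %in% tree$tip.label])
  if (length(unique(as.character(syms))) < 2L) {
    warning("tip character is invariant; rates are weakly identifiable")
  }
  if (!is.null(seed)) set.seed(seed)
  nll <- function(logp) {
    Q <- build_rate_matrix(spec, exp(logp))
    pr <- pruning_pass(tree, Ltips, Q)
    prior <- root_prior_vector(root_prior, Q, pr$part[pr$root, ])
    lik <- sum(prior * pr$part[pr$root, ])
    if (lik <= 0 || !is.finite(lik)) return(1e10)
    -(log(lik) + pr$logsc[pr$root])
  }
  H <- max(ape::node.depth.edgelength(tree))
  base_rate <- 1 / max(H, .Machine$double.eps)
  np <- spec$n_free
  starts <- lapply(seq_len(restarts), function(r) {
    if (r == 1L) rep(log(base_rate), np)
    else log(base_rate) + log(10) * runif(np, -2.5, 1.5)
  })
  lo <- rep(log(lower), np)
  hi <- rep(log(upper), np)
  logs <- vector("list", restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    st <- pmin(pmax(starts[[r]], lo), hi)
    o <- tryCatch(
      stats::nlminb(st, nll, lower = lo, upper = hi,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(o)) {
      logs[[r]] <- data.frame(restart = r, value = NA_real_,
                              convergence = NA_integer_)
      next
    }
    logs[[r]] <- data.frame(restart = r, value = o$objective,
                            convergence = o$convergence)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  restart_log <- do.call(rbind, logs)
  rates <- exp(best$par)
  loglik <- -best$objective
  structure(list(
    spec = spec, rates = rates, Q = build_rate_matrix(spec, rates),
    loglik = loglik, n_free = np, aic = 2 * np - 2 * loglik,
    converged = any(restart_log$convergence == 0, na.rm = TRUE),
    restart_log = restart_log,
    root_prior = root_prior,
    digest = digest
  ), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(x$spec$pattern, "fit:", x$n_free, "free rate(s), logL =",
      format(x$loglik, digits = 7), ", AIC =", format(x$aic, digits = 7),
      if (!x$converged) "(no restart converged!)", "\n")
  cat("  rates:", paste(formatC(x$rates, format = "g", digits = 4),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Rank model fits by AIC
#'
#' @param ... `mk_fit` objects (or a single list of them), all fitted to
#'   the same tree and tip data.
#' @return Data frame sorted by AIC ascending, with `model`, `n_free`,
#'   `loglik`, `aic`, `delta_aic`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "mk_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "mk_fit")))
  digs <- vapply(fits, `[[`, character(1), "digest")
  if (length(unique(digs)) > 1L) {
    stop("fits were not computed on identical tree + data")
  }
  out <- data.frame(
    model = vapply(fits, function(f) f$spec$pattern, character(1)),
    n_free = vapply(fits, `[[`, integer(1), "n_free"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$aic, out$n_free), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}

#' Count gains and losses of a derived state on a tree
#'
#' Assigns each node its maximum-posterior state (or takes true node states
#' directly) and counts branches along which the derived state was gained
#' (parent in the ancestral/precursor set, child derived) or lost (the
#' reverse). Posterior ties are broken toward the non-derived class, so
#' counting is conservative.
#'
#' @param x Either an [marginal_asr()] result, or a character vector of
#'   node states in `ape` numbering (length `Ntip + Nnode`; requires
#'   `tree`).
#' @param tree Required when `x` is a state vector.
#' @param derived Character vector of derived state(s); defaults to
#'   `"used"` when present among the states, else the last state.
#' @return Object of class `origin_count`: list with `gains`, `losses`,
#'   `gain_edges`, `loss_edges` (data frames: parent, child, states), and
#'   `low_confidence` node indices (empty for true-state input).
#' @export
count_transitions <- function(x, tree = NULL, derived = NULL) {
  if (inherits(x, "ancestral_reconstruction")) {
    tree <- x$tree
    states <- x$states
    node_state <- x$map_state
    lowconf <- x$low_confidence
  } else {
    if (is.null(tree)) stop("tree is required when x is a state vector")
    node_state <- as.character(x)
    states <- unique(node_state)
    lowconf <- integer(0)
    if (length(node_state) != ape::Ntip(tree) + tree$Nnode) {
      stop("state vector must cover all tips and internal nodes")
    }
  }
  if (is.null(derived)) {
    derived <- if ("used" %in% states) "used" else states[length(states)]
  }
  ps <- node_state[tree$edge[, 1]]
  cs <- node_state[tree$edge[, 2]]
  gain <- !(ps %in% derived) & (cs %in% derived)
  loss <- (ps %in% derived) & !(cs %in% derived)
  mk_df <- function(sel) data.frame(
    parent = tree$edge[sel, 1], child = tree$edge[sel, 2],
    parent_state = ps[sel], child_state = cs[sel],
    stringsAsFactors = FALSE
  )
  structure(list(
    gains = sum(gain), losses = sum(loss),
    gain_edges = mk_df(gain), loss_edges = mk_df(loss),
    derived = derived, low_confidence = lowconf
  ), class = "origin_count")
}

#' @export
print.origin_count <- function(x, ...) {
  cat("Origins of {", paste(x$derived, collapse = ", "), "}: ",
      x$gains, " gain(s), ", x$losses, " loss(es)\n", sep = "")
  if (length(x$low_confidence)) {
    cat("  ", length(x$low_confidence),
        "node(s) with max posterior < 0.95\n")
  }
  invisible(x)
}

#' Export counted transitions as a table
#'
#' @param oc An [count_transitions()] result.
#' @return Data frame with one row per event: `parent`, `child`,
#'   `parent_state`, `child_state`, `event` (gain/loss).
#' @export
transition_table <- function(oc) {
  stopifnot(inherits(oc, "origin_count"))
  g <- oc$gain_edges
  l <- oc$loss_edges
  g$event <- rep("gain", nrow(g))
  l$event <- rep("loss", nrow(l))
  out <- rbind(g, l)
  rownames(out) <- NULL
  out
}
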