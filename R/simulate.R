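#' Configuration for a synthetic foot-use study
#'
#' Bundles every knob of the generator with defaults that emulate the
#' empirical setting: a Yule tree; a precursor-model trait history started
#' from the ancestral state; per-species repository media counts that are
#' log-normal with a heavy right tail spanning roughly 1 to 10^4; a
#' constant per-media probability of capturing foot use (so species-level
#' detection probability is `1 - (1 - p)^m`); and per-media behavior flags
#' drawn to respect the implication hierarchy.
#'
#' @param n_tips Number of species (default 250).
#' @param birth,death Birth-death rates of the tree simulation, per unit
#'   branch length. Branch lengths are read as millions of years, so the
#'   default is a pure-birth (Yule) process at an avian-like speciation
#'   rate of 0.1/Myr, giving trees a few tens of Myr deep on which the
#'   default trait rates produce repeated gains and losses.
#' @param spec Trait model, a [rate_model_spec()] (default `PREC`).
#' @param rates True rates (default `c(0.05, 0.02, 0.1, 0.05)` per unit
#'   branch length for `PREC`).
#' @param root_state Root state label (default first state of `spec`).
#' @param media_meanlog,media_sdlog Log-normal media-count parameters
#'   (defaults 5 and 1.5: median about 150 media per species).
#' @param p_media Per-media probability that a media record of a foot-using
#'   species shows foot use (default 0.005).
#' @param behavior_probs Named conditional probabilities used when scoring
#'   a foot-use media record; see Details in the package vignette.
#' @param p_media_shape Optional shape for beta-distributed per-species
#'   heterogeneity in `p_media`; `NULL` (default) keeps it constant.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_tips = 250, birth = 0.1, death = 0,
                              spec = rate_model_spec("PREC"),
                              rates = c(0.05, 0.02, 0.1, 0.05),
                              root_state = spec$states[1],
                              media_meanlog = 5, media_sdlog = 1.5,
                              p_media = 0.005,
                              behavior_probs = c(
                                grasping = 0.6, free_grasping = 0.4,
                                free_grasping_in_flight = 0.2,
                                use_of_toes = 0.3, use_of_one_leg = 0.4,
                                foot_to_beak = 0.3, foot_to_midline = 0.15,
                                inward_rotation = 0.2,
                                outward_rotation = 0.05),
                              p_media_shape = NULL) {
  stopifnot(n_tips >= 2, birth > 0, death >= 0,
            inherits(spec, "rate_model_spec"),
            length(rates) == spec$n_free, all(rates >= 0),
            root_state %in% spec$states,
            p_media >= 0, p_media <= 1,
            all(behavior_probs >= 0 & behavior_probs <= 1))
  structure(list(
    n_tips = n_tips, birth = birth, death = death, spec = spec,
    rates = rates, root_state = root_state,
    media_meanlog = media_meanlog, media_sdlog = media_sdlog,
    p_media = p_media, behavior_probs = behavior_probs,
    p_media_shape = p_media_shape
  ), class = "simulation_config")
}

#' Simulate an ultrametric birth-death tree
#'
#' @param n_tips Number of tips.
#' @param birth,death Speciation and extinction rates per Myr (default a
#'   Yule process at 0.1/Myr).
#' @param seed Optional integer seed; identical seeds give identical trees.
#' @return A `phylo` with tips labeled `sp0001`, `sp0002`, ...
#' @export
simulate_tree <- function(n_tips, birth = 0.1, death = 0, seed = NULL) {
  if (n_tips < 2) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = death)
  tr$tip.label <- sprintf("sp%04d", seq_len(n_tips))
  tr
}

#' Simulate a discrete character along a tree with a full event log
#'
#' Exact continuous-time Markov simulation: along every branch, waiting
#' times to the next transition are exponential with the current state's
#' total exit rate, and each realized transition is appended to the event
#' log. The log therefore contains the true number of gains and losses,
#' against which reconstruction-based counts can be scored.
#'
#' @param tree A `phylo`.
#' @param Q Generator from [build_rate_matrix()].
#' @param root_state State label at the root.
#' @param seed Optional integer seed.
#' @return List of class `trait_history`: `tip_states` (named character),
#'   `node_states` (length `Ntip + Nnode`, ape numbering), `events` (data
#'   frame: edge, parent, child, time_along_edge, from, to), and the tree.
#' @export
simulate_character <- function(tree, Q, root_state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- rownames(Q)
  if (is.null(states)) states <- as.character(seq_len(nrow(Q)))
  stopifnot(root_state %in% states)
  nt <- ape::Ntip(tree)
  N <- nt + tree$Nnode
  tre <- ape::reorder.phylo(tree, "postorder")
  node_state <- character(N)
  node_state[nt + 1L] <- root_state
  ev <- list()
  # preorder = reverse postorder: parents are assigned before children
  for (e in rev(seq_len(nrow(tre$edge)))) {
    p <- tre$edge[e, 1]; ch <- tre$edge[e, 2]
    s <- node_state[p]
    tlen <- tre$edge.length[e]
    pos <- 0
    repeat {
      i <- match(s, states)
      exit <- -Q[i, i]
      if (exit <= 0) break
      pos <- pos + rexp(1, exit)
      if (pos >= tlen) break
      to <- sample(states[-i], 1, prob = Q[i, -i])
      ev[[length(ev) + 1L]] <- data.frame(
        edge = e, parent = p, child = ch, time_along_edge = pos,
        from = s, to = to, stringsAsFactors = FALSE)
      s <- to
    }
    node_state[ch] <- s
  }
  events <- if (length(ev)) do.call(rbind, ev) else data.frame(
    edge = integer(0), parent = integer(0), child = integer(0),
    time_along_edge = numeric(0), from = character(0), to = character(0),
    stringsAsFactors = FALSE)
  structure(list(
    tip_states = setNames(node_state[seq_len(nt)], tre$tip.label),
    node_states = node_state, events = events, tree = tre
  ), class = "trait_history")
}

# True gains/losses of `derived` in an event log.
true_transition_counts <- function(history, derived = "used") {
  ev <- history$events
  gains <- sum(!(ev$from %in% derived) & ev$to %in% derived)
  losses <- sum(ev$from %in% derived & !(ev$to %in% derived))
  list(gains = gains, losses = losses)
}

#' Simulate media counts, detections, and per-media behavior scores
#'
#' Each species receives a log-normal repository media count. Species in
#' the derived (foot-using) state have each media record independently show
#' foot use with probability `p_media`; a scored row is emitted for every
#' such record, with the remaining behavior flags drawn conditionally so
#' the implication hierarchy always holds. Species in the ancestral or
#' precursor states never show foot use (they are observationally
#' identical), so they produce no scored rows.
#'
#' @param tip_states Named character vector of true states per species.
#' @param config A [simulation_config()].
#' @param seed Optional integer seed.
#' @param derived State label(s) counting as foot-using (default `"used"`).
#' @return List: `media` (Dataset-1-shaped data frame of scored rows),
#'   `species` (Dataset-2-shaped data frame: species, true_state,
#'   media_count, n_footuse_media, detected, p_media).
#' @export
simulate_media_and_scoring <- function(tip_states, config, seed = NULL,
                                       derived = "used") {
  if (!is.null(seed)) set.seed(seed)
  sp <- names(tip_states)
  n <- length(sp)
  m <- pmax(1L, as.integer(round(rlnorm(n, config$media_meanlog,
                                        config$media_sdlog))))
  p <- if (is.null(config$p_media_shape)) {
    rep(config$p_media, n)
  } else {
    a <- config$p_media_shape
    stats::rbeta(n, a, a * (1 - config$p_media) / config$p_media)
  }
  is_user <- tip_states %in% derived
  hits <- ifelse(is_user, rbinom(n, m, p), 0L)
  bp <- config$behavior_probs
  rows <- vector("list", n)
  for (i in which(hits > 0L)) {
    h <- hits[i]
    flags <- matrix(0L, h, length(BEHAVIOR_FLAGS),
                    dimnames = list(NULL, BEHAVIOR_FLAGS))
    flags[, "foot_use"] <- 1L
    flags[, "grasping"] <- rbinom(h, 1, bp[["grasping"]])
    flags[, "free_grasping"] <- flags[, "grasping"] *
      rbinom(h, 1, bp[["free_grasping"]])
    flags[, "free_grasping_in_flight"] <- flags[, "free_grasping"] *
      rbinom(h, 1, bp[["free_grasping_in_flight"]])
    for (f in c("use_of_toes", "use_of_one_leg", "foot_to_beak",
                "foot_to_midline", "inward_rotation", "outward_rotation")) {
      flags[, f] <- rbinom(h, 1, bp[[f]])
    }
    rows[[i]] <- cbind(
      data.frame(species = sp[i],
                 media_id = sprintf("%s_m%05d", sp[i], seq_len(h)),
                 source = sample(c("macaulay", "wikiaves", "other"), h,
                                 replace = TRUE, prob = c(0.5, 0.1, 0.4)),
                 stringsAsFactors = FALSE),
      as.data.frame(flags))
  }
  media <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(media)) {
    media <- cbind(data.frame(species = character(0), media_id = character(0),
                              source = character(0)),
                   as.data.frame(matrix(integer(0), 0, length(BEHAVIOR_FLAGS),
                                        dimnames = list(NULL, BEHAVIOR_FLAGS))))
  }
  rownames(media) <- NULL
  species <- data.frame(
    species = sp, true_state = unname(tip_states), media_count = m,
    n_footuse_media = hits, detected = hits > 0L, p_media = p,
    stringsAsFactors = FALSE)
  list(media = media, species = species)
}

#' Generate a complete synthetic study bundle on disk
#'
#' Runs the whole generator — tree, trait history, media scoring — and
#' writes cross-consistent plain-text files: `tree.nwk`, `media.csv`
#' (Dataset-1 shape), `species.csv` (Dataset-2 shape), `truth.json` (true
#' rates, node states, event log, gain/loss counts, detection parameters),
#' and `config.yaml` (the configuration echoed with the seed). Identical
#' `(config, seed)` produce byte-identical bundles.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every random draw.
#' @return Invisibly, a list with the in-memory `tree`, `history`, `media`,
#'   `species`, and the file paths.
#' @export
generate_study_bundle <- function(config, dir, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tree <- simulate_tree(config$n_tips, config$birth, config$death)
  Q <- build_rate_matrix(config$spec, config$rates)
  history <- simulate_character(tree, Q, config$root_state)
  obs <- simulate_media_and_scoring(history$tip_states, config)
  tc <- true_transition_counts(history, derived = config$spec$states[config$spec$k])

  paths <- list(
    tree = file.path(dir, "tree.nwk"),
    media = file.path(dir, "media.csv"),
    species = file.path(dir, "species.csv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml"))
  ape::write.tree(history$tree, file = paths$tree)
  write.csv(obs$media, paths$media, row.names = FALSE, quote = FALSE)
  write.csv(obs$species, paths$species, row.names = FALSE, quote = FALSE)
  truth <- list(
    seed = seed, pattern = config$spec$pattern, states = config$spec$states,
    rates = config$rates, root_state = config$root_state,
    node_states = history$node_states, events = history$events,
    true_gains = tc$gains, true_losses = tc$losses,
    p_media = config$p_media,
    analytic_threshold_75 = if (config$p_media > 0)
      ceiling(log(0.25) / log(1 - config$p_media)) else NA)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$spec <- list(pattern = config$spec$pattern, states = config$spec$states,
                   root_prior = config$spec$root_prior)
  yaml::write_yaml(c(list(seed = seed), unclass(cfg)), paths$config)
  invisible(list(tree = history$tree, history = history, media = obs$media,
                 species = obs$species, paths = paths, truth = truth))
}
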