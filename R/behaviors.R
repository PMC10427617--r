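# The ten scored pedal-manipulation behaviors, in canonical column order.
BEHAVIOR_FLAGS <- c(
  "foot_use", "grasping", "free_grasping", "free_grasping_in_flight",
  "use_of_toes", "use_of_one_leg", "foot_to_beak", "foot_to_midline",
  "inward_rotation", "outward_rotation"
)

#' Behavior flags scored on each media record
#'
#' The ten binary behaviors recorded for every photograph or video of a bird
#' manipulating an object with its feet, from plain foot use (holding or
#' pinning an object with a claw) up to free grasping in flight and foot
#' rotations.
#'
#' @return Character vector of the ten flag names, in canonical order.
#' @export
#' @examples
#' behavior_flags()
behavior_flags <- function() BEHAVIOR_FLAGS

#' Implication rules among behavior flags
#'
#' The behavior taxonomy is hierarchical: an object grasped in flight is
#' necessarily freely grasped, free grasping is a form of grasping, and any
#' scored behavior entails foot use. These rules are configuration rather
#' than hard-coded semantics; whether lifting the foot to the beak entails a
#' closed-claw grasp is left off by default because holding without grasping
#' is possible.
#'
#' @param foot_to_beak_implies_grasping Logical; add the rule
#'   `foot_to_beak => grasping`.
#' @return A list of length-2 character vectors `c(from, to)`, each read as
#'   "`from` set implies `to` set".
#' @export
behavior_implications <- function(foot_to_beak_implies_grasping = FALSE) {
  imp <- list(
    c("free_grasping_in_flight", "free_grasping"),
    c("free_grasping", "grasping")
  )
  for (f in setdiff(BEHAVIOR_FLAGS, "foot_use")) {
    imp[[length(imp) + 1L]] <- c(f, "foot_use")
  }
  if (foot_to_beak_implies_grasping) {
    imp[[length(imp) + 1L]] <- c("foot_to_beak", "grasping")
  }
  imp
}

# Rows of `flags` (0/1 matrix with BEHAVIOR_FLAGS columns) that violate an
# implication rule. Returns a character vector like "grasping=>foot_use"
# per violating (row, rule), named by row index.
find_implication_violations <- function(flags, implications) {
  out <- character(0)
  idx <- integer(0)
  for (rule in implications) {
    bad <- which(flags[, rule[1]] == 1L & flags[, rule[2]] == 0L)
    if (length(bad)) {
      out <- c(out, rep(paste0(rule[1], "=>", rule[2]), length(bad)))
      idx <- c(idx, bad)
    }
  }
  names(out) <- idx
  out
}

# Set all implied flags (transitive closure over the rule list).
close_implications <- function(flags, implications) {
  repeat {
    changed <- FALSE
    for (rule in implications) {
      bad <- flags[, rule[1]] == 1L & flags[, rule[2]] == 0L
      if (any(bad)) {
        flags[bad, rule[2]] <- 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  flags
}
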