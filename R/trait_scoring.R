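#' Read and validate a per-media behavior table
#'
#' Parses a table with one row per scored photograph or video: a species
#' name, a media identifier, an optional source, and the ten binary behavior
#' flags (see [behavior_flags()]). Under strict validation, rows violating
#' the behavior implication hierarchy (e.g. `grasping = 1` with
#' `foot_use = 0`) are an error; under lenient validation the implied flags
#' are set automatically with a warning.
#'
#' @param x Path to a CSV/TSV file (separator sniffed from the extension:
#'   `.tsv`/`.tab` are tab-separated, anything else comma), or a data frame
#'   already in memory.
#' @param strict Logical; reject implication violations instead of repairing
#'   them.
#' @param implications Rule list from [behavior_implications()].
#' @return A data frame of validated media records with columns `species`,
#'   `media_id`, `source`, and the ten behavior flags as integers.
#' @export
parse_media_table <- function(x, strict = TRUE,
                              implications = behavior_implications()) {
  if (is.character(x)) {
    sep <- if (grepl("\\.(tsv|tab)$", x, ignore.case = TRUE)) "\t" else ","
    x <- read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
  }
  x <- as.data.frame(x)
  if ("species_id" %in% names(x) && !"species" %in% names(x)) {
    names(x)[names(x) == "species_id"] <- "species"
  }
  required <- c("species", "media_id", BEHAVIOR_FLAGS)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("media table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(x) == 0L) {
    out <- x[, intersect(c("species", "media_id", "source", BEHAVIOR_FLAGS),
                         names(x)), drop = FALSE]
    if (!"source" %in% names(out)) out$source <- character(0)
    return(out[, c("species", "media_id", "source", BEHAVIOR_FLAGS)])
  }
  if (!"source" %in% names(x)) x$source <- "other"
  x$source <- as.character(x$source)
  bad_src <- !x$source %in% c("macaulay", "wikiaves", "other")
  if (any(bad_src)) {
    stop("unknown media source(s): ",
         paste(unique(x$source[bad_src]), collapse = ", "))
  }
  x$species <- as.character(x$species)
  x$media_id <- as.character(x$media_id)
  if (any(!nzchar(x$species)) || anyNA(x$species)) {
    stop("empty species name in media table")
  }
  if (anyDuplicated(x$media_id)) {
    stop("duplicate media_id: ",
         paste(unique(x$media_id[duplicated(x$media_id)]), collapse = ", "))
  }
  flags <- as.matrix(x[, BEHAVIOR_FLAGS])
  if (!is.numeric(flags) || anyNA(flags) || !all(flags %in% c(0, 1))) {
    stop("behavior flags must all be 0 or 1")
  }
  storage.mode(flags) <- "integer"
  viol <- find_implication_violations(flags, implications)
  if (length(viol)) {
    if (strict) {
      stop("implication rule violation(s) in ", length(viol), " cell(s), e.g. row ",
           names(viol)[1], ": ", viol[1])
    }
    flags <- close_implications(flags, implications)
    warning("auto-set implied behavior flags in ",
            length(unique(names(viol))), " row(s)")
  }
  x[, BEHAVIOR_FLAGS] <- flags
  x[, c("species", "media_id", "source", BEHAVIOR_FLAGS)]
}

#' Union of behaviors observed across a species' media
#'
#' @param records Data frame of media records for a single species (rows of
#'   the table returned by [parse_media_table()]).
#' @return Named integer vector over the ten behavior flags: 1 if the
#'   behavior was observed in any media record.
#' @export
behavior_union <- function(records) {
  if (nrow(records) == 0L) {
    return(setNames(integer(length(BEHAVIOR_FLAGS)), BEHAVIOR_FLAGS))
  }
  if (length(unique(records$species)) > 1L) {
    stop("records mix species: ",
         paste(unique(records$species), collapse = ", "))
  }
  u <- as.integer(colSums(as.matrix(records[, BEHAVIOR_FLAGS])) > 0)
  setNames(u, BEHAVIOR_FLAGS)
}

#' Species-level dexterity index
#'
#' The number of distinct pedal-manipulation behaviors (0-10) observed for a
#' species across all of its media records: the size of the union of set
#' flags, not a per-media average, so a single clear video can contribute
#' several behaviors.
#'
#' @inheritParams behavior_union
#' @return Integer in 0..10.
#' @export
dexterity_index <- function(records) {
  sum(behavior_union(records))
}

#' Classify species foot-use status against a detection threshold
#'
#' A species is `present` as soon as any media record shows foot use. With
#' no such record, the species' total media availability decides whether
#' absence is informative: below the clade's detection threshold the species
#' is `insufficient` (too few media to tell), at or above it `absent`.
#'
#' @param has_foot_use Logical vector: any foot-use media for the species.
#' @param media_count Non-negative integer vector of repository media counts.
#' @param threshold Detection threshold (single non-negative number, or a
#'   vector recycled against the species).
#' @return Character vector over `c("present", "absent", "insufficient")`.
#' @export
species_status <- function(has_foot_use, media_count, threshold) {
  if (any(threshold < 0)) stop("threshold must be >= 0")
  if (any(media_count < 0)) stop("media_count must be >= 0")
  ifelse(has_foot_use, "present",
         ifelse(media_count < threshold, "insufficient", "absent"))
}

#' Aggregate media records into species profiles
#'
#' Builds the species-level summary table: clade labels, repository media
#' count, behavior union, dexterity index, and foot-use status. Species
#' listed in `taxonomy` but with no media records get a dexterity index of 0
#' and, lacking foot-use evidence, are classified by their media count.
#'
#' @param media Validated media table from [parse_media_table()].
#' @param taxonomy Data frame with columns `species`, `genus`, `family`,
#'   `order`; its species set defines the output rows.
#' @param media_counts Data frame with columns `species`, `media_count`
#'   (repository snapshot totals). Species absent from it get count 0.
#' @param threshold Detection threshold passed to [species_status()]; either
#'   a single number or a data frame with columns `species`, `threshold`.
#' @return Data frame with one row per species: `species`, `genus`,
#'   `family`, `order`, `media_count`, the ten behavior flags,
#'   `dexterity_index`, `status`.
#' @export
species_profiles <- function(media, taxonomy, media_counts, threshold) {
  stopifnot(all(c("species", "genus", "family", "order") %in% names(taxonomy)))
  sp <- taxonomy$species
  extra <- setdiff(unique(media$species), sp)
  if (length(extra)) {
    stop("media records for species missing from taxonomy: ",
         paste(head(extra, 5), collapse = ", "))
  }
  counts <- setNames(rep(0L, length(sp)), sp)
  if (!is.null(media_counts)) {
    keep <- media_counts$species %in% sp
    counts[media_counts$species[keep]] <-
      as.integer(media_counts$media_count[keep])
  }
  if (is.data.frame(threshold)) {
    thr <- setNames(threshold$threshold, threshold$species)[sp]
    if (anyNA(thr)) stop("threshold table misses some species")
  } else {
    thr <- rep(threshold, length(sp))
  }
  un <- t(vapply(sp, function(s) {
    behavior_union(media[media$species == s, , drop = FALSE])
  }, integer(length(BEHAVIOR_FLAGS))))
  out <- data.frame(
    species = sp, genus = taxonomy$genus, family = taxonomy$family,
    order = taxonomy$order, media_count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(un))
  out$dexterity_index <- as.integer(rowSums(un))
  out$status <- species_status(un[, "foot_use"] == 1L, out$media_count, thr)
  rownames(out) <- NULL
  out
}

#' Write a species-profile table to CSV
#'
#' @param profiles Output of [species_profiles()].
#' @param file Destination path.
#' @return `file`, invisibly.
#' @export
write_species_profiles <- function(profiles, file) {
  write.csv(profiles, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Canonical diet categories and the niche label each maps to when dominant.
DIET_NICHES <- c(
  invertebrates = "invertivore", vertebrates = "vertivore",
  carrion = "scavenger", fruit = "frugivore", nectar = "nectarivore",
  seeds = "granivore", other_plant = "herbivore"
)

#' Assign a trophic niche from diet percentages
#'
#' A species belongs to a diet category when more than 60% of its diet is of
#' that single type; species with no category above 60% are omnivores. The
#' inequality is strict: exactly 60% does not qualify. Percentage tables are
#' typically rounded at source, so totals up to `100 + tol` are accepted.
#'
#' @param percentages Named numeric vector of diet percentages (names among
#'   `r paste(names(pedex:::DIET_NICHES), collapse = ", ")`), or a data frame
#'   of such columns, one row per species.
#' @param cutoff Dominance cutoff in percent (default 60).
#' @param tol Rounding tolerance on the total (default 0.5).
#' @return Niche label(s): e.g. `"frugivore"` for dominant fruit, or
#'   `"omnivore"`.
#' @export
assign_trophic_niche <- function(percentages, cutoff = 60, tol = 0.5) {
  if (is.data.frame(percentages)) {
    cols <- intersect(names(DIET_NICHES), names(percentages))
    return(vapply(seq_len(nrow(percentages)), function(i) {
      assign_trophic_niche(unlist(percentages[i, cols]), cutoff, tol)
    }, character(1)))
  }
  p <- percentages[!is.na(percentages)]
  if (any(p < 0 | p > 100)) stop("diet percentages must lie in [0, 100]")
  if (sum(p) > 100 + tol) {
    stop("diet percentages sum to ", round(sum(p), 2), " > ", 100 + tol)
  }
  over <- p[p > cutoff]
  if (length(over) == 0L) return("omnivore")
  cat <- names(over)[which.max(over)]
  unname(ifelse(cat %in% names(DIET_NICHES), DIET_NICHES[cat], cat))
}

#' Fractions of foot-use evidence classes per diet category
#'
#' For each diet category, the fraction of species with confirmed foot use,
#' with likely foot use (species never searched but belonging to a family
#' where foot use was confirmed), and with no evidence. Fractions within a
#' category sum to 1.
#'
#' @param species Data frame with columns `species`, `family`, `diet`,
#'   `searched` (logical), and `foot_use` (logical; may be `NA` for
#'   unsearched species).
#' @param confirmed_families Character vector of families where foot use was
#'   confirmed.
#' @return Data frame with columns `diet`, `n`, `foot_use`,
#'   `likely_foot_use`, `no_evidence` (the last three are fractions).
#' @export
summarize_status_by_diet <- function(species, confirmed_families) {
  stopifnot(all(c("species", "family", "diet", "searched", "foot_use") %in%
                  names(species)))
  if (anyNA(species$family) || any(!nzchar(species$family))) {
    stop("species with unknown family: ",
         paste(head(species$species[is.na(species$family) |
                                      !nzchar(species$family)], 5),
               collapse = ", "))
  }
  cls <- ifelse(
    !is.na(species$foot_use) & species$foot_use, "foot_use",
    ifelse(!species$searched & species$family %in% confirmed_families,
           "likely_foot_use", "no_evidence")
  )
  diets <- sort(unique(species$diet))
  out <- do.call(rbind, lapply(diets, function(d) {
    sel <- species$diet == d
    n <- sum(sel)
    data.frame(
      diet = d, n = n,
      foot_use = sum(cls[sel] == "foot_use") / n,
      likely_foot_use = sum(cls[sel] == "likely_foot_use") / n,
      no_evidence = sum(cls[sel] == "no_evidence") / n,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
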