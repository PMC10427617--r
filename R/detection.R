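# Firth (Jeffreys-penalized) logistic regression by Newton iteration with
# step halving. Keeps estimates finite under complete separation, where the
# ordinary ML fit diverges. X is the design matrix including intercept.
firth_logit <- function(X, y, maxit = 200, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen_loglik <- function(b) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    W <- p * (1 - p)
    XtWX <- crossprod(X * W, X)
    ld <- determinant(XtWX, logarithm = TRUE)$modulus
    sum(y * eta - log1p(exp(eta))) + 0.5 * ld
  }
  ll <- pen_loglik(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    XtWX <- crossprod(X * W, X)
    XtWXi <- solve(XtWX)
    # hat diagonal of the weighted regression
    h <- rowSums((X %*% XtWXi) * X) * W
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(XtWXi %*% U)
    lam <- 1
    repeat {
      cand <- beta + lam * step
      llc <- pen_loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    beta_new <- beta + lam * step
    done <- max(abs(beta_new - beta)) < tol
    beta <- beta_new
    ll <- pen_loglik(beta)
    if (done) break
  }
  p <- plogis(drop(X %*% beta))
  V <- solve(crossprod(X * (p * (1 - p)), X))
  list(coefficients = beta, vcov = V, iter = it)
}

#' Fit a logistic detection curve for a clade
#'
#' Models the probability that foot use was detected for a species (at least
#' one media record showing it) as a logistic function of the species' media
#' availability. The default predictor scale is `log10(media_count)` because
#' repository counts span four orders of magnitude; raw counts are available
#' as an option. When the data are completely or quasi-completely separated
#' (including the degenerate all-detected / none-detected cases) the ML fit
#' diverges, so a Jeffreys-penalized (Firth) fit is used instead and the
#' curve is flagged.
#'
#' @param observations Data frame with columns `media_count` (positive
#'   integers) and `detected` (logical or 0/1); an optional `species` column
#'   is carried along.
#' @param predictor_scale `"log10"` (default) or `"raw"`.
#' @return Object of class `detection_curve`: list with `coefficients`
#'   (intercept, slope), `vcov`, `predictor_scale`, `n_obs`,
#'   `separation_flag`, `method` (`"ml"` or `"firth"`), and the observed
#'   media range.
#' @export
fit_detection_curve <- function(observations,
                                predictor_scale = c("log10", "raw")) {
  predictor_scale <- match.arg(predictor_scale)
  stopifnot(all(c("media_count", "detected") %in% names(observations)))
  m <- observations$media_count
  if (any(m < 1)) stop("media_count must be >= 1")
  y <- as.integer(as.logical(observations$detected))
  if (length(y) < 2L) stop("need at least 2 observations")
  s <- if (predictor_scale == "log10") log10(m) else as.numeric(m)
  X <- cbind(`(Intercept)` = 1, media = s)

  separation <- length(unique(y)) < 2L
  method <- "ml"
  if (!separation) {
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    pr <- fit$fitted.values
    # quasi-separation: fitted probabilities pinned to 0/1
    separation <- !fit$converged ||
      all(pr[y == 1] > 1 - 1e-8) && all(pr[y == 0] < 1e-8)
  }
  if (separation) {
    method <- "firth"
    ff <- firth_logit(X, y)
    cf <- ff$coefficients
    V <- ff$vcov
  } else {
    cf <- fit$coefficients
    eta <- drop(X %*% cf)
    w <- plogis(eta) * (1 - plogis(eta))
    V <- solve(crossprod(X * w, X))
  }
  names(cf) <- c("intercept", "slope")
  dimnames(V) <- list(names(cf), names(cf))
  structure(list(
    coefficients = cf, vcov = V, predictor_scale = predictor_scale,
    n_obs = length(y), separation_flag = separation, method = method,
    media_range = range(m)
  ), class = "detection_curve")
}

#' @export
print.detection_curve <- function(x, ...) {
  cat("Logistic detection curve (", x$predictor_scale, " media scale, n = ",
      x$n_obs, ")\n", sep = "")
  cat(sprintf("  intercept %.4f  slope %.4f  [%s%s]\n",
              x$coefficients[1], x$coefficients[2], x$method,
              if (x$separation_flag) ", separation" else ""))
  invisible(x)
}

#' Detection probability (with confidence band) at given media counts
#'
#' @param curve A [fit_detection_curve()] result.
#' @param media_count Vector of media counts.
#' @param ci Confidence level for the pointwise Wald band on the linear
#'   predictor (transformed through the inverse logit); `NULL` for the point
#'   estimate only.
#' @return Data frame with `media_count`, `prob`, and (if `ci`) `lower`,
#'   `upper`.
#' @export
predict_detection <- function(curve, media_count, ci = 0.95) {
  s <- if (curve$predictor_scale == "log10") log10(media_count)
       else as.numeric(media_count)
  X <- cbind(1, s)
  eta <- drop(X %*% curve$coefficients)
  out <- data.frame(media_count = media_count, prob = plogis(eta))
  if (!is.null(ci)) {
    se <- sqrt(rowSums((X %*% curve$vcov) * X))
    z <- qnorm(1 - (1 - ci) / 2)
    out$lower <- plogis(eta - z * se)
    out$upper <- plogis(eta + z * se)
  }
  out
}

#' Media-count detection threshold for a clade
#'
#' The smallest integer media count at which the lower pointwise Wald
#' confidence bound of the fitted detection curve reaches the target
#' detection probability (75% by default). Because the lower bound lies
#' below the point estimate everywhere, this threshold is conservative:
#' it is never smaller than the point-estimate crossing. The crossing is
#' found by integer scan over `[1, 10 x max observed media]` (the bound is
#' monotone in media count when the slope is positive); it can optionally be
#' rounded up to a multiple for reporting.
#'
#' @param curve A [fit_detection_curve()] result.
#' @param p Target detection probability (default 0.75).
#' @param ci Confidence level of the lower bound (default 0.95); `ci = NULL`
#'   uses the point estimate.
#' @param round_up_to Round the threshold up to this multiple (default 1,
#'   i.e. plain ceiling).
#' @param max_media Upper end of the search range; defaults to 10x the
#'   largest observed media count.
#' @param clade_id Optional label carried into the result.
#' @return Object of class `threshold_result`: list with `clade_id`,
#'   `threshold` (integer, or `NA` with a `reason` when undefined),
#'   `probability_level`, `ci_level`, `fallback_clade` (`NA` here; set by
#'   [clade_threshold_pipeline()]), and `separation_flag`.
#' @export
detection_threshold <- function(curve, p = 0.75, ci = 0.95, round_up_to = 1,
                                max_media = NULL, clade_id = NA_character_) {
  stopifnot(inherits(curve, "detection_curve"))
  res <- list(clade_id = clade_id, threshold = NA_integer_,
              probability_level = p, ci_level = if (is.null(ci)) NA_real_ else ci,
              fallback_clade = NA_character_,
              separation_flag = curve$separation_flag, reason = NA_character_)
  class(res) <- "threshold_result"
  if (curve$coefficients["slope"] <= 0) {
    res$reason <- "non-positive slope: detection does not increase with media"
    return(res)
  }
  if (is.null(max_media)) max_media <- 10 * curve$media_range[2]
  mm <- seq_len(max(1, ceiling(max_media)))
  pd <- predict_detection(curve, mm, ci = ci)
  bound <- if (is.null(ci)) pd$prob else pd$lower
  hit <- which(bound >= p)
  if (!length(hit)) {
    res$reason <- sprintf(
      "lower %s band never reaches %.2f within media <= %d",
      if (is.null(ci)) "curve" else paste0(100 * ci, "% CI"), p, max(mm))
    return(res)
  }
  thr <- mm[hit[1]]
  res$threshold <- as.integer(ceiling(thr / round_up_to) * round_up_to)
  res
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("Detection threshold", if (!is.na(x$clade_id)) paste0("[", x$clade_id, "]"),
      ":", if (is.na(x$threshold)) paste("undefined -", x$reason)
          else paste0(x$threshold, " media (p = ", x$probability_level,
                      ", CI ", x$ci_level, ")"), "\n")
  if (!is.na(x$fallback_clade)) cat("  (from fallback clade", x$fallback_clade, ")\n")
  invisible(x)
}

#' Per-clade detection thresholds with exclusions and fallbacks
#'
#' Fits a detection curve and extracts a threshold for each configured
#' clade. A clade configuration supports (i) an exclusion rule of the kind
#' used for parrots, dropping species with more than a given media count but
#' no detected foot use before fitting (such species genuinely lack the
#' behavior and would distort the detection curve); and (ii) a fallback
#' parent clade whose threshold is reused when the clade has too few species
#' to fit a logistic regression (as done for shrikes and drongos, which
#' borrow the Corvoidea threshold).
#'
#' @param species Species table with columns `species`, `media_count`,
#'   `detected`, and whatever column the clade memberships reference.
#' @param config List (or path to a YAML file) with elements:
#'   `clades`: named list, each with `filter` (list `column`, `values`)
#'   or `species` (explicit vector), optional `exclude_undetected_over`
#'   (media cutoff), optional `fallback` (name of another clade);
#'   optional top-level `p`, `ci`, `min_n` (default 10), `round_up_to`,
#'   `predictor_scale`.
#' @return Named list of `threshold_result` objects, one per clade, each
#'   with `n_fit` (rows used in the fit) attached.
#' @export
clade_threshold_pipeline <- function(species, config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- config$p %||% 0.75
  ci <- config$ci %||% 0.95
  min_n <- config$min_n %||% 10
  round_up_to <- config$round_up_to %||% 1
  scale <- config$predictor_scale %||% "log10"
  clades <- config$clades
  if (is.null(names(clades)) || any(!nzchar(names(clades)))) {
    stop("every clade in the config must be named")
  }

  clade_rows <- lapply(clades, function(cl) {
    if (!is.null(cl$species)) {
      sel <- species$species %in% cl$species
    } else if (!is.null(cl$filter)) {
      sel <- species[[cl$filter$column]] %in% cl$filter$values
    } else {
      stop("clade needs a `species` list or a `filter`")
    }
    rows <- species[sel, , drop = FALSE]
    if (!is.null(cl$exclude_undetected_over)) {
      drop <- rows$media_count > cl$exclude_undetected_over &
        !as.logical(rows$detected)
      rows <- rows[!drop, , drop = FALSE]
    }
    rows
  })

  # detect cycles in the fallback graph before resolving
  fb <- vapply(clades, function(cl) cl$fallback %||% NA_character_, character(1))
  for (start in names(clades)) {
    seen <- character(0)
    cur <- start
    while (!is.na(fb[cur])) {
      if (cur %in% seen) stop("cycle in fallback graph at clade ", cur)
      seen <- c(seen, cur)
      cur <- fb[cur]
      if (!cur %in% names(clades)) stop("unknown fallback clade: ", cur)
    }
  }

  fitted <- list()
  fit_one <- function(name) {
    if (!is.null(fitted[[name]])) return(fitted[[name]])
    rows <- clade_rows[[name]]
    if (nrow(rows) < min_n && !is.na(fb[name])) {
      parent <- fit_one(fb[name])
      res <- parent
      res$clade_id <- name
      res$fallback_clade <- unname(fb[name])
      attr(res, "n_fit") <- nrow(rows)
    } else {
      curve <- fit_detection_curve(rows, predictor_scale = scale)
      res <- detection_threshold(curve, p = p, ci = ci,
                                 round_up_to = round_up_to, clade_id = name)
      attr(res, "n_fit") <- nrow(rows)
      attr(res, "curve") <- curve
    }
    fitted[[name]] <<- res
    res
  }
  out <- lapply(names(clades), fit_one)
  setNames(out, names(clades))
}

#' Tabulate clade thresholds
#'
#' Flattens the result of [clade_threshold_pipeline()] into the shape of a
#' per-clade threshold table (clade, n, coefficients, threshold, flags).
#'
#' @param thresholds Named list from [clade_threshold_pipeline()].
#' @return Data frame, one row per clade.
#' @export
threshold_table <- function(thresholds) {
  out <- do.call(rbind, lapply(names(thresholds), function(nm) {
    th <- thresholds[[nm]]
    cv <- attr(th, "curve")
    data.frame(
      clade = nm, n = attr(th, "n_fit") %||% NA_integer_,
      intercept = if (is.null(cv)) NA_real_ else cv$coefficients[1],
      slope = if (is.null(cv)) NA_real_ else cv$coefficients[2],
      threshold = th$threshold,
      separation = isTRUE(th$separation_flag),
      fallback = th$fallback_clade,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Classify families as codeable or unknown from total media
#'
#' A family with confirmed foot use is always codeable as present, however
#' few media exist. A family with no confirmed foot use is codeable as
#' absent only when its total media availability reaches the cutoff
#' (default 1500, the upper range of clade-level detection thresholds);
#' below it the family enters downstream reconstructions as unknown.
#'
#' @param families Data frame with columns `family`, `total_media`,
#'   `foot_use_confirmed` (logical).
#' @param cutoff Media cutoff (strict `<` comparison; default 1500).
#' @return Data frame with columns `family`, `codeable` (logical), `state`
#'   in `c("present", "absent", "unknown")`.
#' @export
family_data_sufficiency <- function(families, cutoff = 1500) {
  stopifnot(all(c("family", "total_media", "foot_use_confirmed") %in%
                  names(families)))
  if (any(families$total_media < 0)) stop("total_media must be >= 0")
  state <- ifelse(families$foot_use_confirmed, "present",
                  ifelse(families$total_media < cutoff, "unknown", "absent"))
  data.frame(family = families$family, codeable = state != "unknown",
             state = state, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
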