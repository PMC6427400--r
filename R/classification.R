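# Two-species discrimination from per-feature normal models. For each
# feature the decision boundary is the abscissa between the two class means
# where the normal densities intersect; the tail areas beyond it give the
# per-class misclassification probabilities. Events are labeled by majority
# vote over the usable frequency features (magnitude ratios are excluded:
# their class distributions overlap too much to discriminate).

#' Intersection of two normal densities between their means
#'
#' Solves the quadratic obtained by equating the two log-densities and
#' returns the root strictly between the means. With equal SDs this is the
#' midpoint of the means.
#'
#' @param mu1,sd1 mean and SD of the first normal.
#' @param mu2,sd2 mean and SD of the second normal.
#' @return the boundary abscissa x*.
#' @export
gaussian_intersection <- function(mu1, sd1, mu2, sd2) {
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  if (mu1 == mu2) stop("means must differ")
  if (sd1 == sd2) return((mu1 + mu2) / 2)
  a <- 1 / (2 * sd2^2) - 1 / (2 * sd1^2)
  b <- mu1 / sd1^2 - mu2 / sd2^2
  cc <- mu2^2 / (2 * sd2^2) - mu1^2 / (2 * sd1^2) + log(sd2 / sd1)
  roots <- Re(polyroot(c(cc, b, a)))
  lo <- min(mu1, mu2); hi <- max(mu1, mu2)
  between <- roots[roots > lo & roots < hi]
  if (length(between) == 0L)
    stop("no density intersection between the means (mu = ", mu1, ", ", mu2,
         "; sd = ", sd1, ", ", sd2, ")")
  between[1L]
}

#' Misclassification probabilities of two overlapping normal class models
#'
#' With the boundary at the density intersection x*, the probability that a
#' member of the lower-mean class is labeled as the higher-mean class is the
#' upper tail of the low model above x*, and conversely the lower tail of
#' the high model below x*. Identical models overlap completely and give
#' (0.5, 0.5).
#'
#' @param model_low `normal_model` (or list with `mu`, `sigma`) of the
#'   lower-mean class.
#' @param model_high model of the higher-mean class.
#' @return list with `x_star`, `p_low_as_high`, `p_high_as_low`.
#' @export
misclassification_probs <- function(model_low, model_high) {
  if (model_low$mu == model_high$mu && model_low$sigma == model_high$sigma)
    return(list(x_star = model_low$mu, p_low_as_high = 0.5, p_high_as_low = 0.5))
  if (model_low$mu >= model_high$mu)
    stop("model_low must have the smaller mean")
  xs <- gaussian_intersection(model_low$mu, model_low$sigma,
                              model_high$mu, model_high$sigma)
  list(x_star = xs,
       p_low_as_high = stats::pnorm(xs, model_low$mu, model_low$sigma,
                                    lower.tail = FALSE),
       p_high_as_low = stats::pnorm(xs, model_high$mu, model_high$sigma))
}

#' Build a two-species classifier from species profiles
#'
#' Computes, for each shared feature, the Gaussian-intersection decision
#' boundary between the two species models.
#'
#' @param profile_a,profile_b `species_profile` objects (see
#'   [build_profile()]), or lists with `species` and `models`.
#' @param features features to vote with (default the three frequency
#'   features; magnitude ratios are deliberately not offered).
#' @param rule `"majority"` (per-feature votes, majority wins) or
#'   `"likelihood"` (sum of per-feature log-likelihoods).
#' @return a `classifier_model`.
#' @export
build_classifier <- function(profile_a, profile_b,
                             features = c("f0_aut", "f0_fft", "f1_minus_f0"),
                             rule = c("majority", "likelihood")) {
  rule <- match.arg(rule)
  features <- intersect(features,
                        intersect(names(profile_a$models), names(profile_b$models)))
  if (length(features) == 0L) stop("profiles share no requested feature")
  boundaries <- lapply(features, function(fn) {
    ma <- profile_a$models[[fn]]; mb <- profile_b$models[[fn]]
    lowfirst <- ma$mu < mb$mu
    low <- if (lowfirst) ma else mb
    high <- if (lowfirst) mb else ma
    p <- misclassification_probs(low, high)
    list(x_star = p$x_star,
         low_label = if (lowfirst) profile_a$species else profile_b$species,
         high_label = if (lowfirst) profile_b$species else profile_a$species,
         p_low_as_high = p$p_low_as_high, p_high_as_low = p$p_high_as_low)
  })
  names(boundaries) <- features
  structure(list(labels = c(profile_a$species, profile_b$species),
                 profiles = list(profile_a, profile_b),
                 features = features, boundaries = boundaries, rule = rule),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat("classifier_model:", paste(x$labels, collapse = " vs "),
      "| rule:", x$rule, "\n")
  for (fn in x$features) {
    b <- x$boundaries[[fn]]
    cat(sprintf("  %-12s x* = %7.2f  p(%s->%s) = %.4f  p(%s->%s) = %.4f\n",
                fn, b$x_star, b$low_label, b$high_label, b$p_low_as_high,
                b$high_label, b$low_label, b$p_high_as_low))
  }
  invisible(x)
}

usable_value <- function(model, fn, value) {
  if (is.na(value) || !is.finite(value)) return(FALSE)
  # a value is usable when it lies inside at least one species' octave gate
  ok <- vapply(model$profiles, function(p) {
    g <- p$gates[[fn]] %||% c(-Inf, Inf)
    value >= g[1L] && value <= g[2L]
  }, TRUE)
  any(ok)
}

#' Classify one event from its feature values
#'
#' Majority rule: each usable feature votes for the species on whose side of
#' the feature's decision boundary the value falls; the final label is the
#' majority of votes, with ties (or no usable feature) labeled `"unknown"`.
#' Likelihood rule: the label maximizing the summed per-feature normal
#' log-likelihoods.
#'
#' @param features named list/one-row data.frame of feature values.
#' @param model a `classifier_model`.
#' @return list with `label`, `votes` (named character of per-feature
#'   votes), `confidence` (fraction of agreeing votes; NA for likelihood
#'   rule).
#' @export
classify_event <- function(features, model) {
  stopifnot(inherits(model, "classifier_model"))
  votes <- character(0)
  if (model$rule == "likelihood") {
    ll <- c(0, 0)
    used <- 0L
    for (fn in model$features) {
      v <- features[[fn]]
      if (!usable_value(model, fn, v)) next
      used <- used + 1L
      for (j in 1:2) {
        m <- model$profiles[[j]]$models[[fn]]
        ll[j] <- ll[j] + stats::dnorm(v, m$mu, m$sigma, log = TRUE)
      }
    }
    if (used == 0L || ll[1L] == ll[2L])
      return(list(label = "unknown", votes = votes, confidence = NA_real_))
    return(list(label = model$labels[which.max(ll)], votes = votes,
                confidence = NA_real_))
  }
  for (fn in model$features) {
    v <- features[[fn]]
    if (!usable_value(model, fn, v)) next
    b <- model$boundaries[[fn]]
    votes[fn] <- if (v < b$x_star) b$low_label
                 else if (v > b$x_star) b$high_label
                 else NA_character_
  }
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0L)
    return(list(label = "unknown", votes = votes, confidence = NA_real_))
  tab <- table(votes)
  top <- tab[tab == max(tab)]
  label <- if (length(top) > 1L) "unknown" else names(top)
  list(label = label, votes = votes,
       confidence = max(tab) / length(votes))
}

#' Classify every row of a feature table
#'
#' @param features data.frame from [event_features()].
#' @param model a `classifier_model`.
#' @return data.frame with `event_id` (if present), `label`, `confidence`
#'   and one vote column per feature.
#' @export
classify_events <- function(features, model) {
  out <- lapply(seq_len(nrow(features)), function(i) {
    r <- classify_event(as.list(features[i, ]), model)
    v <- stats::setNames(rep(NA_character_, length(model$features)),
                         paste0("vote_", model$features))
    if (length(r$votes) > 0L) v[paste0("vote_", names(r$votes))] <- r$votes
    c(list(label = r$label, confidence = r$confidence), as.list(v))
  })
  res <- do.call(rbind, lapply(out, as.data.frame))
  if ("event_id" %in% names(features))
    res <- cbind(event_id = features$event_id, res)
  res
}

#' Evaluate a classifier against labeled events
#'
#' @param model a `classifier_model`.
#' @param features data.frame of feature values with a `label` column of
#'   true species labels.
#' @return list with `confusion` (true x predicted table, including
#'   "unknown"), `error_rate` (misclassified / labeled, unknowns excluded
#'   from the denominator's errors but reported), and `per_feature`
#'   (empirical single-feature error rates, for comparison against the
#'   Gaussian-overlap predictions).
#' @export
evaluate_classifier <- function(model, features) {
  stopifnot(nrow(features) >= 1L, "label" %in% names(features))
  pred <- classify_events(features, model)$label
  truth <- features$label
  confusion <- table(truth = truth,
                     predicted = factor(pred, levels = c(model$labels, "unknown")))
  decided <- pred != "unknown"
  errors <- sum(pred[decided] != truth[decided])
  per_feature <- lapply(model$features, function(fn) {
    b <- model$boundaries[[fn]]
    v <- features[[fn]]
    ok <- vapply(v, function(x) usable_value(model, fn, x), TRUE)
    if (!any(ok)) return(list(n = 0L, errors = 0L, rate = NA_real_))
    single <- ifelse(v[ok] < b$x_star, b$low_label, b$high_label)
    err <- sum(single != truth[ok])
    list(n = sum(ok), errors = err, rate = err / sum(ok))
  })
  names(per_feature) <- model$features
  list(confusion = confusion,
       error_rate = if (sum(decided) > 0L) errors / sum(decided) else NA_real_,
       n_unknown = sum(!decided),
       per_feature = per_feature)
}
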