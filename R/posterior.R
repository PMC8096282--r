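#' Estimate class priors from pair counts
#'
#' Priors are the fractions of pattern-position pairs residing in true vs
#' false loops of the training ensemble.
#'
#' @param n_true_pairs,n_false_pairs Non-negative counts.
#' @return Named numeric `c(prior_true, prior_false)` summing to 1.
#' @export
#' @examples
#' estimate_priors(549, 451) # c(0.549, 0.451)
estimate_priors <- function(n_true_pairs, n_false_pairs) {
  stopifnot(n_true_pairs >= 0, n_false_pairs >= 0)
  tot <- n_true_pairs + n_false_pairs
  if (tot == 0) stop("both counts are zero; priors undefined")
  c(prior_true = n_true_pairs / tot, prior_false = n_false_pairs / tot)
}

#' Construct a posterior loop-classification model
#'
#' Combines class priors with fitted class-conditional densities of the
#' pattern-pair SHAPE difference `D` (reactivity at the pattern's high
#' position minus its low position). `prior_true` is the prior probability
#' that a pattern pair resides in a true loop.
#'
#' @param f_true,f_false `class_conditional` objects from
#'   [fit_class_conditional()] (NIG for true loops, Johnson's SU for false).
#' @param prior_true,prior_false Priors in (0, 1) summing to 1.
#' @return A `posterior_model` object.
#' @export
posterior_model <- function(f_true, f_false, prior_true = 0.549,
                            prior_false = 1 - prior_true) {
  stopifnot(inherits(f_true, "class_conditional"),
            inherits(f_false, "class_conditional"),
            prior_true > 0, prior_true < 1,
            abs(prior_true + prior_false - 1) < 1e-9)
  structure(list(prior_true = prior_true, prior_false = prior_false,
                 f_true = f_true, f_false = f_false),
            class = "posterior_model")
}

#' Fit a posterior model from training differences
#'
#' @param true_d,false_d Difference samples from true / false loops, e.g.
#'   from [make_training_differences()].
#' @param priors Optional priors; by default estimated from the sample
#'   counts via [estimate_priors()].
#' @return A `posterior_model`.
#' @export
fit_posterior_model <- function(true_d, false_d, priors = NULL) {
  pr <- priors %||% estimate_priors(length(true_d), length(false_d))
  posterior_model(fit_class_conditional(true_d, "true"),
                  fit_class_conditional(false_d, "false"),
                  prior_true = pr[[1]], prior_false = pr[[2]])
}

#' @export
print.posterior_model <- function(x, ...) {
  cat("<posterior_model> priors (true, false) = (",
      signif(x$prior_true, 4), ", ", signif(x$prior_false, 4), ")\n", sep = "")
  cat("  f_true : ", x$f_true$family, "\n", sep = "")
  cat("  f_false: ", x$f_false$family, "\n", sep = "")
  invisible(x)
}

#' Posterior probability that a pattern pair lies in a true loop
#'
#' Bayes' rule over the two class-conditional densities:
#' `P(true | D) = p_t f_t(D) / (p_t f_t(D) + p_f f_f(D))`, evaluated in log
#' space. Where both densities underflow to zero the datum is uninformative
#' and the prior is returned with a warning.
#'
#' @param model A `posterior_model`.
#' @param d Numeric vector of observed differences.
#' @return Posterior probabilities in `[0, 1]`.
#' @export
posterior_prob <- function(model, d) {
  la <- log(model$prior_true) +
    cc_log_density(model$f_true$family, model$f_true$params, d)
  lb <- log(model$prior_false) +
    cc_log_density(model$f_false$family, model$f_false$params, d)
  p <- 1 / (1 + exp(lb - la))
  dead <- !is.finite(la) & !is.finite(lb)
  if (any(dead)) {
    warning("density underflow at ", sum(dead),
            " value(s); returning the prior")
    p[dead] <- model$prior_true
  }
  # one-sided underflow: the informative side wins outright
  p[is.finite(la) & !is.finite(lb)] <- 1
  p[!is.finite(la) & is.finite(lb)] <- 0
  p
}

#' Log-odds penalty of a posterior probability
#'
#' `-ln(p / (1 - p))`: positive exactly when `p < 0.5`, zero at even odds.
#' Probabilities at 0 or 1 are clipped to `[1e-12, 1 - 1e-12]` with a
#' warning.
#'
#' @param p Posterior probabilities.
#' @return Penalty values.
#' @export
#' @examples
#' log_odds_penalty(0.5)          # 0
#' log_odds_penalty(1 / (1 + exp(1))) # 1
log_odds_penalty <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    warning("posterior at 0 or 1 clipped before taking log odds")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  -log(p / (1 - p))
}

#' Per-loop posterior penalties
#'
#' Applies every characteristic pattern of a loop's motif to its SHAPE
#' reactivities: for each pattern the difference `D` (high minus low
#' position, skipped when either value is missing), its posterior and its
#' log-odds penalty are computed. The loop penalty sums the penalties of
#' pairs whose posterior is strictly below `posterior_cutoff` (each such
#' term is positive); it is 0 when no pair falls below the cutoff or no
#' pair is evaluable. Loops of motifs with no characteristic pattern are
#' flagged `patterns_available = FALSE` with penalty `NA`.
#'
#' @param loops A loop tibble from [extract_loops()] (or an [rna_structure],
#'   whose loops are extracted first).
#' @param profile A `shape_profile` covering the structure.
#' @param patterns A pattern tibble (see [identify_patterns()]).
#' @param model A `posterior_model`.
#' @param posterior_cutoff Inclusion threshold for the penalty sum
#'   (default 0.5, i.e. pairs more likely false than true).
#' @return The loop tibble with added columns `patterns_available`,
#'   `n_pairs_evaluated`, `n_pairs_failing`, `penalty` and a `pairs`
#'   list-column of per-pattern records (`high_pos`, `low_pos`, `d`,
#'   `posterior`, `delta`).
#' @export
loop_penalties <- function(loops, profile, patterns, model,
                           posterior_cutoff = 0.5) {
  if (inherits(loops, "rna_structure")) loops <- extract_loops(loops)
  n <- nrow(loops)
  avail <- logical(n); pen <- rep(NA_real_, n)
  nev <- integer(n); nfail <- integer(n)
  pair_records <- vector("list", n)
  for (k in seq_len(n)) {
    m <- loops$motif[k]
    pats <- patterns[patterns$motif == m, , drop = FALSE]
    avail[k] <- nrow(pats) > 0L
    if (!avail[k]) {
      pair_records[[k]] <- empty_pair_record()
      next
    }
    mp <- motif_positions(loops$loop_type[k], loops$sides[[k]])
    hi <- mp[pats$high_pos]; lo <- mp[pats$low_pos]
    d <- as.numeric(profile[hi]) - as.numeric(profile[lo])
    ok <- !is.na(d)
    post <- rep(NA_real_, length(d))
    del <- rep(NA_real_, length(d))
    if (any(ok)) {
      post[ok] <- posterior_prob(model, d[ok])
      del[ok] <- log_odds_penalty(post[ok])
    }
    fails <- ok & post < posterior_cutoff
    pen[k] <- if (any(fails)) sum(del[fails]) else 0
    nev[k] <- sum(ok); nfail[k] <- sum(fails)
    pair_records[[k]] <- tibble::tibble(
      high_pos = pats$high_pos, low_pos = pats$low_pos,
      seq_high = hi, seq_low = lo, d = d, posterior = post, delta = del
    )
  }
  dplyr::mutate(loops, patterns_available = avail,
                n_pairs_evaluated = nev, n_pairs_failing = nfail,
                penalty = pen, pairs = pair_records)
}

empty_pair_record <- function() {
  tibble::tibble(high_pos = integer(), low_pos = integer(),
                 seq_high = integer(), seq_low = integer(),
                 d = numeric(), posterior = numeric(), delta = numeric())
}

#' Save / load a posterior model as JSON
#'
#' Serializes priors, family names, parameter vectors and KS p-values with
#' full double precision, so reloaded models reproduce posteriors exactly.
#'
#' @param model A `posterior_model`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    prior_true = model$prior_true,
    prior_false = model$prior_false,
    f_true = list(family = model$f_true$family,
                  params = as.list(model$f_true$params),
                  ks_p = model$f_true$ks_p, n = model$f_true$n),
    f_false = list(family = model$f_false$family,
                   params = as.list(model$f_false$params),
                   ks_p = model$f_false$ks_p, n = model$f_false$n)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()`: a `posterior_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(o) {
    structure(list(family = o$family, params = unlist(o$params),
                   ks_p = o$ks_p %||% NA_real_, loglik = NA_real_,
                   n = o$n %||% NA_integer_),
              class = "class_conditional")
  }
  posterior_model(mk(obj$f_true), mk(obj$f_false),
                  prior_true = obj$prior_true, prior_false = obj$prior_false)
}
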