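#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a posterior model
#'
#' One row per fitted class-conditional parameter.
#'
#' @param x A `posterior_model`.
#' @param ... Unused.
#' @return Tibble: `class`, `family`, `term`, `estimate`.
#' @export
tidy.posterior_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(class = "true", family = x$f_true$family,
                   term = names(x$f_true$params),
                   estimate = unname(x$f_true$params)),
    tibble::tibble(class = "false", family = x$f_false$family,
                   term = names(x$f_false$params),
                   estimate = unname(x$f_false$params))
  )
}

#' Glance at a posterior model
#'
#' @param x A `posterior_model`.
#' @param ... Unused.
#' @return One-row tibble with priors, KS p-values and training sizes.
#' @export
glance.posterior_model <- function(x, ...) {
  tibble::tibble(
    prior_true = x$prior_true, prior_false = x$prior_false,
    ks_p_true = x$f_true$ks_p, ks_p_false = x$f_false$ks_p,
    n_true = x$f_true$n, n_false = x$f_false$n
  )
}

#' Tidy a refinement result
#'
#' @param x A `refinement_result` from [select_structure()].
#' @param ... Unused.
#' @return The per-candidate audit tibble (without the nested loop
#'   tables).
#' @export
tidy.refinement_result <- function(x, ...) {
  dplyr::select(x$audit, -"loops")
}

#' Glance at a refinement result
#'
#' @param x A `refinement_result`.
#' @param ... Unused.
#' @return One-row tibble: chosen index, fallback flag, total penalty and
#'   guidance loop-category counts.
#' @export
glance.refinement_result <- function(x, ...) {
  tibble::tibble(
    chosen_index = x$chosen_index,
    fallback_used = x$fallback_used,
    total_penalty = x$total_penalty,
    n_candidates = nrow(x$audit),
    n_good = sum(x$assessments$category == "good"),
    n_fair = sum(x$assessments$category == "fair"),
    n_poor = sum(x$assessments$category == "poor")
  )
}
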