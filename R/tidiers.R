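#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-mode tidy summary of a bounded landmark fit
#'
#' @param x an `ssm_fit`.
#' @param ... unused.
#' @return tibble with one row per retained mode: `mode`, `score_mm`,
#'   `bound_active`.
#' @exportS3Method generics::tidy
tidy.ssm_fit <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$scores), score_mm = x$scores,
                 bound_active = x$bound_active)
}

#' One-row summary of a bounded landmark fit
#'
#' @param x an `ssm_fit`.
#' @param ... unused.
#' @return tibble: `config`, `k_sd`, `objective_mm2`, `iterations`,
#'   `converged`, `n_active_bounds`.
#' @exportS3Method generics::glance
glance.ssm_fit <- function(x, ...) {
  tibble::tibble(config = x$config, k_sd = x$k_sd, objective_mm2 = x$objective,
                 iterations = x$iterations, converged = x$converged,
                 n_active_bounds = sum(x$bound_active))
}

#' Tidy per-muscle forces of a static-optimization solution
#'
#' @param x a `muscle_solution`.
#' @param ... unused.
#' @return the per-muscle force/stress tibble.
#' @exportS3Method generics::tidy
tidy.muscle_solution <- function(x, ...) x$forces

#' One-row summary of a static-optimization solution
#'
#' @param x a `muscle_solution`.
#' @param ... unused.
#' @return tibble: `objective`, `max_residual_Nm`, `n_active`.
#' @exportS3Method generics::glance
glance.muscle_solution <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 max_residual_Nm = max(abs(x$residual_Nm)),
                 n_active = sum(x$forces$force_N > 0))
}

#' Tidy pairwise table of a condition comparison
#' @param x a `condition_comparison`. @param ... unused.
#' @return the pairwise post-hoc tibble.
#' @exportS3Method generics::tidy
tidy.condition_comparison <- function(x, ...) x$pairwise

#' Main-effect row of a condition comparison
#' @param x a `condition_comparison`. @param ... unused.
#' @return one-row tibble (Friedman main effect + Kendall's W).
#' @exportS3Method generics::glance
glance.condition_comparison <- function(x, ...) x$main

#' Per-participant table of a method-agreement analysis
#' @param x a `method_agreement`. @param ... unused.
#' @return per-participant tibble with both methods' percentage changes.
#' @exportS3Method generics::tidy
tidy.method_agreement <- function(x, ...) x$table

#' One-row summary of a method-agreement analysis
#' @param x a `method_agreement`. @param ... unused.
#' @return summary tibble (mean/SD absolute difference, concordance).
#' @exportS3Method generics::glance
glance.method_agreement <- function(x, ...) x$summary
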