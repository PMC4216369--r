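#' Tidy a test result
#'
#' One-row tibble view of a [mir_test][new_mir_test]: statistic, p-value,
#' method, exactness, total n.
#'
#' @param x a `mir_test`.
#' @param ... unused.
#'
#' @return A one-row tibble.
#' @method tidy mir_test
#' @export
tidy.mir_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p_value, method = x$method,
    exact = x$exact, n = sum(x$n_used)
  )
}

#' @rdname tidy.mir_test
#' @method glance mir_test
#' @export
glance.mir_test <- function(x, ...) tidy.mir_test(x)

#' Tidy a Cox proportional-hazards result
#'
#' @param x a `cox_result` from [coxph_fit()].
#' @param ... unused.
#'
#' @return Term-level tibble with `term`, `estimate` (log hazard ratio),
#'   `std.error`, `statistic` (Wald z), `p.value`.
#' @method tidy cox_result
#' @export
tidy.cox_result <- function(x, ...) {
  tibble::tibble(
    term = x$term, estimate = x$estimate, std.error = x$std_error,
    statistic = x$z, p.value = x$p
  )
}

#' @rdname tidy.cox_result
#' @method glance cox_result
#' @export
glance.cox_result <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"), converged = attr(x, "converged"),
    logLik = attr(x, "loglik")[2]
  )
}
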