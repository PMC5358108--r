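#' Average profiles (or ECDF curves) across aggregates
#'
#' Interpolates each aggregate's curve onto a common 101-point grid on
#' [0, 100] ru (unit resolution) and returns the pointwise mean with an
#' error half-width per channel — the "mean profile with shaded error"
#' summary of a cohort.
#'
#' @param profiles list of >= 2 `lam_nprofile` or `lam_ecdf` objects.
#' @param error `"sem"` (standard error of the mean, default) or `"sd"`.
#' @return a `lam_meanprofile` tibble: `channel`, `x`, `mean`, `err`,
#'   `n`; attribute `value` names the averaged quantity (`density` or
#'   `F`).
#' @export
average_profiles <- function(profiles, error = c("sem", "sd")) {
  error <- match.arg(error)
  if (length(profiles) < 2) stop("need at least 2 profiles to average")
  value <- if ("density" %in% names(profiles[[1]])) "density" else "F"
  grid <- 0:100
  long <- purrr::imap(profiles, function(p, i) {
    p |>
      dplyr::group_by(.data$channel) |>
      dplyr::reframe(value = approx(.data$x, .data[[value]], xout = grid, rule = 2)$y,
                     x = grid) |>
      dplyr::mutate(id = i)
  }) |> dplyr::bind_rows()
  out <- long |>
    dplyr::group_by(.data$channel, .data$x) |>
    dplyr::summarise(
      n = dplyr::n(),
      err = if (error == "sem") sd(.data$value) / sqrt(dplyr::n()) else sd(.data$value),
      mean = mean(.data$value),
      .groups = "drop") |>
    dplyr::select("channel", "x", "mean", "err", "n")
  structure(out, class = c("lam_meanprofile", class(tibble::tibble())),
            error = error, value = value)
}

#' Two-tailed Mann-Whitney U test between two score groups
#'
#' The U statistic counts, over all cross-group pairs, how often a value
#' in `a` exceeds one in `b`, with half credit for ties. The two-tailed
#' p-value is exact (full enumeration of the rank distribution) when the
#' combined sample is small (`n1 + n2 <= 25`) and tie-free, and otherwise
#' uses the normal approximation with tie and continuity correction.
#'
#' @param a,b numeric score vectors (each nonempty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   default `NULL` chooses by the rule above. Exact p-values are not
#'   available with ties.
#' @return a `lam_mwtest` object with fields `U`, `n1`, `n2`, `p_value`,
#'   `method`; see [tidy()] and [glance()].
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- if (is.null(exact)) (length(a) + length(b) <= 25) && !ties
               else isTRUE(exact) && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE, alternative = "two.sided"))
  structure(list(U = unname(wt$statistic),
                 n1 = length(a), n2 = length(b),
                 p_value = min(1, wt$p.value),
                 method = if (use_exact) "exact"
                          else "normal approximation (tie/continuity corrected)"),
            class = "lam_mwtest")
}

#' @export
print.lam_mwtest <- function(x, ...) {
  cat(sprintf("Mann-Whitney two-tailed test: U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Tidy a Mann-Whitney test result
#'
#' @param x a `lam_mwtest`.
#' @param ... unused.
#' @return a one-row tibble with `statistic` (U), `n1`, `n2`, `p.value`
#'   and `method`.
#' @exportS3Method generics::tidy
tidy.lam_mwtest <- function(x, ...) {
  tibble::tibble(statistic = x$U, n1 = x$n1, n2 = x$n2,
                 p.value = x$p_value, method = x$method)
}

#' @rdname tidy.lam_mwtest
#' @exportS3Method generics::glance
glance.lam_mwtest <- function(x, ...) tidy(x)
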