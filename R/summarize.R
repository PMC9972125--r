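#' Equal-tail interval of a sample
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2`, using the
#' type-7 (linear interpolation) quantile rule so limits are bit-reproducible
#' across implementations. The reported median elsewhere in the package is
#' the 50th percentile under the same rule.
#'
#' @param x Numeric vector of draws.
#' @param level Interval mass, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' equal_tail_interval(rnorm(1e4))
#' @export
equal_tail_interval <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (length(x) < 20) warn("fewer than 20 draws; tail quantiles are poorly resolved")
  alpha <- (1 - level) / 2
  q <- quantile(x, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Highest-density interval of a sample
#'
#' The shortest interval spanning `ceiling(level * length(x))` consecutive
#' order statistics — the empirical shortest-interval construction of an HPD
#' interval, meaningful for unimodal samples. Ties between equally short
#' windows are broken deterministically in favour of the lowest lower limit.
#'
#' @inheritParams equal_tail_interval
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rexp(1e4))   # hugs zero, narrower than equal-tail
#' @export
hpd_interval <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (length(x) < 20) warn("fewer than 20 draws; the HPD interval is poorly resolved")
  xs <- sort(x)
  S <- length(xs)
  m <- ceiling(level * S)
  if (m >= S) return(c(lower = xs[1], upper = xs[S]))
  widths <- xs[m:S] - xs[1:(S - m + 1)]
  i <- which.min(widths)  # first minimum = lowest lower limit
  c(lower = xs[i], upper = xs[i + m - 1])
}

#' Summarize index draws with medians and 95% intervals
#'
#' Reduces a draw matrix (bootstrap empirical distribution or posterior
#' distribution of the four indices) to the reporting layout: median,
#' equal-tail limits and HPD limits per index.
#'
#' @param draws An `index_draws` object from [bootstrap_indices()] or
#'   [posterior_indices()], or any data frame with columns `rate`,
#'   `sensitivity`, `specificity`, `consistency`.
#' @param level Interval mass, default 0.95.
#' @return A tibble with one row per index: `index`, `median`, `eq_lower`,
#'   `eq_upper`, `hpd_lower`, `hpd_upper`, `level`.
#' @examples
#' X <- sim_responses(sim_params(0.5, 5, seed = 1), n = 200, seed = 2)
#' d <- bootstrap_indices(X, cutpoints(cut_sd = 0), resamples = 50, seed = 3)
#' summarize_draws(d)
#' @export
summarize_draws <- function(draws, level = 0.95) {
  cols <- c("rate", "sensitivity", "specificity", "consistency")
  missing <- setdiff(cols, names(draws))
  if (length(missing)) {
    abort(paste0("draws lack index columns: ", paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(cols, function(nm) {
    x <- draws[[nm]]
    eq <- equal_tail_interval(x, level)
    hpd <- hpd_interval(x, level)
    tibble(
      index = nm,
      median = quantile(x, 0.5, names = FALSE, type = 7),
      eq_lower = eq[["lower"]], eq_upper = eq[["upper"]],
      hpd_lower = hpd[["lower"]], hpd_upper = hpd[["upper"]],
      level = level
    )
  })
}

# Constructor shared by the bootstrap and the posterior propagation.
new_index_draws <- function(df, source, n_failed = 0L, cut = NULL) {
  out <- as_tibble(df)
  attr(out, "source") <- source
  attr(out, "n_failed") <- as.integer(n_failed)
  attr(out, "cut") <- cut
  class(out) <- c("index_draws", class(out))
  out
}

#' @export
print.index_draws <- function(x, ...) {
  cat(sprintf("<index_draws> %d %s draws (%d discarded)\n",
              nrow(x), attr(x, "source"), attr(x, "n_failed")))
  NextMethod()
}

#' Density plot of index draws
#'
#' One density panel per index — the visual counterpart of
#' [summarize_draws()].
#'
#' @param object An `index_draws` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.index_draws <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("rate", "sensitivity", "specificity", "consistency")],
    dplyr::everything(), names_to = "index", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(
      x = "index value", y = "density",
      title = sprintf("%s distribution of classification indices",
                      attr(object, "source"))
    )
}
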