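#' Factorial conditions of the coverage study
#'
#' The crossed data-generating conditions: sample size, number of items and
#' average loading. The default grid is the 18-cell design (2 sample sizes
#' x 3 average loadings x 3 numbers of items); cutpoints, interval types,
#' index types and interval methods multiply the number of evaluated
#' intervals but not the number of generating cells.
#'
#' @param n Sample sizes. Default `c(200, 500)`.
#' @param n_items Numbers of items. Default `c(5, 10, 20)`.
#' @param loading Average loadings. Default `c(0.5, 0.6, 0.7)`.
#' @return A tibble with one row per condition.
#' @examples
#' sim_conditions()
#' @export
sim_conditions <- function(n = c(200, 500), n_items = c(5, 10, 20),
                           loading = c(0.5, 0.6, 0.7)) {
  tidyr::expand_grid(n = n, n_items = n_items, loading = loading)
}

#' Number of summary intervals a design evaluates
#'
#' Expands the full factorial bookkeeping: conditions x replications x
#' indices x cutpoints x interval types x interval methods. At the
#' reference design (18 conditions, 1,000 replications, 4 indices, 3
#' cutpoints, 2 interval types, 3 methods) this is 1,296,000.
#'
#' @param conditions A tibble from [sim_conditions()].
#' @param replications Replications per condition. Default 1000.
#' @param indices,cutpoints,intervals,methods Multiplicities of the
#'   evaluation factors.
#' @return Integer count of summary intervals.
#' @examples
#' sim_design_size()
#' @export
sim_design_size <- function(conditions = sim_conditions(),
                            replications = 1000, indices = 4,
                            cutpoints = 3, intervals = 2, methods = 3) {
  nrow(conditions) * replications * indices * cutpoints * intervals * methods
}

#' Run one simulation condition
#'
#' Scores one interval method in one generating condition. A single true
#' parameter set is drawn for the condition ([sim_params()]) and held fixed;
#' cutpoints are resolved once against its implied moments and also held
#' fixed across replications, so every replication is scored against the
#' same true index values. Per replication: simulate `n` responses, build
#' the method's draw matrix (bootstrap refits, or Gibbs posterior draws
#' propagated to indices), summarize with [summarize_draws()], and score
#' both interval types against the truth.
#'
#' Defaults are desk scale (200 replications, 200 bootstrap resamples, 2
#' chains x 2,000 iterations with burn-in 500 and thin 4);
#' `full_scale = TRUE` restores 1,000 replications, 500 resamples and 3
#' chains x 5,000 iterations (burn-in 1,000, thin 4).
#'
#' @param n,n_items,loading One generating condition (see
#'   [sim_conditions()]).
#' @param cut_sd Standardized cutpoint offset (0, 0.75 or 1.5 in the
#'   reference design). Default 0.
#' @param method `"bootstrap"`, `"bayes_diffuse"` or `"bayes_empirical"`.
#' @param replications Monte-Carlo replications.
#' @param resamples Bootstrap resamples per replication.
#' @param chains,iterations,burnin,thin Gibbs schedule per replication.
#' @param pseudo_n Pseudo sample size for empirical priors. Default 20.
#' @param level Interval mass. Default 0.95.
#' @param seed Root seed; the generating parameters and every replication
#'   use spawned child seeds.
#' @param direction Positive-decision side, see [cutpoints()].
#' @param full_scale Use the full-scale settings? Default `FALSE`.
#' @return A tibble with one row per index x interval type: the condition
#'   columns, `truth`, `coverage`, `balance_left`, `balance_right`
#'   (coverage + balance_left + balance_right = 1 exactly), `rel_bias` of
#'   the mean median estimate, `mean_width`, `n_failed` and `replications`.
#'   Conditions with more than 5% failed replications carry `flagged =
#'   TRUE`.
#' @examples
#' run_condition(n = 200, n_items = 5, loading = 0.5, method = "bootstrap",
#'               replications = 5, resamples = 30, seed = 1)
#' @export
run_condition <- function(n, n_items, loading, cut_sd = 0,
                          method = c("bootstrap", "bayes_diffuse", "bayes_empirical"),
                          replications = 200, resamples = 200,
                          chains = 2, iterations = 2000, burnin = 500,
                          thin = 4, pseudo_n = 20, level = 0.95, seed = 1,
                          direction = c("above", "below"),
                          full_scale = FALSE) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  if (full_scale) {
    replications <- 1000; resamples <- 500
    chains <- 3; iterations <- 5000; burnin <- 1000; thin <- 4
  }

  seeds <- spawn_seeds(seed, replications + 1L)
  gen_params <- sim_params(loading, n_items, seed = seeds[1])
  cut <- resolve_cutpoints(cutpoints(cut_sd = cut_sd, direction = direction),
                           implied_moments(gen_params))
  truth <- classification_indices(gen_params, cut)

  idx_names <- c("rate", "sensitivity", "specificity", "consistency")
  n_failed <- 0L
  summaries <- vector("list", replications)
  for (r in seq_len(replications)) {
    rs <- spawn_seeds(seeds[r + 1L], 2L)
    res <- tryCatch({
      X <- sim_responses(gen_params, n, seed = rs[1])
      draws <- switch(
        method,
        bootstrap = bootstrap_indices(X, cut, resamples = resamples,
                                      seed = rs[2]),
        bayes_diffuse = posterior_indices(
          gibbs_lfm(X, prior_diffuse(n_items), chains = chains,
                    iterations = iterations, burnin = burnin, thin = thin,
                    seed = rs[2]),
          cut
        ),
        bayes_empirical = {
          ml <- fit_lfm(X)
          posterior_indices(
            gibbs_lfm(X, prior_empirical(ml, pseudo_n = pseudo_n),
                      chains = chains, iterations = iterations,
                      burnin = burnin, thin = thin, seed = rs[2]),
            cut
          )
        }
      )
      summarize_draws(draws, level = level)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L
    summaries[[r]] <- res
  }

  ok <- !vapply(summaries, is.null, logical(1))
  if (n_failed > 0.05 * replications) {
    warn(sprintf("condition flagged: %d of %d replications failed",
                 n_failed, replications))
  }
  if (!any(ok)) abort("every replication failed; nothing to score")

  all_sum <- dplyr::bind_rows(summaries[ok])
  truth_long <- tibble(index = idx_names, truth = as.numeric(truth[1, idx_names]))

  scored <- all_sum |>
    tidyr::pivot_longer(
      cols = c("eq_lower", "eq_upper", "hpd_lower", "hpd_upper"),
      names_to = c("interval", ".value"), names_sep = "_"
    ) |>
    dplyr::mutate(interval = dplyr::recode(.data$interval,
                                           eq = "equal_tail", hpd = "hpd")) |>
    dplyr::left_join(truth_long, by = "index") |>
    dplyr::group_by(.data$index, .data$interval) |>
    dplyr::summarise(
      truth = .data$truth[1],
      coverage = mean(.data$truth <= .data$upper & .data$truth >= .data$lower),
      balance_left = mean(.data$truth < .data$lower),
      balance_right = mean(.data$truth > .data$upper),
      rel_bias = (mean(.data$median) - .data$truth[1]) / .data$truth[1],
      mean_width = mean(.data$upper - .data$lower),
      .groups = "drop"
    )

  dplyr::bind_cols(
    tibble(n = n, n_items = n_items, loading = loading, cut_sd = cut_sd,
           method = method)[rep(1, nrow(scored)), ],
    scored,
    tibble(n_failed = n_failed, replications = replications,
           flagged = n_failed > 0.05 * replications)[rep(1, nrow(scored)), ]
  )
}

#' Tabulate simulation results in the coverage-and-balance layout
#'
#' Formats rows of [run_condition()] output as
#' `coverage[balance_left,balance_right]` cells, one column per average
#' loading, with cells whose coverage falls outside the acceptability band
#' marked by `*`.
#'
#' @param results A tibble of [run_condition()] rows.
#' @param band Acceptable coverage band. Default `c(0.925, 0.975)`.
#' @return A tibble with identifying columns `method`, `interval`, `index`,
#'   `n_items`, `n` and one formatted column per loading; empty input
#'   yields an empty tibble.
#' @export
results_table <- function(results, band = c(0.925, 0.975)) {
  if (nrow(results) == 0) return(tibble())
  results |>
    dplyr::mutate(
      cell = sprintf("%.3f[%.3f,%.3f]%s", .data$coverage,
                     .data$balance_left, .data$balance_right,
                     ifelse(.data$coverage < band[1] | .data$coverage > band[2],
                            "*", "")),
      loading = paste0("f=", .data$loading)
    ) |>
    dplyr::select(dplyr::all_of(c("method", "interval", "index", "n_items",
                                  "n", "loading", "cell"))) |>
    tidyr::pivot_wider(names_from = "loading", values_from = "cell") |>
    dplyr::arrange(.data$method, .data$interval, .data$index,
                   .data$n_items, .data$n)
}
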