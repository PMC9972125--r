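#' Write a simulated dataset with its generating-parameter sidecar
#'
#' Saves an item-response matrix as CSV (header row = item names) together
#' with a JSON sidecar (`<path>.json`) recording the generating parameters
#' and seed, so any fixture on disk can be regenerated or audited.
#'
#' @param params An [lfm_params] object.
#' @param n Number of respondents to simulate.
#' @param seed Integer seed for the response simulation (required here:
#'   fixtures must be reproducible).
#' @param path CSV file path; the sidecar is written alongside as
#'   `<path>.json`.
#' @return Invisibly, the simulated tibble.
#' @examples
#' p <- sim_params(0.6, 4, seed = 1)
#' path <- file.path(tempdir(), "toy.csv")
#' write_sim_fixture(p, n = 20, seed = 2, path = path)
#' read_sim_fixture(path)$params
#' @export
write_sim_fixture <- function(params, n, seed, path) {
  params <- as_lfm_params(params)
  X <- sim_responses(params, n, seed = seed)
  utils::write.csv(X, path, row.names = FALSE)
  sidecar <- list(
    n = n, seed = seed,
    loadings = params$loadings, intercepts = params$intercepts,
    residual_variances = params$residual_variances,
    latent_mean = params$latent_mean, latent_variance = params$latent_variance
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(X)
}

#' @describeIn write_sim_fixture read a fixture back; returns a list with
#'   the response tibble (`data`), the generating [lfm_params] (`params`),
#'   `n` and `seed`.
#' @export
read_sim_fixture <- function(path) {
  data <- as_tibble(utils::read.csv(path, check.names = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(
    data = data,
    params = lfm_params(
      loadings = side$loadings, intercepts = side$intercepts,
      residual_variances = side$residual_variances,
      latent_mean = side$latent_mean, latent_variance = side$latent_variance
    ),
    n = side$n, seed = side$seed
  )
}
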