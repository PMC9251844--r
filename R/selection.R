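#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`. When `n <= k + 1` the
#' correction is undefined and `Inf` is returned, which removes the model
#' from selection.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Effective sample size.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Simplest-model rule over an AICc table
#'
#' Among the most parsimonious models (those within `delta` AICc units of
#' the best), selects the one with the fewest parameters, avoiding the
#' retention of uninformative parameters. Ties on parameter count go to the
#' lower AICc.
#'
#' @param aicc_values Numeric vector of AICc values (non-finite entries are
#'   treated as failed fits and never selected).
#' @param n_params Integer vector of parameter counts, same length.
#' @param delta AICc window (default 2).
#' @return Index of the selected model.
#' @export
select_model <- function(aicc_values, n_params, delta = 2) {
  stopifnot(length(aicc_values) == length(n_params))
  ok <- is.finite(aicc_values)
  if (!any(ok)) stop("no candidate model converged")
  best <- min(aicc_values[ok])
  cand <- which(ok & aicc_values <= best + delta)
  cand[order(n_params[cand], aicc_values[cand])][1L]
}

# Assemble the standard selection table.
selection_table <- function(labels, loglik, k, aicc_values) {
  sel <- select_model(aicc_values, k)
  data.frame(model = labels, n_params = k, loglik = loglik,
             AICc = aicc_values, dAICc = aicc_values - min(aicc_values[is.finite(aicc_values)]),
             selected = seq_along(labels) == sel,
             stringsAsFactors = FALSE)
}
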