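#' Cox negative log partial likelihood
#'
#' The training objective: for observed events i,
#' `L = -sum_i [ r_i - log sum_{j: t_j >= t_i} exp(r_j) ]`,
#' with the risk set inclusive of ties (`t_j = t_i`), which coincides with
#' Breslow's approximation when event times are tied. Computed with a
#' log-sum-exp stabilization over time-sorted suffixes. `L >= 0` because each
#' subject belongs to its own risk set.
#'
#' @param risks numeric vector of per-sample risk scores (log relative
#'   hazards).
#' @param time numeric vector of follow-up times.
#' @param event integer vector in \{0, 1\}; at least one event is required.
#' @param grad also return the analytic gradient with respect to `risks`.
#' @return If `grad = FALSE`, the scalar loss. Otherwise a list with `value`
#'   and `grad` (vector of the same length as `risks`).
#' @examples
#' cox_nll(c(0, 0, 0), time = c(1, 2, 3), event = c(1, 0, 0))  # log(3)
#' @export
cox_nll <- function(risks, time, event, grad = FALSE) {
  n <- length(risks)
  stopifnot(length(time) == n, length(event) == n)
  if (anyNA(risks) || any(!is.finite(risks))) {
    stop_cf("risks must be finite", class = "coxformer_validation_error")
  }
  if (sum(event == 1) == 0L) {
    stop_cf("no observed events; the partial likelihood is undefined",
            class = "coxformer_loss_error")
  }
  ord <- order(time, decreasing = TRUE)
  r <- risks[ord]; e <- as.numeric(event[ord]); t <- time[ord]
  M <- max(r)
  # cumulative log-sum-exp over the descending-time ordering: position k
  # holds log sum_{q <= k} exp(r_q), i.e. the risk-set denominator once the
  # whole tie group at that time has been absorbed.
  cs <- M + log(cumsum(exp(r - M)))
  rl <- rle(t)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  gend <- rep.int(ends, rl$lengths)     # last index of each sample's tie group
  gstart <- rep.int(starts, rl$lengths) # first index of each sample's tie group
  denom <- cs[gend]
  value <- -sum(e * (r - denom))
  if (!grad) return(value)
  # dL/dr_j = -e_j + sum over events i with t_i <= t_j of exp(r_j) / S_i
  h <- e * exp(-(denom - M))
  rev_cum_h <- rev(cumsum(rev(h)))
  g <- -e + exp(r - M) * rev_cum_h[gstart]
  grad_out <- numeric(n)
  grad_out[ord] <- g
  list(value = value, grad = grad_out)
}
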