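#' Concordance index for censored survival data
#'
#' Fraction of comparable ordered sample pairs whose predicted risk ordering
#' matches the observed survival ordering. A pair (i, j) is comparable when
#' `time[i] > time[j]` and subject j's death was observed (`event[j] = 1`);
#' it is concordant when `risk[i] < risk[j]` — the shorter-lived subject
#' carries the higher predicted risk. Pairs with exactly tied survival times
#' are not comparable under the strict inequality and are excluded.
#'
#' Tie handling for tied *predictions*: `"strict"` scores a tied pair 0
#' (the literal indicator definition); `"half"` scores it 0.5 (Harrell's
#' convention). Default is `"strict"`.
#'
#' @param risks numeric vector of predicted risk scores (higher = worse
#'   prognosis).
#' @param time numeric vector of follow-up times.
#' @param event integer vector in \{0, 1\}.
#' @param tie_policy `"strict"` or `"half"`.
#' @return An object of class `concordance_result`: a list with `cindex`,
#'   `comparable_pairs` and `concordant_pairs` (the latter fractional under
#'   the half policy).
#' @examples
#' concordance_index(c(0.9, 0.8, 0.1, 0.2), c(2, 4, 3, 1), c(1, 0, 1, 1))
#' @export
concordance_index <- function(risks, time, event,
                              tie_policy = c("strict", "half")) {
  tie_policy <- match.arg(tie_policy)
  n <- length(risks)
  stopifnot(length(time) == n, length(event) == n)
  if (anyNA(risks) || any(!is.finite(risks))) {
    stop_cf("risks must be finite", class = "coxformer_validation_error")
  }
  # comparable[i, j] <- time_i > time_j and event_j == 1
  comp <- outer(time, time, ">") & rep(event == 1, each = n)
  comparable <- sum(comp)
  if (comparable == 0L) {
    stop_cf("no comparable pairs (all samples censored or tied); C-index undefined",
            class = "coxformer_metric_error")
  }
  conc_lt <- outer(risks, risks, "<")
  concordant <- sum(conc_lt & comp)
  if (tie_policy == "half") {
    ties <- outer(risks, risks, "==")
    concordant <- concordant + 0.5 * sum(ties & comp)
  }
  structure(list(cindex = concordant / comparable,
                 comparable_pairs = as.integer(comparable),
                 concordant_pairs = concordant),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("C-index %.5f (%g / %d comparable pairs)\n",
              x$cindex, x$concordant_pairs, x$comparable_pairs))
  invisible(x)
}

#' Brute-force concordance index (testing oracle)
#'
#' Same contract as [concordance_index()], computed by an explicit double
#' loop over all ordered pairs. Intended as an independent oracle in tests,
#' not for large cohorts.
#'
#' @inheritParams concordance_index
#' @return a `concordance_result`.
#' @export
brute_force_cindex <- function(risks, time, event,
                               tie_policy = c("strict", "half")) {
  tie_policy <- match.arg(tie_policy)
  n <- length(risks)
  comparable <- 0L
  concordant <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] > time[j] && event[j] == 1) {
        comparable <- comparable + 1L
        if (risks[i] < risks[j]) {
          concordant <- concordant + 1
        } else if (tie_policy == "half" && risks[i] == risks[j]) {
          concordant <- concordant + 0.5
        }
      }
    }
  }
  if (comparable == 0L) {
    stop_cf("no comparable pairs (all samples censored or tied); C-index undefined",
            class = "coxformer_metric_error")
  }
  structure(list(cindex = concordant / comparable,
                 comparable_pairs = comparable,
                 concordant_pairs = concordant),
            class = "concordance_result")
}
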