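#' Tidy a displacement-CDF fit
#'
#' @param x A `cdf_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term, estimate`.
#' @method tidy cdf_fit
#' @export
tidy.cdf_fit <- function(x, ...) {
  if (x$n_components == 1) {
    tibble::tibble(term = "D_app", estimate = x$D_app)
  } else {
    tibble::tibble(term = c("A", "D_slow", "D_fast"),
                   estimate = c(x$A, x$D_slow, x$D_fast))
  }
}

#' @rdname tidy.cdf_fit
#' @method glance cdf_fit
#' @export
glance.cdf_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, residual_ss = x$residual_ss,
                 n = x$n, lag_s = x$lag,
                 flagged = !is.null(x$flag))
}

#' Tidy a fitted diffusion HMM
#'
#' @param x An `hmm_fit` object.
#' @param ... Unused.
#' @return One row per state: diffusion coefficient, occupancy, stay
#'   probability and mean lifetime.
#' @method tidy hmm_fit
#' @export
tidy.hmm_fit <- function(x, ...) {
  tibble::tibble(state = seq_len(x$K), D = x$D,
                 occupancy = x$occupancy, stay_prob = diag(x$T),
                 lifetime_s = x$lifetimes_s)
}

#' @rdname tidy.hmm_fit
#' @method glance hmm_fit
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble::tibble(K = x$K, logLik = x$logLik, BIC = x$BIC,
                 n_steps = x$n_steps, n_tracks = x$n_tracks,
                 n_iter = x$n_iter, flagged = !is.null(x$flag))
}

#' Serialize a fit to a JSON record
#'
#' @param x A `cdf_fit` or `hmm_fit` object.
#' @param path Optional file path; when given the JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(x, path = NULL) {
  rec <- unclass(x)
  rec$ll_trace <- NULL
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
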