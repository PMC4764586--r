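#' Rayleigh step likelihood of a diffusive state
#'
#' Emission density of a radial displacement under isotropic 2-D diffusion:
#' `p(r | D) = r / (2 D dt) * exp(-r^2 / (4 D dt))`, which integrates to 1
#' over `r >= 0` and has its mode at `sqrt(2 D dt)`.
#'
#' @param r Radial displacement(s), um.
#' @param D Diffusion coefficient, um^2/s (> 0).
#' @param dt Frame interval, seconds.
#' @param log Return the log density.
#' @return Density values.
#' @export
step_likelihood <- function(r, D, dt, log = FALSE) {
  if (D <= 0) stop("D must be > 0", call. = FALSE)
  stopifnot(all(r >= 0))
  s2 <- 2 * D * dt
  ld <- log(pmax(r, .Machine$double.xmin)) - log(s2) - r^2 / (2 * s2)
  if (log) ld else exp(ld)
}

# Displacement sequences per track, as a list of numeric vectors (>= 1 step).
track_steps <- function(tracks) {
  d <- tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(dplyr::n() >= 2, all(diff(.data$frame) == 1L)) |>
    dplyr::summarise(r = list(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
                     frame0 = min(.data$frame), .groups = "drop")
  d
}

# Pad step sequences into an n_tracks x max_len matrix (NA beyond each track).
steps_matrix <- function(steps) {
  lens <- lengths(steps$r)
  R <- matrix(NA_real_, nrow(steps), max(lens))
  for (i in seq_len(nrow(steps))) R[i, seq_len(lens[i])] <- steps$r[[i]]
  list(R = R, lens = lens, track_id = steps$track_id, frame0 = steps$frame0)
}

# One Baum-Welch EM run on the padded step matrix; K states, shared
# parameters across tracks, scaled forward-backward. Returns parameters,
# log-likelihood trace and expected sufficient statistics.
hmm_em <- function(sm, D0, T0, pi0, dt, max_iter = 500, tol = 1e-8) {
  R <- sm$R; lens <- sm$lens
  n <- nrow(R); Tmax <- ncol(R); K <- length(D0)
  D <- D0; TT <- T0; pv <- pi0
  ll_trace <- numeric(0)
  alive <- outer(lens, seq_len(Tmax), `>=`)
  R2 <- R^2
  for (iter in seq_len(max_iter)) {
    # emission log-densities per state: n x Tmax x K
    B <- array(0, dim = c(n, Tmax, K))
    for (k in seq_len(K))
      B[, , k] <- exp(log(pmax(R, .Machine$double.xmin)) - log(2 * D[k] * dt) -
                        R2 / (4 * D[k] * dt))
    B[is.na(R)] <- 1  # inert beyond track end
    alpha <- array(0, dim = c(n, Tmax, K))
    beta <- array(0, dim = c(n, Tmax, K))
    cc <- matrix(1, n, Tmax)
    a <- sweep(matrix(B[, 1, ], n, K), 2, pv, `*`)
    cc[, 1] <- rowSums(a)
    alpha[, 1, ] <- a / cc[, 1]
    if (Tmax > 1) for (t in 2:Tmax) {
      act <- alive[, t]
      if (!any(act)) break
      a <- (matrix(alpha[, t - 1, ], n, K) %*% TT) * matrix(B[, t, ], n, K)
      s <- rowSums(a)
      s[!act | s == 0] <- 1
      cc[act, t] <- s[act]
      alpha[, t, ] <- a / s
    }
    beta[cbind(seq_len(n), lens, rep(1, n))] <- 1
    if (K > 1) for (k in 2:K) beta[cbind(seq_len(n), lens, rep(k, n))] <- 1
    if (Tmax > 1) for (t in (Tmax - 1):1) {
      act <- alive[, t + 1]
      if (!any(act)) next
      b <- (matrix(beta[, t + 1, ], n, K) * matrix(B[, t + 1, ], n, K)) %*% t(TT)
      sc <- cc[, t + 1]
      upd <- act & lens > t
      beta[upd, t, ] <- b[upd, , drop = FALSE] / sc[upd]
    }
    ll <- sum(log(cc[alive]))
    ll_trace <- c(ll_trace, ll)
    gamma <- alpha * beta
    gamma <- gamma * ifelse(array(alive, dim = dim(gamma)), 1, 0)
    # xi sums for transitions
    xi_sum <- matrix(0, K, K)
    if (Tmax > 1) for (t in 1:(Tmax - 1)) {
      act <- alive[, t + 1]
      if (!any(act)) next
      for (j in seq_len(K)) for (k in seq_len(K)) {
        v <- alpha[, t, j] * TT[j, k] * B[, t + 1, k] * beta[, t + 1, k] /
          cc[, t + 1]
        xi_sum[j, k] <- xi_sum[j, k] + sum(v[act])
      }
    }
    # M-step
    gsum <- apply(gamma, 3, sum)
    Dnew <- numeric(K)
    for (k in seq_len(K)) {
      Dnew[k] <- sum(gamma[, , k] * R2, na.rm = TRUE) / (4 * dt * gsum[k])
    }
    Dnew <- pmax(Dnew, 1e-6)
    pnew <- colSums(matrix(gamma[, 1, ], n, K))
    pnew <- pnew / sum(pnew)
    Tnew <- xi_sum / rowSums(xi_sum)
    Tnew[is.na(Tnew)] <- 1 / K
    conv <- iter > 1 &&
      abs(ll - ll_trace[iter - 1]) < tol * (abs(ll_trace[iter - 1]) + 1e-12)
    D <- Dnew; pv <- pnew; TT <- Tnew
    if (conv) break
  }
  list(D = D, T = TT, pi = pv, logLik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, n_iter = length(ll_trace),
       occupancy = apply(gamma, 3, sum) / sum(gamma))
}

#' Fit a pooled K-state diffusion hidden Markov model
#'
#' Baum-Welch EM over the pooled track set: each track is an independent
#' sequence, the motion parameters (per-state diffusion coefficients,
#' per-frame transition matrix, initial distribution) are shared across
#' tracks. The best of `n_restarts` runs by log-likelihood is returned, with
#' states sorted by decreasing diffusion coefficient (state 1 = fast D1,
#' state 2 = slow D2). Convergence at relative log-likelihood change below
#' `tol` or `max_iter` iterations. Localization error is not modelled in the
#' emissions, so coefficients are apparent.
#'
#' @param tracks Track tibble.
#' @param K Number of diffusive states (1 or 2 in the default model space).
#' @param n_restarts EM restarts from perturbed initializations.
#' @param seed Optional seed for restart initializations.
#' @param frame_interval Frame interval, seconds.
#' @param max_iter,tol EM stopping rule.
#' @return Object of class `hmm_fit`: `K, D, T, pi, logLik, BIC, n_steps,
#'   occupancy, lifetimes_s` (mean holding time `dt / (1 - T[k,k])`),
#'   `ll_trace`, and `flag` (`"degenerate_state"` when a state's occupancy
#'   falls below 1%).
#' @export
fit_hmm <- function(tracks, K = 2, n_restarts = 3, seed = NULL,
                    frame_interval = 0.035, max_iter = 500, tol = 1e-8) {
  stopifnot(K >= 1)
  if (!is.null(seed)) set.seed(seed)
  steps <- track_steps(tracks)
  if (nrow(steps) == 0) stop("no track with >= 2 frames", call. = FALSE)
  sm <- steps_matrix(steps)
  n_steps <- sum(sm$lens)
  if (n_steps < 50 * K)
    stop("need at least 50 steps per state to fit the HMM", call. = FALSE)
  dt <- frame_interval
  r_all <- sm$R[!is.na(sm$R)]
  Dhat <- mean(r_all^2) / (4 * dt)
  if (K == 1) {
    ll <- sum(step_likelihood(r_all, Dhat, dt, log = TRUE))
    fit <- list(D = Dhat, T = matrix(1, 1, 1), pi = 1, logLik = ll,
                ll_trace = ll, n_iter = 1L, occupancy = 1)
  } else {
    # spread initial D over quantiles of the single-step estimate
    q <- stats::quantile(r_all^2 / (4 * dt),
                         probs = seq(0.2, 0.8, length.out = K))
    runs <- purrr::map(seq_len(n_restarts), function(s) {
      D0 <- pmax(as.numeric(q) * stats::runif(K, 0.5, 2), 1e-4)
      T0 <- matrix(0.1 / (K - 1), K, K); diag(T0) <- 0.9
      pi0 <- rep(1 / K, K)
      hmm_em(sm, D0, T0, pi0, dt, max_iter, tol)
    })
    fit <- runs[[which.max(purrr::map_dbl(runs, "logLik"))]]
    ord <- order(fit$D, decreasing = TRUE)  # state 1 = fast
    fit$D <- fit$D[ord]; fit$pi <- fit$pi[ord]
    fit$T <- fit$T[ord, ord, drop = FALSE]
    fit$occupancy <- fit$occupancy[ord]
  }
  p <- K + K * (K - 1) + (K - 1)
  bic <- -2 * fit$logLik + p * log(n_steps)
  flag <- if (K > 1 && any(fit$occupancy < 0.01)) "degenerate_state" else NULL
  structure(list(K = as.integer(K), D = fit$D, T = fit$T, pi = fit$pi,
                 logLik = fit$logLik, BIC = bic, n_steps = n_steps,
                 n_tracks = nrow(steps), occupancy = fit$occupancy,
                 lifetimes_s = dt / (1 - diag(fit$T)),
                 frame_interval = dt, ll_trace = fit$ll_trace,
                 n_iter = fit$n_iter, flag = flag),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("%d-state diffusion HMM (%d steps, %d tracks)\n",
              x$K, x$n_steps, x$n_tracks))
  for (k in seq_len(x$K))
    cat(sprintf("  state %d: D = %.4f um^2/s, occupancy %.2f, mean lifetime %.2f s\n",
                k, x$D[k], x$occupancy[k], x$lifetimes_s[k]))
  cat(sprintf("  logLik = %.1f, BIC = %.1f\n", x$logLik, x$BIC))
  if (!is.null(x$flag)) cat("  flagged:", x$flag, "\n")
  invisible(x)
}

#' Select the number of diffusive states by BIC
#'
#' Fits each candidate K and returns the model minimizing
#' `BIC = -2 logL + p log(n_steps)` with `p = K + K(K-1) + (K-1)` free
#' parameters. This is a deliberately simple, documented model-selection
#' criterion: it reproduces the 1-vs-2-state decision on well-separated
#' states without claiming equivalence to variational-Bayes evidence.
#'
#' @inheritParams fit_hmm
#' @param K_candidates Candidate state counts.
#' @return The winning `hmm_fit`, with attribute `candidates` (tibble of K,
#'   logLik, BIC).
#' @export
select_model <- function(tracks, K_candidates = c(1, 2), n_restarts = 3,
                         seed = NULL, frame_interval = 0.035) {
  stopifnot(length(K_candidates) >= 1)
  fits <- purrr::map(K_candidates, ~ fit_hmm(tracks, .x, n_restarts, seed,
                                             frame_interval))
  bics <- purrr::map_dbl(fits, "BIC")
  best <- fits[[which.min(bics)]]
  attr(best, "candidates") <- tibble::tibble(
    K = as.integer(K_candidates),
    logLik = purrr::map_dbl(fits, "logLik"), BIC = bics)
  best
}

viterbi_path <- function(r, model) {
  K <- model$K
  if (K == 1) return(rep(1L, length(r)))
  dt <- model$frame_interval
  n <- length(r)
  lB <- vapply(seq_len(K), function(k) step_likelihood(r, model$D[k], dt, log = TRUE),
               numeric(n))
  lB <- matrix(lB, n, K)
  lT <- log(model$T)
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1, ] <- log(model$pi) + lB[1, ]
  if (n > 1) for (t in 2:n) {
    for (k in seq_len(K)) {
      v <- delta[t - 1, ] + lT[, k]
      psi[t, k] <- which.max(v)
      delta[t, k] <- v[psi[t, k]] + lB[t, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

# Run-length encode a per-step label sequence into state visits; visits
# touching the first/last step of the track are boundary visits.
visits_from_labels <- function(state, frame, dt) {
  n_total <- length(state)
  rl <- rle(state)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  tibble::tibble(state = rl$values,
                 start_frame = frame[starts],
                 n_steps = rl$lengths,
                 duration_s = rl$lengths * dt,
                 at_start = starts == 1L,
                 at_end = ends == n_total)
}

#' Annotate per-step motion states along each track
#'
#' Computes the Viterbi state path of every track under a fitted model and
#' extracts state visits as maximal runs of one state. A step's state is
#' keyed by the frame at which the step starts. Visits touching a track's
#' first or last step are marked as boundary visits.
#'
#' @param tracks Track tibble (a single track also works).
#' @param model A fitted [fit_hmm()] model with the same frame interval.
#' @return List of class `state_annotation` with `steps` (tibble
#'   `track_id, frame, state`) and `visits` (tibble `track_id, state,
#'   start_frame, n_steps, duration_s, at_start, at_end`).
#' @export
annotate_states <- function(tracks, model) {
  stopifnot(inherits(model, "hmm_fit"))
  steps <- track_steps(tracks)
  if (nrow(steps) == 0) stop("no track with >= 1 step", call. = FALSE)
  dt <- model$frame_interval
  ann <- purrr::pmap(steps, function(track_id, r, frame0) {
    path <- viterbi_path(r, model)
    tibble::tibble(track_id = track_id,
                   frame = frame0 + seq_along(path) - 1L, state = path)
  }) |> purrr::list_rbind()
  visits <- ann |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) visits_from_labels(g$state, g$frame, dt)) |>
    dplyr::ungroup()
  structure(list(steps = ann, visits = visits, K = model$K,
                 frame_interval = dt),
            class = "state_annotation")
}

#' Pooled state-duration distributions
#'
#' Pools visit durations across tracks per state. With
#' `internal_only = TRUE`, visits touching a track's first or last step are
#' excluded (those durations are censored by the track boundary).
#'
#' @param annotation A [annotate_states()] result.
#' @param internal_only Drop boundary visits.
#' @return Tibble of class `duration_histogram` (`state, duration_s,
#'   at_start, at_end`) with attribute `summary` (per-state visit counts and
#'   mean durations).
#' @export
duration_histograms <- function(annotation, internal_only = FALSE) {
  stopifnot(inherits(annotation, "state_annotation"))
  v <- annotation$visits
  if (internal_only) v <- dplyr::filter(v, !.data$at_start, !.data$at_end)
  out <- dplyr::select(v, "state", "duration_s", "at_start", "at_end")
  smry <- out |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(n_visits = dplyr::n(),
                     mean_duration_s = mean(.data$duration_s), .groups = "drop")
  structure(out, summary = smry, internal_only = internal_only,
            class = c("duration_histogram", class(out)))
}
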