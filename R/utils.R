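#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Time to translate a protein at a given elongation rate
#'
#' `n_residues / rate_aa_per_s`, in seconds. Defaults describe beta-actin:
#' 375 amino acids at an elongation rate of 5.6 aa/s take about 67 s, the
#' benchmark against which transient slow-state lifetimes (a few seconds)
#' are compared.
#'
#' @param n_residues Protein length in amino acids.
#' @param rate_aa_per_s Elongation rate in amino acids per second.
#' @return Translation time in seconds.
#' @export
translation_time <- function(n_residues = 375, rate_aa_per_s = 5.6) {
  stopifnot(n_residues > 0, rate_aa_per_s > 0)
  n_residues / rate_aa_per_s
}

#' Expected number of co-moving events
#'
#' Mean of the number of trajectories passing the co-movement test:
#' `n_trajectories * pass_rate` (e.g. 9000 trajectories at a 5% pass rate
#' give 450 expected events).
#'
#' @param n_trajectories Number of trajectories screened.
#' @param pass_rate Fraction passing the co-movement test.
#' @return Expected event count.
#' @export
expected_comoving_count <- function(n_trajectories, pass_rate) {
  stopifnot(n_trajectories >= 0, pass_rate >= 0, pass_rate <= 1)
  n_trajectories * pass_rate
}
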