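#' Initial frequency of an admixture-introduced allele
#'
#' The frequency of an allele in the admixed population immediately after a
#' single admixture pulse is the admixture-weighted average of the source
#' frequencies: `freq_P * alpha_P + freq_A * (1 - alpha_P)`. With source
#' frequencies 0.915 and 0.049 and a P fraction of 0.246 this gives 0.262,
#' i.e. 0.26 at two decimals.
#'
#' @param freq_P,freq_A allele frequency in sources P and A, each between 0
#'   and 1.
#' @param alpha_P admixture fraction from source P, between 0 and 1.
#' @return the initial admixed-population frequency.
#' @export
initial_frequency <- function(freq_P, freq_A, alpha_P) {
  stopifnot(freq_P >= 0, freq_P <= 1, freq_A >= 0, freq_A <= 1,
            alpha_P >= 0, alpha_P <= 1)
  freq_P * alpha_P + freq_A * (1 - alpha_P)
}

#' One deterministic generation of allele-frequency change under selection
#'
#' Expected next-generation frequency of the favoured allele C under
#' additive selection with genotype fitnesses 1, 1-s, 1-2s for CC, CT, TT:
#' `p' = [p^2 + p(1-p)(1-s)] / [p^2 + 2p(1-p)(1-s) + (1-p)^2(1-2s)]`,
#' the post-selection allele frequency with the mean fitness as normaliser.
#' The fixed points 0 and 1 are preserved, and `p'` is increasing in s for
#' interior p.
#'
#' @param p current frequency in [0, 1].
#' @param s selection coefficient; the mean fitness must stay positive
#'   (for s >= 0.5 it can reach 0 at small p, which errors).
#' @return the expected frequency at the next generation.
#' @export
freq_update <- function(p, s) {
  stopifnot(all(p >= 0), all(p <= 1))
  w_bar <- p^2 + 2 * p * (1 - p) * (1 - s) + (1 - p)^2 * (1 - 2 * s)
  if (any(w_bar <= 0))
    stop("mean fitness is non-positive (s = ", s, "); model undefined")
  (p^2 + p * (1 - p) * (1 - s)) / w_bar
}

# Internal vectorised Wright-Fisher step for a batch of trajectories with
# per-trajectory s. Genotype fitnesses are clamped at zero so that draws of
# s > 0.5 from a wide prior remain well-defined (such trajectories sweep to
# fixation and are rejected by any sub-unity acceptance window anyway).
wf_step <- function(p, s, N) {
  w2 <- 1
  w1 <- pmax(0, 1 - s)
  w0 <- pmax(0, 1 - 2 * s)
  w_bar <- p^2 * w2 + 2 * p * (1 - p) * w1 + (1 - p)^2 * w0
  p_exp <- (p^2 * w2 + p * (1 - p) * w1) / w_bar
  stats::rbinom(length(p), 2 * N, p_exp) / (2 * N)
}

#' Simulate many Wright-Fisher trajectories at once
#'
#' Vectorised companion of [simulate_trajectory()]: one trajectory per
#' element of `s`, all sharing `N`, `g` and `p0`. This is the engine behind
#' [abc_estimate()].
#'
#' @param s vector of selection coefficients (one trajectory each).
#' @param N diploid population size.
#' @param g number of generations.
#' @param p0 initial allele frequency.
#' @param seed optional integer seed.
#' @return numeric vector of final allele frequencies, same length as `s`.
#' @export
simulate_trajectories <- function(s, N, g, p0, seed = NULL) {
  stopifnot(N >= 1, g >= 1, p0 >= 0, p0 <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- rep(p0, length(s))
  for (t in seq_len(g)) p <- wf_step(p, s, N)
  p
}

#' Simulate a Wright-Fisher trajectory with additive selection
#'
#' Iterates for `g` generations: deterministic selection update
#' ([freq_update()]), then binomial resampling of `2N` allele copies. Returns
#' the final frequency (optionally the whole path).
#'
#' @param s selection coefficient.
#' @param N diploid population size.
#' @param g number of generations.
#' @param p0 initial allele frequency.
#' @param seed optional integer seed.
#' @param full_path if TRUE also return the length `g + 1` frequency path.
#' @return final frequency, or a list with `final` and `path`.
#' @export
simulate_trajectory <- function(s, N, g, p0, seed = NULL, full_path = FALSE) {
  stopifnot(N >= 1, g >= 1, p0 >= 0, p0 <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- p0
  path <- if (full_path) numeric(g + 1) else NULL
  if (full_path) path[1] <- p0
  for (t in seq_len(g)) {
    p <- wf_step(p, s, N)
    if (full_path) path[t + 1] <- p
  }
  if (full_path) list(final = p, path = path) else p
}

#' Acceptance window around an observed allele frequency
#'
#' Relative tolerance window `[obs (1 - tol), obs (1 + tol)]`, clipped to
#' [0, 1]. With the observed frequency 0.76 and a 5% tolerance this is
#' [0.722, 0.798].
#'
#' @param observed_freq observed frequency in (0, 1).
#' @param tolerance relative tolerance in (0, 1).
#' @return numeric vector `c(lower, upper)`.
#' @export
acceptance_window <- function(observed_freq, tolerance) {
  stopifnot(observed_freq > 0, observed_freq < 1,
            tolerance >= 0, tolerance < 1)
  c(max(0, observed_freq * (1 - tolerance)),
    min(1, observed_freq * (1 + tolerance)))
}

#' Rejection-ABC estimate of a selection coefficient
#'
#' Repeatedly draws s from a uniform prior, simulates a Wright-Fisher
#' trajectory of `g` generations from `p0`, and accepts the draw when the
#' final allele frequency falls inside `window` (closed interval). Sampling
#' stops once `n_accept` draws are accepted; the posterior is summarised by
#' its mean and the equal-tailed 2.5% / 97.5% empirical quantiles.
#'
#' Trajectories are simulated in vectorised batches; the accepted set is
#' identical to sequential simulation in draw order, and identical seeds
#' reproduce identical posteriors.
#'
#' @param p0 initial allele frequency.
#' @param N diploid population size.
#' @param g generations between admixture and observation.
#' @param window acceptance interval, e.g. from [acceptance_window()].
#' @param n_accept number of accepted draws required (default 10000).
#' @param prior lower/upper bound of the uniform prior on s (default (0, 1)).
#' @param seed optional integer seed.
#' @param batch_size trajectories simulated per batch.
#' @param max_attempts attempts after which an acceptance rate below 1e-6
#'   aborts with an error (unreachable window).
#' @return an object of class `abc_posterior`: accepted `draws`, `mean`,
#'   `ci` (95% equal-tailed), `attempts` and `acceptance_rate`.
#' @export
abc_estimate <- function(p0, N, g, window, n_accept = 10000,
                         prior = c(0, 1), seed = NULL, batch_size = 10000,
                         max_attempts = 1e7) {
  stopifnot(length(window) == 2, window[1] <= window[2],
            window[1] >= 0, window[2] <= 1, n_accept >= 1)
  if (!is.null(seed)) set.seed(seed)
  accepted <- numeric(0)
  attempts <- 0
  while (length(accepted) < n_accept) {
    s <- stats::runif(batch_size, prior[1], prior[2])
    p <- simulate_trajectories(s, N, g, p0)
    attempts <- attempts + batch_size
    accepted <- c(accepted, s[p >= window[1] & p <= window[2]])
    if (attempts >= max_attempts &&
        length(accepted) / attempts < 1e-6)
      stop("acceptance rate below 1e-6 after ", attempts,
           " attempts; window unreachable")
  }
  draws <- accepted[seq_len(n_accept)]
  structure(list(draws = draws, mean = mean(draws),
                 ci = unname(stats::quantile(draws, c(0.025, 0.975))),
                 attempts = attempts,
                 acceptance_rate = length(accepted) / attempts),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("abc_posterior: mean s = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$mean, x$ci[1], x$ci[2]))
  cat(sprintf("  %d accepted / %d attempts (rate %.3g)\n",
              length(x$draws), x$attempts, x$acceptance_rate))
  invisible(x)
}
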