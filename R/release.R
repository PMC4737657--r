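# Binomial model of neurotransmitter release averaging: how many presynaptic
# spikes (and how much time at a given firing rate) are needed to estimate
# synaptic strength at a target coefficient of variation.

#' Coefficient of variation of cumulative binomial release
#'
#' With `n` presynaptic action potentials each releasing one or more vesicles
#' with probability `p_r`, the cumulative release count has mean
#' \eqn{\mu = n p_r} and variance \eqn{\sigma^2 = n p_r (1 - p_r)}, so
#' \deqn{\mathrm{CV} = \sigma/\mu = \sqrt{(1 - p_r) / (n p_r)}.}
#'
#' @param n Number of presynaptic spikes (>= 1; may be real-valued).
#' @param p_r Release probability per action potential, in `(0, 1]`.
#' @return The coefficient of variation (dimensionless); 0 when `p_r = 1`.
#' @examples
#' release_cv(1306, 0.1) # ~0.083
#' @export
release_cv <- function(n, p_r) {
  check_pr(p_r)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  sqrt((1 - p_r) / (n * p_r))
}

#' Spikes required to reach a target CV of cumulative release
#'
#' Inverts [release_cv()]: the number of presynaptic spikes needed to reduce
#' the variability of the cumulative release count to a target coefficient of
#' variation is \eqn{n = (1 - p_r) / (p_r\,\mathrm{CV}^2)}.
#'
#' @param p_r Release probability per action potential, in `(0, 1]`.
#' @param cv Target coefficient of variation (> 0); the axon-coupled pair
#'   estimate of synaptic precision is 0.083.
#' @return Real-valued spike count; round to an integer for tabulation
#'   (e.g. 1306 at `p_r = 0.1`, `cv = 0.083`). Zero when `p_r = 1`.
#' @export
spikes_required <- function(p_r, cv) {
  check_pr(p_r)
  if (any(cv <= 0)) stop("`cv` must be positive", call. = FALSE)
  (1 - p_r) / (p_r * cv^2)
}

#' Averaging time window from spike count and firing rate
#'
#' @param n Spike count (>= 0).
#' @param rate Presynaptic firing rate in Hz (> 0).
#' @return Time window `T = n / rate` in seconds.
#' @examples
#' averaging_time(1306, 1)  # 1306 s ~ 21.8 min
#' averaging_time(145, 25)  # 5.8 s
#' @export
averaging_time <- function(n, rate) {
  if (any(rate <= 0)) stop("`rate` must be positive (Hz)", call. = FALSE)
  if (any(n < 0)) stop("`n` must be non-negative", call. = FALSE)
  n / rate
}

#' Format a duration in seconds as minutes or seconds
#'
#' Renders averaging times the way physiologists tabulate them: durations of
#' a minute or more in minutes, shorter ones in seconds, three significant
#' figures (so 1306 s prints as "21.8 min" and 5.806 s as "5.8 s").
#'
#' @param seconds Duration(s) in seconds.
#' @return Character vector.
#' @export
format_duration <- function(seconds) {
  vapply(seconds, function(s) {
    if (s >= 60) sprintf("%s min", signif(s / 60, 3))
    else sprintf("%s s", signif(s, 3))
  }, character(1))
}

#' Release-averaging time-window table
#'
#' Builds the table of lower bounds on the averaging time window needed for
#' binomially distributed synaptic input to reach a target CV: one row per
#' release probability, with the required spike count and the time window at
#' each firing rate. At the defaults (`cv = 0.083`, `p_r` of 0.1/0.2/0.5,
#' rates 1 and 25 Hz) the rounded spike counts are 1306, 581 and 145, and
#' the windows range from 21.8 min down to 5.8 s.
#'
#' @param cv Target coefficient of variation, default 0.083.
#' @param p_r Vector of release probabilities, default `c(0.1, 0.2, 0.5)`.
#' @param rates Vector of presynaptic firing rates in Hz, default `c(1, 25)`.
#' @return A data frame of class `"release_table"` with columns `p_r`,
#'   `n_spikes` (real-valued), `n_spikes_int` (rounded) and one
#'   `time_s_<rate>Hz` column per rate (seconds, computed from the rounded
#'   spike count). Attributes `cv` and `rates` record the inputs.
#' @examples
#' release_table()
#' @export
release_table <- function(cv = 0.083, p_r = c(0.1, 0.2, 0.5),
                          rates = c(1, 25)) {
  if (length(p_r) == 0) {
    tab <- data.frame(p_r = numeric(0), n_spikes = numeric(0),
                      n_spikes_int = integer(0))
  } else {
    n <- spikes_required(p_r, cv)
    tab <- data.frame(p_r = p_r, n_spikes = n,
                      n_spikes_int = as.integer(round(n)))
  }
  for (r in rates) {
    tab[[sprintf("time_s_%gHz", r)]] <- averaging_time(tab$n_spikes_int, r)
  }
  structure(tab, cv = cv, rates = rates,
            class = c("release_table", "data.frame"))
}

#' @export
print.release_table <- function(x, ...) {
  cat(sprintf(
    "Lower bounds on averaging time for binomial release to reach CV = %g\n\n",
    attr(x, "cv")))
  disp <- data.frame(`p_r` = x$p_r, `spikes n` = x$n_spikes_int,
                     check.names = FALSE)
  for (r in attr(x, "rates")) {
    disp[[sprintf("T (R = %g Hz)", r)]] <-
      format_duration(x[[sprintf("time_s_%gHz", r)]])
  }
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Monte-Carlo check of the binomial release CV
#'
#' Draws `reps` replicate cumulative release counts, each the sum of `n`
#' independent Bernoulli(`p_r`) trials, and returns the empirical
#' coefficient of variation of the replicate sums. Converges to
#' [release_cv()] as `reps` grows.
#'
#' @param n Spikes per replicate (integer >= 1).
#' @param p_r Release probability per spike, in `(0, 1]`.
#' @param reps Number of replicates (>= 2).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A list with `empirical_cv` (sd/mean of the replicate sums) and
#'   `mean` (mean replicate sum, approximately `n * p_r`).
#' @examples
#' simulate_release(1306, 0.1, reps = 1000, seed = 1)
#' @export
simulate_release <- function(n, p_r, reps, seed = 1) {
  check_pr(p_r)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (reps < 2) stop("`reps` must be >= 2", call. = FALSE)
  set.seed(seed)
  sums <- stats::rbinom(reps, size = as.integer(n), prob = p_r)
  m <- mean(sums)
  if (m == 0) {
    return(list(empirical_cv = NA_real_, mean = m))
  }
  list(empirical_cv = stats::sd(sums) / m, mean = m)
}

check_pr <- function(p_r) {
  if (!is.numeric(p_r) || any(p_r <= 0) || any(p_r > 1)) {
    stop("`p_r` must be a probability in (0, 1]", call. = FALSE)
  }
  invisible(p_r)
}
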