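# Statistics of axon-coupled spine pairs: per-pair coefficients of
# variation, random-pairing resampling nulls, two-sample KS comparisons and
# log-log regressions.

# Metrics for which per-pair CVs are tabulated when present in the records.
PAIR_METRICS <- c("head_volume", "psd_area", "neck_diameter", "neck_length",
                  "neck_volume", "docked_vesicles")

#' Coefficient of variation of a pair of measurements
#'
#' The per-pair precision statistic: the sample standard deviation of the two
#' values (denominator n - 1 = 1) divided by their mean,
#' \deqn{\mathrm{CV} = \frac{|a - b| / \sqrt{2}}{(a + b)/2}.}
#' It is symmetric in the two members, zero iff they are equal, and
#' scale-invariant (`pair_cv(c*a, c*b) == pair_cv(a, b)`).
#'
#' @param a,b Positive measurements (vectorized).
#' @return Dimensionless pair CV in `[0, sqrt(2))`.
#' @examples
#' pair_cv(1.0, 1.2) # 0.1286
#' @export
pair_cv <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    stop("pair members must be positive", call. = FALSE)
  }
  (abs(a - b) / sqrt(2)) / ((a + b) / 2)
}

#' Identify axon-coupled spine pairs from connectivity labels
#'
#' Returns every unordered pair of spines that receive input from the same
#' axon. Pairs on the same dendrite share both pre- and postsynaptic
#' activity history and carry the `same_dendrite` flag; when an axon
#' contacts k >= 3 spines on one dendrite (a multi-synaptic bouton
#' configuration such as a triplet) all k(k-1)/2 pairs are returned and
#' flagged `multi_contact`, so they can be excluded from the headline
#' precision statistic as the triplet is in the source analysis.
#'
#' @param records A spine-record data frame with at least `spine_id`,
#'   `axon_id`, `dendrite_id` and `head_volume` columns (see
#'   [generate_population()]). Per-pair CVs are added for every column of
#'   `r toString(PAIR_METRICS)` that is present and positive in both members.
#' @return A data frame with one row per axon-coupled pair: member ids,
#'   `axon_id`, `same_dendrite`, `multi_contact`, `mean_head_volume`,
#'   `larger`/`smaller` head volumes and `cv_<metric>` columns. Zero rows if
#'   no axon contacts two spines.
#' @export
find_axon_coupled_pairs <- function(records) {
  need <- c("spine_id", "axon_id", "dendrite_id", "head_volume")
  if (!all(need %in% names(records))) {
    stop("`records` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$spine_id)) {
    stop("duplicate spine ids in `records`", call. = FALSE)
  }
  rows <- list()
  grp_idx <- split(seq_len(nrow(records)), records$axon_id)
  grp_idx <- grp_idx[lengths(grp_idx) >= 2]
  for (ax in names(grp_idx)) {
    grp <- records[grp_idx[[ax]], , drop = FALSE]
    k <- nrow(grp)
    # contact multiplicity per dendrite within this axon
    dcount <- table(grp$dendrite_id)
    idx <- utils::combn(k, 2)
    for (j in seq_len(ncol(idx))) {
      a <- grp[idx[1, j], ]
      b <- grp[idx[2, j], ]
      same_d <- a$dendrite_id == b$dendrite_id
      multi <- same_d && dcount[[as.character(a$dendrite_id)]] >= 3
      row <- data.frame(
        spine_a = a$spine_id, spine_b = b$spine_id, axon_id = ax,
        same_dendrite = same_d, multi_contact = multi,
        mean_head_volume = (a$head_volume + b$head_volume) / 2,
        larger = max(a$head_volume, b$head_volume),
        smaller = min(a$head_volume, b$head_volume),
        stringsAsFactors = FALSE
      )
      for (m in intersect(PAIR_METRICS, names(records))) {
        va <- a[[m]]
        vb <- b[[m]]
        row[[paste0("cv_", m)]] <-
          if (is.finite(va) && is.finite(vb) && va > 0 && vb > 0) {
            pair_cv(va, vb)
          } else {
            NA_real_
          }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(spine_a = character(0), spine_b = character(0),
                      axon_id = character(0), same_dendrite = logical(0),
                      multi_contact = logical(0),
                      mean_head_volume = numeric(0),
                      larger = numeric(0), smaller = numeric(0),
                      cv_head_volume = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  do.call(rbind, rows)
}

#' Median per-pair coefficient of variation
#'
#' The population-level precision statistic: the median over eligible pairs
#' of the per-pair CVs. By default only same-dendrite pairs enter (those are
#' the pairs with shared pre- and postsynaptic history) and multi-contact
#' (>= 3 spines on one axon-dendrite) pairs are excluded.
#'
#' @param pairs A pair data frame from [find_axon_coupled_pairs()].
#' @param metric Which metric's CV to summarize, default `"head_volume"`.
#' @param exclude_multi_contact Drop `multi_contact` pairs, default `TRUE`.
#' @param same_dendrite_only Keep only same-dendrite pairs, default `TRUE`.
#' @return The median pair CV (dimensionless).
#' @export
median_pair_cv <- function(pairs, metric = "head_volume",
                           exclude_multi_contact = TRUE,
                           same_dendrite_only = TRUE) {
  cvs <- eligible_pair_cvs(pairs, metric, exclude_multi_contact,
                           same_dendrite_only)
  stats::median(cvs)
}

eligible_pair_cvs <- function(pairs, metric = "head_volume",
                              exclude_multi_contact = TRUE,
                              same_dendrite_only = TRUE) {
  col <- paste0("cv_", metric)
  if (!col %in% names(pairs)) {
    stop("no per-pair CV column for metric `", metric, "`", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(pairs))
  if (same_dendrite_only) keep <- keep & pairs$same_dendrite
  if (exclude_multi_contact) keep <- keep & !pairs$multi_contact
  cvs <- pairs[[col]][keep]
  cvs <- cvs[is.finite(cvs)]
  if (length(cvs) < 1) {
    stop("no eligible pairs for metric `", metric, "`", call. = FALSE)
  }
  cvs
}

#' Random-pairing resampling null for pair CVs
#'
#' Builds the null distribution of per-pair CVs (and of their per-resample
#' median) under the hypothesis that pair members are unrelated draws from
#' the population: in each resample, `n_pairs` disjoint pairs are drawn
#' without replacement from the records (each spine used at most once per
#' resample, mirroring drawing 17 random pairs from the 287 reconstructed
#' spines) and their CVs recorded.
#'
#' @param records Spine-record data frame.
#' @param n_pairs Pairs per resample.
#' @param n_resamples Number of resamples, e.g. 5000.
#' @param seed Integer seed; the null is deterministic given the seed.
#' @param metric Metric column to pair, default `"head_volume"`.
#' @return An object of class `"pairing_null"`: list with `pair_cvs`
#'   (`n_resamples` x `n_pairs` matrix), `medians` (per-resample median CV),
#'   `statistic_name`, `n_resamples`, `n_pairs` and `seed`.
#' @seealso [null_p_value()] for the empirical tail probability of an
#'   observed median.
#' @export
random_pairing_null <- function(records, n_pairs, n_resamples, seed = 1,
                                metric = "head_volume") {
  vals <- records[[metric]]
  if (is.null(vals)) stop("no column `", metric, "` in records", call. = FALSE)
  if (length(vals) < 2 * n_pairs) {
    stop("need at least 2 * n_pairs records (", 2 * n_pairs, "), got ",
         length(vals), call. = FALSE)
  }
  if (any(vals <= 0)) stop("metric values must be positive", call. = FALSE)
  set.seed(seed)
  cvs <- matrix(NA_real_, nrow = n_resamples, ncol = n_pairs)
  for (i in seq_len(n_resamples)) {
    pick <- sample(length(vals), 2 * n_pairs, replace = FALSE)
    a <- vals[pick[seq_len(n_pairs)]]
    b <- vals[pick[n_pairs + seq_len(n_pairs)]]
    cvs[i, ] <- pair_cv(a, b)
  }
  structure(
    list(statistic_name = paste0("pair_cv_", metric), pair_cvs = cvs,
         medians = apply(cvs, 1, stats::median), n_resamples = n_resamples,
         n_pairs = n_pairs, seed = seed),
    class = "pairing_null"
  )
}

#' Empirical tail probability of an observed median pair CV
#'
#' The add-one empirical p-value for observing a median pair CV at least as
#' small as `observed` under the random-pairing null: precise matching of
#' coupled pairs shows up as a median far below the null's.
#'
#' @param null A `"pairing_null"` object.
#' @param observed Observed median pair CV.
#' @return p-value in `(0, 1]`.
#' @export
null_p_value <- function(null, observed) {
  stopifnot(inherits(null, "pairing_null"))
  (1 + sum(null$medians <= observed)) / (null$n_resamples + 1)
}

#' @export
print.pairing_null <- function(x, ...) {
  cat(sprintf("Random-pairing null of %s: %d resamples x %d pairs\n",
              x$statistic_name, x$n_resamples, x$n_pairs))
  cat(sprintf("  median of per-resample medians: %.3f\n",
              stats::median(x$medians)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Non-parametric comparison of two samples, appropriate for the highly
#' skewed distributions of spine metrics: the statistic is the supremum
#' distance between the two empirical CDFs, with the p-value from the
#' asymptotic Kolmogorov distribution at effective sample size
#' \eqn{n_x n_y / (n_x + n_y)} by default, or the exact small-sample
#' distribution with `exact = TRUE` (no ties permitted in the exact case).
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact Use the exact null distribution (small n), default `FALSE`.
#' @return List with `D` (in `[0, 1]`) and `p`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6)) # disjoint supports: D = 1
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Log-log (power-law) regression between two positive metrics
#'
#' Spine-metric distributions are right-skewed with long tails, so
#' correlation structure is assessed on the natural-log scale: ordinary
#' least squares of `log(y)` on `log(x)`, i.e. the fit of a power law
#' `y = exp(intercept) * x^slope`. `r2` is the squared Pearson correlation
#' of the logs.
#'
#' @param x,y Positive numeric vectors of equal length >= 3.
#' @return List with `slope`, `intercept`, `r2`, `p_slope` (two-sided test
#'   of slope = 0) and `slope_ci` (95% confidence interval).
#' @export
loglog_regression <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(x <= 0) || any(y <= 0)) {
    stop("all values must be positive for log transformation", call. = FALSE)
  }
  lx <- log(x)
  ly <- log(y)
  if (stats::var(lx) == 0) {
    stop("degenerate predictor: no variance in log(x)", call. = FALSE)
  }
  fit <- stats::lm(ly ~ lx)
  sm <- quiet_perfect_fit(summary(fit))
  ci <- quiet_perfect_fit(stats::confint(fit, "lx", level = 0.95))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p_slope = sm$coefficients["lx", "Pr(>|t|)"],
       slope_ci = unname(ci[1, ]))
}

# An exact power law triggers lm's "essentially perfect fit" warning; that
# case is legitimate here (noiseless synthetic couplings), so muffle it.
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Trend of pair precision with pair size
#'
#' Regresses the per-pair CV on the log mean pair volume. A flat (non
#' significant) slope means small paired synapses are matched as precisely
#' as large ones -- constant CV across the dynamic range, the assumption
#' behind tiling the range with constant-CV strength levels.
#'
#' @param pairs Pair data frame from [find_axon_coupled_pairs()] (>= 3
#'   eligible pairs).
#' @param metric Metric, default `"head_volume"`.
#' @inheritParams median_pair_cv
#' @return List with `slope`, `p` (two-sided significance of the slope) and
#'   `n_pairs`.
#' @export
cv_size_trend <- function(pairs, metric = "head_volume",
                          exclude_multi_contact = TRUE,
                          same_dendrite_only = TRUE) {
  col <- paste0("cv_", metric)
  keep <- rep(TRUE, nrow(pairs))
  if (same_dendrite_only) keep <- keep & pairs$same_dendrite
  if (exclude_multi_contact) keep <- keep & !pairs$multi_contact
  sub <- pairs[keep & is.finite(pairs[[col]]), ]
  if (nrow(sub) < 3) {
    stop("need at least 3 eligible pairs, got ", nrow(sub), call. = FALSE)
  }
  x <- log(sub$mean_head_volume)
  if (stats::var(x) == 0) {
    stop("degenerate predictor: no variance in log mean volume",
         call. = FALSE)
  }
  fit <- stats::lm(sub[[col]] ~ x)
  sm <- quiet_perfect_fit(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       p = sm$coefficients["x", "Pr(>|t|)"],
       n_pairs = nrow(sub))
}

#' Full pair-precision analysis of a spine-record table
#'
#' One-call analysis of axon-coupled pair precision: identifies pairs,
#' computes the median per-pair CV of head volumes (same-dendrite pairs,
#' multi-contact excluded), builds the disjoint random-pairing null,
#' evaluates the empirical tail probability and the KS comparison of the
#' coupled per-pair CVs against the null CVs, and tests the CV-vs-size
#' trend.
#'
#' @param records Spine-record data frame.
#' @param n_resamples Resamples for the null, default 1000.
#' @param seed Seed for the null, default 1.
#' @param metric Metric, default `"head_volume"`.
#' @param exclude_multi_contact Default `TRUE`.
#' @return Object of class `"spine_pair_analysis"`: list with `pairs`,
#'   `n_pairs` (eligible same-dendrite pairs), `median_cv`, `null`
#'   (a `"pairing_null"`), `p_empirical`, `ks` (coupled CVs vs null CVs) and
#'   `size_trend` (or `NULL` when < 3 pairs).
#' @examples
#' pop <- generate_population(population_config(n_spines = 60, seed = 1))
#' cp <- generate_coupled_pairs(pop, pair_config(n_pairs = 8, seed = 1))
#' spine_pair_analysis(cp$population, n_resamples = 200, seed = 1)
#' @export
spine_pair_analysis <- function(records, n_resamples = 1000, seed = 1,
                                metric = "head_volume",
                                exclude_multi_contact = TRUE) {
  pairs <- find_axon_coupled_pairs(records)
  cvs <- eligible_pair_cvs(pairs, metric, exclude_multi_contact,
                           same_dendrite_only = TRUE)
  med <- stats::median(cvs)
  null <- random_pairing_null(records, n_pairs = length(cvs),
                              n_resamples = n_resamples, seed = seed,
                              metric = metric)
  trend <- if (length(cvs) >= 3) {
    cv_size_trend(pairs, metric, exclude_multi_contact)
  } else {
    NULL
  }
  structure(
    list(pairs = pairs, n_pairs = length(cvs), median_cv = med, null = null,
         p_empirical = null_p_value(null, med),
         ks = ks_two_sample(cvs, as.vector(null$pair_cvs)),
         size_trend = trend, metric = metric),
    class = "spine_pair_analysis"
  )
}

#' @export
print.spine_pair_analysis <- function(x, ...) {
  cat("Axon-coupled spine pair precision analysis\n")
  cat(sprintf("  metric:                  %s\n", x$metric))
  cat(sprintf("  eligible pairs:          %d (same dendrite%s)\n", x$n_pairs,
              if (any(x$pairs$multi_contact)) ", multi-contact excluded" else ""))
  cat(sprintf("  median pair CV:          %.3f\n", x$median_cv))
  cat(sprintf("  null median (random):    %.3f [%d resamples]\n",
              stats::median(x$null$medians), x$null$n_resamples))
  cat(sprintf("  empirical p (<= obs):    %.4g\n", x$p_empirical))
  cat(sprintf("  KS coupled vs null CVs:  D = %.3f, p = %.3g\n",
              x$ks$D, x$ks$p))
  if (!is.null(x$size_trend)) {
    cat(sprintf("  CV vs log size trend:    slope %.3f, p = %.3f\n",
                x$size_trend$slope, x$size_trend$p))
  }
  invisible(x)
}

#' @export
summary.spine_pair_analysis <- function(object, ...) print(object, ...)
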