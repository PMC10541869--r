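# Allocation Characteristics Comparison Analysis (ACCA): metrics for
# comparing two sets of allocation results (e.g. simulated vs observed)
# on the national:state split, recipient waiting times and per-state
# allocation percentages.

#' Hellinger distance between two categorical distributions
#'
#' `H(p, q) = (1/sqrt(2)) * sqrt(sum (sqrt(p_i) - sqrt(q_i))^2)`, in
#' `[0, 1]`, symmetric, 0 iff the distributions coincide. Named vectors
#' are aligned by name; supports must match.
#'
#' @param p,q non-negative vectors summing to 1 (within 1e-9).
#' @return the distance.
#' @export
hellinger <- function(p, q) {
  if (!is.null(names(p)) || !is.null(names(q))) {
    kap_assert(!is.null(names(p)) && !is.null(names(q)) &&
                 setequal(names(p), names(q)),
               "mismatched category supports", class = "kap_validation_error")
    q <- q[names(p)]
  }
  kap_assert(length(p) == length(q), "mismatched category supports",
             class = "kap_validation_error")
  kap_assert(abs(sum(p) - 1) < 1e-9 && abs(sum(q) - 1) < 1e-9 &&
               all(p >= 0) && all(q >= 0),
             "inputs must be probability vectors", class = "kap_validation_error")
  sqrt(sum((sqrt(p) - sqrt(q))^2)) / sqrt(2)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum over t of the absolute difference between the two empirical
#' CDFs, computed over the pooled sample points; ties are handled exactly.
#' Used descriptively (no p-value).
#'
#' @param x,y non-empty numeric samples.
#' @return the statistic, in `[0, 1]`.
#' @export
ks_stat <- function(x, y) {
  kap_assert(length(x) > 0 && length(y) > 0, "empty sample",
             class = "kap_validation_error")
  t <- sort(unique(c(x, y)))
  fx <- findInterval(t, sort(x)) / length(x)
  fy <- findInterval(t, sort(y)) / length(y)
  max(abs(fx - fy))
}

#' Pearson (non-excess) kurtosis and kurtosis difference
#'
#' `kurtosis(x) = m4 / m2^2` with central sample moments (normal
#' distribution: 3); `kurtosis_diff` is the absolute difference between
#' the two samples' kurtoses. Requires at least 4 points and nonzero
#' variance per sample.
#'
#' @param x,y numeric samples.
#' @return `kurtosis`: the coefficient; `kurtosis_diff`: `|k(x) - k(y)|`.
#' @export
kurtosis <- function(x) {
  kap_assert(length(x) >= 4, "kurtosis needs >= 4 points",
             class = "kap_validation_error")
  m2 <- mean((x - mean(x))^2)
  kap_assert(m2 > 0, "kurtosis undefined for zero-variance sample",
             class = "kap_validation_error")
  mean((x - mean(x))^4) / m2^2
}

#' @rdname kurtosis
#' @export
kurtosis_diff <- function(x, y) abs(kurtosis(x) - kurtosis(y))

#' National and state allocation proportions
#'
#' Proportions of matched records allocated under the national vs the
#' state tier; discarded donors are excluded from the denominator.
#'
#' @param records MatchRecord data.frame.
#' @return named numeric `c(national = , state = )`, summing to 1.
#' @export
national_state_ratio <- function(records) {
  matched <- records[!is.na(records$recipient_id), , drop = FALSE]
  kap_assert(nrow(matched) > 0, "no matched records",
             class = "kap_validation_error")
  p <- mean(matched$tier == "national")
  c(national = p, state = 1 - p)
}

#' Absolute log-ratio of two medians
#'
#' `|ln(actual / simulated)|`: 0 iff equal, symmetric in its arguments;
#' the per-stratum waiting-time comparison statistic.
#'
#' @param actual_median,simulated_median positive reals.
#' @return non-negative real.
#' @export
median_log_ratio <- function(actual_median, simulated_median) {
  kap_assert(all(actual_median > 0) && all(simulated_median > 0),
             "medians must be positive", class = "kap_validation_error")
  abs(log(actual_median / simulated_median))
}

#' Aggregate dissimilarity score
#'
#' Unweighted mean of normalized components: `bounded` components
#' (Hellinger, KS) already lie in `[0, 1]` and pass through; `unbounded`
#' non-negative components (kurtosis differences, median log-ratios) are
#' squashed by `1 - exp(-x)`. 0 means perfect agreement on every
#' component. The aggregation is deliberately isolated here so an
#' alternative blend can be swapped in.
#'
#' @param bounded numeric vector of components in `[0, 1]`.
#' @param unbounded numeric vector of non-negative components.
#' @return a value in `[0, 1]`.
#' @export
dissimilarity_score <- function(bounded = numeric(0), unbounded = numeric(0)) {
  parts <- c(bounded, 1 - exp(-unbounded))
  kap_assert(length(parts) > 0, "no components",
             class = "kap_validation_error")
  kap_assert(all(parts >= 0 & parts <= 1 + 1e-12),
             "bounded components must lie in [0, 1]",
             class = "kap_validation_error")
  mean(parts)
}

band_or_quintile <- function(values, pooled, kind) {
  switch(kind,
    age = as.character(age_band(values)),
    pra = as.character(pra_band(values)),
    quintile = {
      qs <- stats::quantile(pooled, probs = seq(0, 1, 0.2), na.rm = TRUE,
                            names = FALSE)
      qs[1] <- -Inf; qs[6] <- Inf
      paste0("Q", findInterval(values, qs, rightmost.closed = TRUE,
                               left.open = TRUE))
    })
}

#' Compare two allocation result sets (ACCA report)
#'
#' Builds the full comparison between an "actual" and a "simulated"
#' MatchRecord set:
#' \itemize{
#'   \item national:state split -- raw difference of national proportions
#'     and Hellinger distance between the two 2-category distributions;
#'   \item recipient waiting time (days) -- KS statistic, Pearson kurtosis
#'     difference, and `|log|` ratio of the medians;
#'   \item per-centre allocation percentages -- Hellinger distance;
#'   \item stratified tables of median waiting-time `|log(actual/simulated)|`
#'     by state/centre, age band, EPTS-percentile quintile, PRA band and
#'     blood group;
#'   \item an aggregate dissimilarity score (see [dissimilarity_score()]).
#' }
#'
#' @param actual,simulated MatchRecord data.frames with at least one
#'   matched row each.
#' @return a `kap_acca` list with elements `national_state`,
#'   `waiting_time`, `state_pct`, `stratified` (named list of data.frames)
#'   and `dissimilarity`.
#' @export
acca_compare <- function(actual, simulated) {
  a <- actual[!is.na(actual$recipient_id), , drop = FALSE]
  s <- simulated[!is.na(simulated$recipient_id), , drop = FALSE]
  kap_assert(nrow(a) > 0 && nrow(s) > 0, "need matched records on both sides",
             class = "kap_validation_error")

  ns_a <- national_state_ratio(a)
  ns_s <- national_state_ratio(s)
  ns <- list(actual = ns_a, simulated = ns_s,
             difference = unname(ns_a["national"] - ns_s["national"]),
             hellinger = hellinger(ns_a, ns_s))

  wt <- list(
    ks = ks_stat(a$waiting_time, s$waiting_time),
    kurtosis_diff = kurtosis_diff(a$waiting_time, s$waiting_time),
    median_log_ratio = median_log_ratio(
      max(stats::median(a$waiting_time), 0.5),
      max(stats::median(s$waiting_time), 0.5))
  )

  pct <- function(x) prop.table(table(factor(x$centre, levels = CENTRES)))
  sp <- list(actual = pct(a), simulated = pct(s),
             hellinger = hellinger(as.numeric(pct(a)), as.numeric(pct(s))))

  strat_vars <- list(
    state = function(x, pooled) x$recipient_state,
    age = function(x, pooled) band_or_quintile(x$recipient_age, NULL, "age"),
    epts = function(x, pooled) band_or_quintile(x$recipient_epts_pct, pooled,
                                                "quintile"),
    pra = function(x, pooled) band_or_quintile(x$recipient_pra, NULL, "pra"),
    blood_group = function(x, pooled) x$recipient_blood_group
  )
  pooled_epts <- c(a$recipient_epts_pct, s$recipient_epts_pct)
  stratified <- lapply(strat_vars, function(f) {
    ga <- f(a, pooled_epts); gs <- f(s, pooled_epts)
    groups <- sort(union(unique(ga), unique(gs)))
    med <- function(x, g, lab) {
      v <- x$waiting_time[g == lab]
      if (length(v) == 0) NA_real_ else max(stats::median(v), 0.5)
    }
    out <- data.frame(group = groups, stringsAsFactors = FALSE)
    out$actual_median <- vapply(groups, function(l) med(a, ga, l), numeric(1))
    out$simulated_median <- vapply(groups, function(l) med(s, gs, l),
                                   numeric(1))
    out$abs_log_ratio <- NA_real_
    have <- !is.na(out$actual_median) & !is.na(out$simulated_median)
    out$abs_log_ratio[have] <- median_log_ratio(out$actual_median[have],
                                                out$simulated_median[have])
    out
  })

  strat_mean <- mean(unlist(lapply(stratified, function(t)
    t$abs_log_ratio)), na.rm = TRUE)
  agg <- dissimilarity_score(
    bounded = c(ns$hellinger, wt$ks, sp$hellinger),
    unbounded = c(wt$kurtosis_diff, wt$median_log_ratio, strat_mean))

  structure(list(national_state = ns, waiting_time = wt, state_pct = sp,
                 stratified = stratified, dissimilarity = agg,
                 kurtosis_convention = "Pearson (non-excess), m4/m2^2"),
            class = "kap_acca")
}

#' Write an ACCA report to disk
#'
#' JSON for the scalar metrics plus one flat CSV per stratified table.
#'
#' @param report a `kap_acca` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_acca_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- list(
    national_state = report$national_state[c("difference", "hellinger")],
    waiting_time = report$waiting_time,
    state_pct = list(hellinger = report$state_pct$hellinger),
    dissimilarity = report$dissimilarity,
    kurtosis_convention = report$kurtosis_convention
  )
  jsonlite::write_json(scalars, file.path(dir, "acca_report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(report$stratified)) {
    utils::write.csv(report$stratified[[nm]],
                     file.path(dir, sprintf("acca_stratified_%s.csv", nm)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.kap_acca <- function(x, ...) {
  cat("Allocation characteristics comparison\n")
  cat(sprintf("  national proportion: actual %.3f vs simulated %.3f (H = %.3f)\n",
              x$national_state$actual["national"],
              x$national_state$simulated["national"],
              x$national_state$hellinger))
  cat(sprintf("  waiting time: KS %.3f, kurtosis diff %.3f, median |log-ratio| %.3f\n",
              x$waiting_time$ks, x$waiting_time$kurtosis_diff,
              x$waiting_time$median_log_ratio))
  cat(sprintf("  state percentages: H = %.3f\n", x$state_pct$hellinger))
  cat(sprintf("  aggregate dissimilarity: %.3f\n", x$dissimilarity))
  invisible(x)
}
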