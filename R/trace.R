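# Turning raw multi-segment O2 traces into the three kinetic descriptors
# (tau, R_in, R_st) and the Type A/B/C classification.

#' Configuration for trace feature extraction
#'
#' @param dead_time_s readings before this time are discarded (thermal
#'   equilibration and O2 diffusion into the condenser), s.
#' @param smooth_window centered moving-average window, points (odd). At 10 s
#'   sampling the default spans 210 s, far below typical induction times
#'   (1e4–1e5 s).
#' @param steady_tol relative tolerance around the median late slope used to
#'   grow the steady-phase fitting window.
#' @param init_frac fraction of the (post dead-time) trace span used for the
#'   initial-rate fit.
#' @param theta Type classification band: R_in/R_st within \code{[1-theta,
#'   1+theta]} is "no distinct initial phase" (Type A).
#' @param tau_min_s induction periods shorter than this are not considered
#'   resolvable and the oil is classified Type A.
#' @param min_points minimum number of usable readings.
#' @param rate_floor_sigma the steady slope must exceed this many standard
#'   errors to count as observed oxidation; otherwise the result is censored.
#' @return object of class \code{feature_config}.
#' @export
feature_config <- function(dead_time_s = 1000, smooth_window = 21L,
                           steady_tol = 0.2, init_frac = 0.15,
                           theta = 0.25, tau_min_s = 2000,
                           min_points = 50L, rate_floor_sigma = 2) {
  if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
  structure(list(dead_time_s = dead_time_s,
                 smooth_window = as.integer(smooth_window),
                 steady_tol = steady_tol, init_frac = init_frac,
                 theta = theta, tau_min_s = tau_min_s,
                 min_points = as.integer(min_points),
                 rate_floor_sigma = rate_floor_sigma),
            class = "feature_config")
}

#' Join re-aeration segments into a single consumption curve
#'
#' Within each segment, readings taken after the O2 reservoir has dropped below
#' \code{o2_floor_fraction} of the segment's initial charge are discarded as
#' O2-limited; the remaining pieces are converted to cumulative O2 consumed and
#' concatenated so that consumption is continuous across the seams. Time gaps
#' created by the discarded tails are closed by shifting later segments; the
#' applied offsets are recorded in the provenance attribute.
#'
#' @param segments an \code{o2_trace_set} or a list of data.frames with columns
#'   \code{time_s}, \code{o2_nmol} (and optionally \code{segment}).
#' @param protocol a [vessel_protocol()]; supplies the floor fraction.
#' @return object of class \code{consumption_curve}: a data.frame with
#'   \code{time_s} and \code{consumed_nmol}, plus \code{provenance} attribute.
#' @examples
#' tr <- simulate_autoxidation(kinetic_params(Ri = 1e-6), vessel_protocol(),
#'                             t_end_s = 2e4, sample_interval_s = 50)
#' curve <- join_segments(tr, vessel_protocol())
#' @export
join_segments <- function(segments, protocol = vessel_protocol()) {
  if (inherits(segments, "o2_trace_set")) segments <- unclass(segments)
  if (is.data.frame(segments)) segments <- list(segments)
  stopifnot(length(segments) >= 1L)

  floor_frac <- protocol$o2_floor_fraction
  time_out <- numeric(0); cons_out <- numeric(0)
  prov <- list(); cum0 <- 0; t_shift <- 0; prev_end <- NULL; floor_ref <- NULL
  seg_ids <- integer(0)

  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (!all(c("time_s", "o2_nmol") %in% names(s)))
      stop("join_segments: segment ", i, " lacks time_s/o2_nmol columns")
    if (any(diff(s$time_s) <= 0))
      stop("join_segments: segment ", i, " has non-increasing time")
    o2_init <- s$o2_nmol[1]
    # the floor references the experiment's initial charge: re-aerated
    # segments restart from (nearly) the same level, while a segment recorded
    # without re-aeration is recognized as O2-starved throughout
    if (is.null(floor_ref)) floor_ref <- o2_init
    keep <- s$o2_nmol >= floor_frac * floor_ref
    if (!any(keep)) {
      warning("join_segments: segment ", i,
              " entirely below the O2 floor; dropped")
      next
    }
    # keep the leading run above the floor (noise can dip single points below)
    last_keep <- if (all(keep)) length(keep) else which(!keep)[1] - 1L
    if (last_keep < 2L) {
      warning("join_segments: segment ", i,
              " has <2 usable readings; dropped")
      next
    }
    s <- s[seq_len(last_keep), ]
    consumed <- o2_init - s$o2_nmol
    if (is.null(prev_end)) {
      t_shift <- 0
    } else {
      dt <- stats::median(diff(s$time_s))
      t_shift <- (prev_end - s$time_s[1]) + dt
    }
    prov[[length(prov) + 1L]] <-
      list(segment = if (!is.null(s$segment)) s$segment[1] else i - 1L,
           n_points = nrow(s), time_offset_s = t_shift,
           consumption_offset_nmol = cum0)
    time_out <- c(time_out, s$time_s + t_shift)
    cons_out <- c(cons_out, consumed + cum0)
    seg_ids <- c(seg_ids, rep(prov[[length(prov)]]$segment, nrow(s)))
    prev_end <- time_out[length(time_out)]
    cum0 <- cons_out[length(cons_out)]
  }
  if (length(time_out) == 0L)
    stop("join_segments: no usable data after floor filtering")
  out <- data.frame(time_s = time_out, consumed_nmol = cons_out,
                    segment = seg_ids)
  structure(out, provenance = prov, class = c("consumption_curve",
                                              "data.frame"))
}

#' @export
print.consumption_curve <- function(x, ...) {
  cat("O2 consumption curve: ", nrow(x), " points, ",
      length(attr(x, "provenance")), " segment(s), span ",
      sprintf("%.0f", max(x$time_s)), " s, ",
      sprintf("%.0f", max(x$consumed_nmol)), " nmol consumed\n", sep = "")
  invisible(x)
}

#' @export
plot.consumption_curve <- function(x, ...) {
  plot(x$time_s, x$consumed_nmol, type = "l", xlab = "time (s)",
       ylab = "O2 consumed (nmol)", ...)
  invisible(x)
}

moving_average <- function(y, w) {
  if (w <= 1L || length(y) < w) return(y)
  sm <- stats::filter(y, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- y[is.na(sm)]   # edges keep raw values
  sm
}

#' Extract induction period and oxygen-uptake rates from a consumption curve
#'
#' Implements the tangent-intersection construction used by induction-time
#' instruments: after discarding the dead time and smoothing, a steady-phase
#' regression line is fitted over the maximal late window in which the local
#' slope stays within \code{steady_tol} of its median, an initial-phase line is
#' fitted over the first \code{init_frac} of the trace, and the induction
#' period \eqn{\tau} is the time coordinate of the two lines' intersection.
#'
#' Classification: Type A (linear from the start) when the initial and steady
#' rates agree within \code{theta} or \eqn{\tau} is below \code{tau_min_s};
#' Type B (induction then fast) when the initial rate is distinctly smaller;
#' Type C (initial burst then slow) when it is distinctly larger. \eqn{\tau}
#' is reported as 0 for Types A and C.
#'
#' @param curve a [join_segments()] result (or data.frame with \code{time_s},
#'   \code{consumed_nmol}).
#' @param config a [feature_config()].
#' @return object of class \code{trace_features} with fields \code{tau_s},
#'   \code{R_in_nmol_s}, \code{R_st_nmol_s}, \code{oil_type} ("A","B","C"),
#'   \code{censored} (TRUE when no oxidation is resolved) and
#'   \code{diagnostics} (fit windows, residual scales, per-segment slopes,
#'   config echo).
#' @examples
#' t <- seq(0, 6e4, by = 10)
#' y <- ifelse(t < 3e4, 5 * t, 5 * 3e4 + 50 * (t - 3e4))
#' f <- estimate_features(data.frame(time_s = t, consumed_nmol = y))
#' f$tau_s   # 30000
#' @export
estimate_features <- function(curve, config = feature_config()) {
  stopifnot(is.data.frame(curve))
  df <- curve[curve$time_s >= config$dead_time_s, , drop = FALSE]
  if (nrow(df) < config$min_points)
    stop("estimate_features: only ", nrow(df), " readings after the dead ",
         "time; need at least ", config$min_points)

  t <- df$time_s; y <- df$consumed_nmol
  n <- length(t)
  sm <- moving_average(y, config$smooth_window)

  # local slopes by centered differences; the half-window scales with the
  # trace length so slope noise stays well below the steady slope itself
  h <- max((config$smooth_window - 1L) %/% 2L, 1L, round(0.015 * n))
  idx <- (h + 1L):(n - h)
  slope <- rep(NA_real_, n)
  slope[idx] <- (sm[idx + h] - sm[idx - h]) / (t[idx + h] - t[idx - h])

  # steady phase: maximal contiguous late window with slope near the late median
  late <- idx[idx > stats::quantile(idx, 0.75)]
  med <- stats::median(slope[late], na.rm = TRUE)
  tol <- config$steady_tol * max(abs(med), .Machine$double.eps)
  ok <- abs(slope - med) <= tol
  ok[is.na(ok)] <- FALSE
  i_end <- max(which(ok), n - h)
  i_start <- i_end
  while (i_start > 1L && isTRUE(ok[i_start - 1L])) i_start <- i_start - 1L
  steady_idx <- i_start:min(i_end + h, n)
  if (length(steady_idx) < 5L) steady_idx <- idx[idx > stats::quantile(idx, 0.85)]
  fit_st <- stats::lm(y[steady_idx] ~ t[steady_idx])
  b_st <- unname(stats::coef(fit_st)[2]); a_st <- unname(stats::coef(fit_st)[1])
  se_st <- suppressWarnings(summary(fit_st)$coefficients[2, 2])

  # initial phase: first init_frac of the span, never overlapping the steady
  # window; once a first tau estimate exists, refit the tangent over the
  # leading part of the inhibition phase it delimits and re-intersect
  t0 <- t[1]; span <- t[n] - t0
  init_window <- function(cut) {
    idx <- which(t <= cut)
    idx <- idx[idx < min(steady_idx)]
    if (length(idx) < 3L) idx <- seq_len(max(3L, min(10L, n %/% 4L)))
    idx
  }
  first_cut <- t0 + config$init_frac * span
  init_cut <- first_cut
  tau_hat <- NA_real_
  for (iter in 1:3) {
    init_idx <- init_window(init_cut)
    fit_in <- stats::lm(y[init_idx] ~ t[init_idx])
    b_in <- unname(stats::coef(fit_in)[2]); a_in <- unname(stats::coef(fit_in)[1])
    if (abs(b_st - b_in) <= 1e-12 * max(abs(b_st), 1)) break
    tau_hat <- (a_in - a_st) / (b_st - b_in)
    if (!is.finite(tau_hat) || tau_hat <= t0) break
    new_cut <- min(t0 + 0.6 * (tau_hat - t0), t[min(steady_idx)])
    if (abs(new_cut - init_cut) < span * 1e-3) break
    init_cut <- new_cut
  }

  # initial RATE: the slope at the very start, not a wide-window chord — the
  # inhibited phase accelerates as the antioxidant depletes, so a quadratic
  # fit over a short leading window, differentiated at its start, removes the
  # curvature bias that a straight chord picks up
  rin_cut <- if (is.finite(tau_hat) && tau_hat > t0)
    min(first_cut, t0 + 0.3 * (tau_hat - t0)) else first_cut
  rin_idx <- init_window(rin_cut)
  if (length(rin_idx) >= 8L) {
    tc <- t[rin_idx] - t[rin_idx][1]
    qf <- stats::lm(y[rin_idx] ~ tc + I(tc^2))
    b_rin <- unname(stats::coef(qf)[2])
    if (!is.finite(b_rin)) b_rin <- b_in
  } else b_rin <- b_in

  censored <- FALSE
  if (b_st <= 0 || b_st <= config$rate_floor_sigma * se_st) {
    censored <- TRUE
    oil_type <- NA_character_; tau <- NA_real_
  } else {
    tau_raw <- if (abs(b_st - b_in) > 1e-12 * max(abs(b_st), 1))
      (a_in - a_st) / (b_st - b_in) else NA_real_
    ratio <- max(b_rin, 0) / b_st
    if (ratio > 1 + config$theta) {
      oil_type <- "C"; tau <- 0
    } else if (ratio < 1 - config$theta &&
               is.finite(tau_raw) && tau_raw >= config$tau_min_s) {
      oil_type <- "B"; tau <- tau_raw
    } else {
      oil_type <- "A"; tau <- 0
    }
  }

  seg_slopes <- NULL
  if (!is.null(df$segment)) {
    seg_slopes <- vapply(split(seq_len(n), df$segment), function(ii) {
      if (length(ii) < 3L) return(NA_real_)
      unname(stats::coef(stats::lm(y[ii] ~ t[ii]))[2])
    }, 1)
  }

  structure(list(
    tau_s = tau,
    R_in_nmol_s = max(b_rin, 0),
    R_st_nmol_s = max(b_st, 0),
    oil_type = oil_type,
    censored = censored,
    diagnostics = list(
      steady_window_s = range(t[steady_idx]),
      initial_window_s = range(t[init_idx]),
      initial_rate_window_s = range(t[rin_idx]),
      steady_slope_se = se_st,
      steady_intercept_nmol = a_st,
      initial_intercept_nmol = a_in,
      residual_sd_nmol = stats::sd(stats::residuals(fit_st)),
      per_segment_slopes = seg_slopes,
      config = config
    )
  ), class = "trace_features")
}

#' @export
print.trace_features <- function(x, ...) {
  if (x$censored) {
    cat("Trace features: censored (no oxidation resolved above noise)\n")
    return(invisible(x))
  }
  cat("Trace features (Type ", x$oil_type, " oil)\n", sep = "")
  cat(sprintf("  tau   = %.3g s\n", x$tau_s))
  cat(sprintf("  R_in  = %.3g nmol/s\n", x$R_in_nmol_s))
  cat(sprintf("  R_st  = %.3g nmol/s\n", x$R_st_nmol_s))
  invisible(x)
}

#' Compare induction periods with Oil Stability Index values
#'
#' The headspace induction period and the Rancimat OSI both rank oxidative
#' stability; the former is generally shorter (it is measured at a higher
#' temperature, where radicals are produced faster and antioxidants spent
#' sooner). This helper reports the rank agreement of the two orderings and
#' the per-oil ratio; it asserts nothing causal.
#'
#' @param panel data.frame with columns \code{tau_s} and \code{OSI_h} (and
#'   optionally \code{oil_id}).
#' @return list with \code{rank_correlation} (Spearman), \code{ratios}
#'   (tau / OSI, dimensionless after conversion to hours), \code{n_used},
#'   \code{n_skipped}.
#' @export
compare_tau_to_osi <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("tau_s", "OSI_h") %in% names(panel)))
  ok <- is.finite(panel$tau_s) & is.finite(panel$OSI_h)
  n_skipped <- sum(!ok)
  use <- panel[ok, , drop = FALSE]
  if (nrow(use) < 3L)
    stop("compare_tau_to_osi: need at least 3 oils with both tau and OSI")
  rho <- stats::cor(use$tau_s, use$OSI_h, method = "spearman")
  ratios <- (use$tau_s / 3600) / use$OSI_h
  names(ratios) <- if (!is.null(use$oil_id)) use$oil_id else rownames(use)
  list(rank_correlation = rho, ratios = ratios,
       n_used = nrow(use), n_skipped = n_skipped)
}
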