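# Parameter-level analyses: initiation rate by propyl-gallate standard
# addition, composition-based regressions of the steady oxidation rate and of
# the PG effect, and blend-stability prediction.

#' Published reference models for the steady oxidation rate
#'
#' Named coefficient sets of the two linear models relating the steady
#' oxygen-uptake rate (nmol/s, whole vessel) to the percent content of mono-,
#' di- and tri-unsaturated fatty acids, the second additionally to the acid
#' value (mg KOH/g):
#' \describe{
#'   \item{\code{"unsaturation"}}{R_st = 20.1 + 0.570 MO + 1.54 DI + 2.65 TRI}
#'   \item{\code{"unsaturation_acidity"}}{R_st = 9.82 + 0.634 MO + 1.63 DI +
#'     2.65 TRI + 0.154 H+}
#' }
#'
#' @return named list of coefficient vectors.
#' @seealso [predict_rst()]
#' @export
rst_reference_models <- function() {
  list(
    unsaturation = c(intercept = 20.1, MO_pct = 0.570, DI_pct = 1.54,
                     TRI_pct = 2.65),
    unsaturation_acidity = c(intercept = 9.82, MO_pct = 0.634, DI_pct = 1.63,
                             TRI_pct = 2.65, acidity_mgKOH_g = 0.154)
  )
}

#' Predict the steady oxidation rate from composition
#'
#' Evaluates a steady-rate linear model — either one of the packaged reference
#' models (by name), a raw coefficient vector, or a fitted [fit_rst_model()]
#' object — at the supplied composition.
#'
#' @param model \code{"unsaturation"}, \code{"unsaturation_acidity"}, a named
#'   numeric vector with an \code{intercept} element, or an \code{rst_fit}.
#' @param composition named list/vector or data.frame with \code{MO_pct},
#'   \code{DI_pct}, \code{TRI_pct} and, where the model uses it,
#'   \code{acidity_mgKOH_g}. Missing predictors default to 0.
#' @return predicted rate(s), nmol/s.
#' @examples
#' predict_rst("unsaturation", c(MO_pct = 0, DI_pct = 0, TRI_pct = 0))  # 20.1
#' predict_rst("unsaturation", c(MO_pct = 100))                         # 77.1
#' @export
predict_rst <- function(model, composition) {
  if (inherits(model, "rst_fit")) {
    cf <- stats::coef(model)
  } else if (is.character(model)) {
    ref <- rst_reference_models()
    if (!model %in% names(ref))
      stop("predict_rst: unknown reference model '", model, "'; available: ",
           paste(names(ref), collapse = ", "))
    cf <- ref[[model]]
  } else if (is.numeric(model) && "intercept" %in% names(model)) {
    cf <- model
  } else stop("predict_rst: unusable model specification")

  comp <- as.data.frame(as.list(composition))
  preds <- setdiff(names(cf), "intercept")
  out <- rep(unname(cf["intercept"]), max(nrow(comp), 1L))
  for (p in preds) {
    v <- if (p %in% names(comp)) comp[[p]] else 0
    out <- out + unname(cf[p]) * v
  }
  out
}

#' Fit the steady-rate composition regression
#'
#' Ordinary least squares of the measured steady oxygen-uptake rate on the
#' unsaturated fatty-acid percentages (and optionally the acid value), the
#' empirical model used to show that the fatty-acid composition is the main
#' determinant of the oxidation rate.
#'
#' @param panel data.frame of oil records with columns \code{R_st_nmol_s},
#'   \code{MO_pct}, \code{DI_pct}, \code{TRI_pct} and (if used)
#'   \code{acidity_mgKOH_g}.
#' @param include_acidity add the acid value as a fourth predictor.
#' @return object of classes \code{rst_fit}, \code{oxkin_fit}: coefficients,
#'   classical and heteroscedasticity-consistent (HC3) standard errors,
#'   r-squared, dropped-row bookkeeping; supports \code{coef},
#'   \code{summary}, \code{predict}, \code{print}.
#' @export
fit_rst_model <- function(panel, include_acidity = FALSE) {
  stopifnot(is.data.frame(panel))
  preds <- c("MO_pct", "DI_pct", "TRI_pct",
             if (include_acidity) "acidity_mgKOH_g")
  need <- c("R_st_nmol_s", preds)
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("fit_rst_model: panel lacks columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(panel[, need])
  n_dropped <- sum(!ok)
  if (n_dropped)
    message("fit_rst_model: dropped ", n_dropped, " row(s) with missing values")
  d <- panel[ok, , drop = FALSE]
  if (nrow(d) < length(preds) + 2L)
    stop("fit_rst_model: need at least ", length(preds) + 2L,
         " complete rows, have ", nrow(d))
  X <- cbind(1, as.matrix(d[, preds]))
  if (kappa(X, exact = TRUE) > 1e8)
    stop("fit_rst_model: predictor matrix is (nearly) collinear; ",
         "refusing an unstable fit")
  fml <- stats::as.formula(paste("R_st_nmol_s ~", paste(preds, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  sm <- suppressWarnings(summary(fit))
  cf <- stats::coef(fit)
  names(cf)[1] <- "intercept"
  structure(list(
    model_name = if (include_acidity) "unsaturation_acidity" else "unsaturation",
    coefficients = cf,
    se = stats::setNames(sm$coefficients[, 2], names(cf)),
    # measured uptake rates carry noise roughly proportional to their size,
    # so heteroscedasticity-consistent errors are reported alongside
    se_robust = stats::setNames(
      suppressWarnings(sqrt(diag(sandwich::vcovHC(fit, type = "HC3")))),
      names(cf)),
    r2 = sm$r.squared,
    n_obs = nrow(d),
    n_dropped = n_dropped,
    residuals = stats::residuals(fit),
    lm = fit
  ), class = c("rst_fit", "oxkin_fit"))
}

#' @export
coef.oxkin_fit <- function(object, ...) object$coefficients

#' @export
print.oxkin_fit <- function(x, ...) {
  cat("Model '", x$model_name, "' (n = ", x$n_obs, ", r2 = ",
      sprintf("%.3f", x$r2), ")\n", sep = "")
  cf <- data.frame(estimate = x$coefficients, se = x$se)
  print(signif(cf, 4))
  if (!is.null(x$outlier_ids) && length(x$outlier_ids))
    cat("flagged outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.oxkin_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$lm)) print(summary(object$lm))
  invisible(object)
}

#' @export
predict.rst_fit <- function(object, newdata, ...) {
  predict_rst(object, newdata)
}

#' Estimate the initiation rate (per trapped radical) by standard addition
#'
#' A fixed dose of propyl gallate extends the induction period by
#' \eqn{n [PG] / R_i}; inverting this gives \eqn{R_i/n = [PG]/(\tau_{PG} -
#' \tau)}. Because the PG stoichiometric factor at the working temperature is
#' not known, only the ratio \eqn{R_i/n} is reported, never \eqn{R_i} itself.
#' Oils where PG produces no measurable extension (typically high iron or high
#' acidity) yield a censored result rather than an error.
#'
#' @param tau_s induction period without PG, s (vector).
#' @param tau_PG_s induction period with PG, s.
#' @param pg_molar PG dose, M (default: 500 mg/L).
#' @return data.frame with \code{Ri_over_n} (M/s; \code{NA} where censored)
#'   and \code{censored} (logical: PG ineffective).
#' @examples
#' estimate_Ri_over_n(0, 4.72e4, pg_molar = 2.36e-3)  # 5e-8 M/s
#' @export
estimate_Ri_over_n <- function(tau_s, tau_PG_s,
                               pg_molar = pg_molar_from_mg_L(500)) {
  stopifnot(length(tau_s) == length(tau_PG_s), pg_molar > 0)
  ext <- tau_PG_s - tau_s
  censored <- !is.finite(ext) | ext <= 0
  out <- data.frame(Ri_over_n = ifelse(censored, NA_real_, pg_molar / ext),
                    censored = censored)
  attr(out, "pg_molar") <- pg_molar
  out
}

pg_effect_data <- function(panel, min_oils = 5L) {
  stopifnot(is.data.frame(panel))
  need <- c("tau_s", "tau_PG_s", "bis_allylic_M")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("PG-effect fit: panel lacks columns: ", paste(miss, collapse = ", "))
  excl <- if (!is.null(panel$excluded_flag)) panel$excluded_flag %in% TRUE
          else rep(FALSE, nrow(panel))
  d <- panel[!excl, , drop = FALSE]
  d$pg_effect_s <- d$tau_PG_s - d$tau_s
  d <- d[is.finite(d$pg_effect_s) & d$pg_effect_s > 0 &
           is.finite(d$bis_allylic_M), , drop = FALSE]
  if (nrow(d) < min_oils)
    stop("PG-effect fit: only ", nrow(d), " usable oils after exclusions; ",
         "need at least ", min_oils)
  d
}

#' Fit the hyperbolic PG-effect model
#'
#' Nonlinear least squares of the PG-induced inhibition extension on the
#' bis-allylic group concentration,
#' \deqn{\tau_{PG} - \tau = a / (b + [\mathrm{bis\text{-}allylic}]),}
#' the form expected when the initiation rate is proportional to the
#' bis-allylic content (plus a small baseline). Oils flagged as excluded
#' (high iron / high acidity, where PG is ineffective) are removed first.
#' Start values come from the linearized reciprocal fit.
#'
#' @param panel data.frame with \code{tau_s}, \code{tau_PG_s},
#'   \code{bis_allylic_M} and optionally \code{excluded_flag}, \code{oil_id}.
#' @return \code{pg_hyperbolic_fit} / \code{oxkin_fit} with coefficients
#'   \code{a} (s M) and \code{b} (M), r-squared and residuals.
#' @export
fit_pg_effect_hyperbolic <- function(panel) {
  d <- pg_effect_data(panel)
  y <- d$pg_effect_s; x <- d$bis_allylic_M
  lin <- stats::lm(I(1 / y) ~ x)
  sl <- unname(stats::coef(lin)[2]); ic <- unname(stats::coef(lin)[1])
  a0 <- if (sl > 0) 1 / sl else max(y) * (0.1 + stats::median(x))
  b0 <- max(ic * a0, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a / (b + x), start = list(a = a0, b = b0),
                      lower = c(a = 0, b = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit_pg_effect_hyperbolic: nonlinear fit failed (",
           conditionMessage(e), "); linearized start was a = ", signif(a0, 4),
           ", b = ", signif(b0, 4), call. = FALSE)
  )
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(
    model_name = "pg_effect_hyperbolic",
    coefficients = cf,
    se = tryCatch(summary(fit)$coefficients[, 2],
                  error = function(e) rep(NA_real_, 2)),
    r2 = r2, n_obs = length(y), residuals = res,
    data = data.frame(bis_allylic_M = x, pg_effect_s = y),
    nls = fit
  ), class = c("pg_hyperbolic_fit", "oxkin_fit"))
}

#' @export
predict.pg_hyperbolic_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$bis_allylic_M else newdata
  cf <- object$coefficients
  unname(cf["a"] / (cf["b"] + x))
}

#' Fit the reciprocal-linearized PG-effect model with outlier flagging
#'
#' Ordinary least squares of \eqn{1/(\tau_{PG} - \tau)} on the bis-allylic
#' concentration — the linearization under which proportional initiation gives
#' a straight line through (nearly) the origin. Points whose externally
#' studentized residual exceeds \code{outlier_sigma} are flagged (PG
#' interacting with impurities is the usual cause) and the line is refitted
#' without them; both fits are reported.
#'
#' @param panel as for [fit_pg_effect_hyperbolic()].
#' @param outlier_sigma studentized-residual threshold (default 2.5).
#' @return \code{pg_reciprocal_fit} / \code{oxkin_fit}: coefficients
#'   \code{slope} (1/(s M)) and \code{intercept} (1/s) of the outlier-cleaned
#'   fit, \code{outlier_ids}, and the full-data fit under \code{$full_fit}.
#' @export
fit_pg_effect_linear_reciprocal <- function(panel, outlier_sigma = 2.5) {
  d <- pg_effect_data(panel)
  y <- 1 / d$pg_effect_s; x <- d$bis_allylic_M
  ids <- if (!is.null(d$oil_id)) as.character(d$oil_id)
         else as.character(seq_along(x))
  fit_all <- stats::lm(y ~ x)
  sig_all <- suppressWarnings(summary(fit_all)$sigma)
  if (sig_all <= 1e-8 * max(stats::sd(y), .Machine$double.eps)) {
    # numerically exact fit: nothing to flag
    out_mask <- rep(FALSE, length(y))
  } else {
    stud <- stats::rstudent(fit_all)
    # a non-finite deletion residual means the leave-one-out fit is (near)
    # exact — the point in question is then an extreme outlier if its raw
    # residual carries essentially all the misfit
    big_raw <- abs(stats::residuals(fit_all)) > 3 * sig_all
    out_mask <- (is.finite(stud) & abs(stud) > outlier_sigma) |
      (!is.finite(stud) & big_raw)
  }
  outlier_ids <- ids[out_mask]
  fit <- if (any(out_mask)) stats::lm(y ~ x, subset = !out_mask) else fit_all
  sm <- suppressWarnings(summary(fit))
  pack <- function(f, s) {
    cf <- stats::setNames(stats::coef(f), c("intercept", "slope"))
    list(coefficients = cf[c("slope", "intercept")],
         se = stats::setNames(s$coefficients[, 2], c("intercept", "slope"))[
           c("slope", "intercept")],
         r2 = s$r.squared)
  }
  main <- pack(fit, sm)
  structure(list(
    model_name = "pg_effect_reciprocal",
    coefficients = main$coefficients,
    se = main$se,
    r2 = main$r2,
    n_obs = sum(!out_mask),
    outlier_ids = outlier_ids,
    residuals = stats::residuals(fit),
    full_fit = c(pack(fit_all, suppressWarnings(summary(fit_all))),
                 list(n_obs = length(y))),
    data = data.frame(oil_id = ids, bis_allylic_M = x,
                      reciprocal_effect = y, outlier = out_mask)
  ), class = c("pg_reciprocal_fit", "oxkin_fit"))
}

#' @export
predict.pg_reciprocal_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$bis_allylic_M else newdata
  cf <- object$coefficients
  unname(cf["intercept"] + cf["slope"] * x)
}

#' Predict the stability of an oil blend
#'
#' Mixing-rule prediction anchored to the inhibition-duration law
#' \eqn{\tau = n[AH]/R_i}: the antioxidant pools of the components mix
#' linearly, as do their initiation rates, so
#' \deqn{\tau_{blend} = \frac{\sum_i \phi_i \tau_i R_i}{\sum_i \phi_i R_i}}
#' (computed on the \eqn{R_i/n} basis, so the unknown stoichiometric factor
#' cancels). The steady rate is predicted from the volume-weighted composition
#' through a steady-rate model. The rationale states which blending regime
#' applies: a low-initiation unstable component can be stabilized by a stable
#' oil, whereas a high-initiation component drains the stable oil's
#' antioxidants and the blend inherits (roughly) the unstable behaviour.
#'
#' @param components data.frame, one row per component, with \code{tau_s},
#'   either \code{Ri_over_n} (M/s) or \code{tau_s}/\code{tau_PG_s} to derive
#'   it, and (for the steady-rate prediction) \code{MO_pct}, \code{DI_pct},
#'   \code{TRI_pct}, \code{acidity_mgKOH_g}.
#' @param fractions volume fractions, summing to 1.
#' @param rst_model model passed to [predict_rst()].
#' @param pg_molar PG dose used when deriving \code{Ri_over_n}.
#' @return object of class \code{blend_prediction}: \code{tau_s},
#'   \code{R_st_nmol_s}, per-component table, \code{rationale}.
#' @examples
#' comps <- data.frame(tau_s = c(8e4, 0), Ri_over_n = c(5e-8, 5e-8),
#'                     MO_pct = c(40, 20), DI_pct = c(10, 30),
#'                     TRI_pct = c(0, 5), acidity_mgKOH_g = c(0.5, 1))
#' predict_blend(comps, c(0.5, 0.5))$tau_s  # 4e4
#' @export
predict_blend <- function(components, fractions,
                          rst_model = "unsaturation_acidity",
                          pg_molar = pg_molar_from_mg_L(500)) {
  stopifnot(is.data.frame(components), nrow(components) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("predict_blend: fractions must sum to 1")
  if (any(fractions < 0)) stop("predict_blend: fractions must be >= 0")
  if (is.null(components$tau_s) || any(!is.finite(components$tau_s)))
    stop("predict_blend: every component needs tau_s")

  ri <- components$Ri_over_n
  if (is.null(ri) && !is.null(components$tau_PG_s))
    ri <- estimate_Ri_over_n(components$tau_s, components$tau_PG_s,
                             pg_molar)$Ri_over_n
  qualitative_only <- is.null(ri) || any(!is.finite(ri))
  if (qualitative_only) {
    warning("predict_blend: missing Ri/n for some components; ",
            "returning a qualitative prediction only")
    tau_blend <- NA_real_
  } else {
    # pooled antioxidant (sum phi_i * tau_i * Ri_i) over pooled initiation
    tau_blend <- sum(fractions * components$tau_s * ri) / sum(fractions * ri)
  }

  rst_blend <- NA_real_
  comp_cols <- c("MO_pct", "DI_pct", "TRI_pct", "acidity_mgKOH_g")
  have <- intersect(comp_cols, names(components))
  if (length(intersect(c("MO_pct", "DI_pct", "TRI_pct"), have)) == 3L) {
    mixed <- lapply(have, function(cc) sum(fractions * components[[cc]]))
    names(mixed) <- have
    rst_blend <- predict_rst(rst_model, mixed)
  }

  rationale <- if (qualitative_only) {
    "initiation rates unknown: only composition-level prediction available"
  } else {
    stable <- which.max(components$tau_s)
    unstable <- which.min(components$tau_s)
    if (stable == unstable ||
        diff(range(components$tau_s)) < 0.1 * max(components$tau_s, 1)) {
      "components have similar induction periods; blend behaves like either"
    } else if (ri[unstable] <= 2 * ri[stable]) {
      paste0("stabilizable blend: the short-tau component has a low ",
             "initiation rate (high PG effect), so antioxidants donated by ",
             "the stable component persist in the blend")
    } else {
      paste0("antioxidant-draining blend: the short-tau component's high ",
             "initiation rate consumes the stable component's antioxidants; ",
             "the blend stays close to the unstable behaviour")
    }
  }

  structure(list(
    tau_s = tau_blend,
    R_st_nmol_s = rst_blend,
    components = data.frame(fraction = fractions,
                            tau_s = components$tau_s,
                            Ri_over_n = if (qualitative_only) NA_real_ else ri),
    rationale = rationale
  ), class = "blend_prediction")
}

#' @export
print.blend_prediction <- function(x, ...) {
  cat("Blend stability prediction\n")
  cat(sprintf("  tau  = %.3g s\n", x$tau_s))
  if (is.finite(x$R_st_nmol_s))
    cat(sprintf("  R_st = %.3g nmol/s\n", x$R_st_nmol_s))
  cat("  ", x$rationale, "\n", sep = "")
  invisible(x)
}
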