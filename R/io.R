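# Format readers/writers and report rendering. Units are fixed at the
# boundary: time s, O2 amounts nmol, concentrations M, acid value mg KOH/g,
# iron ppm, composition percent. Comma-separated, "." decimal, header row
# mandatory.

#' Read / write oxygen-uptake trace CSV files
#'
#' The trace format has a mandatory header \code{time_s,o2_nmol} and an
#' optional \code{segment} column (ordinal between re-aerations; absent means
#' a single segment). A metadata sidecar JSON (same path with \code{.json}
#' appended) is written alongside when the trace carries protocol metadata,
#' and read back if present.
#'
#' @param path CSV file path.
#' @return \code{read_trace_csv}: an \code{o2_trace_set} (list of segment
#'   data.frames).
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("read_trace_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "o2_nmol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_trace_csv: ", path, ": malformed header, missing column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$segment)) df$segment <- 0L
  for (cc in c("time_s", "o2_nmol", "segment")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop("read_trace_csv: ", path, ": non-numeric '", cc, "' at data line",
           if (length(bad) > 1) "s" else "", " ",
           paste(utils::head(bad + 1L, 5), collapse = ", "))
    if (anyNA(v))
      stop("read_trace_csv: ", path, ": missing '", cc, "' at data line ",
           which(is.na(v))[1] + 1L)
    df[[cc]] <- v
  }
  segs <- split(df, df$segment)
  for (s in segs) {
    if (any(diff(s$time_s) <= 0)) {
      i <- which(diff(s$time_s) <= 0)[1]
      stop("read_trace_csv: ", path, ": non-monotone time in segment ",
           s$segment[1], " near data line ",
           which(df$time_s == s$time_s[i + 1])[1] + 1L)
    }
    if (any(s$o2_nmol < 0))
      stop("read_trace_csv: ", path, ": negative O2 amount in segment ",
           s$segment[1])
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  structure(unname(lapply(segs, function(s) {
    rownames(s) <- NULL
    s[, c("time_s", "o2_nmol", "segment")]
  })), class = "o2_trace_set", metadata = meta)
}

#' @rdname read_trace_csv
#' @param segments an \code{o2_trace_set} or list of segment data.frames.
#' @param metadata optional list written to the JSON sidecar (sample id,
#'   temperature, protocol fields).
#' @export
write_trace_csv <- function(segments, path, metadata = NULL) {
  if (inherits(segments, "o2_trace_set")) {
    if (is.null(metadata)) {
      proto <- attr(segments, "protocol")
      if (!is.null(proto)) metadata <- list(protocol = unclass(proto))
    }
    segments <- unclass(segments)
  }
  df <- do.call(rbind, c(segments, list(make.row.names = FALSE)))
  utils::write.csv(df[, c("time_s", "o2_nmol", "segment")], path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(metadata))
    jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

panel_columns <- c("oil_id", "SAT_pct", "MO_pct", "DI_pct", "TRI_pct",
                   "bis_allylic_M", "acidity_mgKOH_g", "iron_ppm",
                   "peroxide_mEqO2_kg", "tau_s", "tau_PG_s", "R_in_nmol_s",
                   "R_st_nmol_s", "OSI_h", "excluded_flag")

#' Read / write oil-panel CSV files
#'
#' The panel format is one row per oil with the columns \code{oil_id},
#' \code{SAT_pct}, \code{MO_pct}, \code{DI_pct}, \code{TRI_pct},
#' \code{bis_allylic_M}, \code{acidity_mgKOH_g}, \code{iron_ppm},
#' \code{peroxide_mEqO2_kg}, \code{tau_s}, \code{tau_PG_s},
#' \code{R_in_nmol_s}, \code{R_st_nmol_s}, \code{OSI_h},
#' \code{excluded_flag}; measured descriptors may be empty. Record invariants
#' (percentages in range and summing to at most 100, non-negative
#' concentrations and rates) are enforced on load: all violations are
#' collected and reported together, and offending rows are rejected. A
#' non-flagged oil with \code{tau_PG_s < tau_s} is kept with a warning (its PG
#' effect is censored downstream).
#'
#' @param path CSV file path.
#' @return \code{read_panel_csv}: data.frame of oil records.
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop("read_panel_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"oil_id" %in% names(df))
    stop("read_panel_csv: ", path, ": malformed header (no oil_id column)")
  if (is.null(df$excluded_flag)) df$excluded_flag <- FALSE
  df$excluded_flag <- as.logical(df$excluded_flag)

  problems <- character(0)
  bad_rows <- logical(nrow(df))
  pct_cols <- intersect(c("SAT_pct", "MO_pct", "DI_pct", "TRI_pct"), names(df))
  nonneg <- intersect(c("bis_allylic_M", "acidity_mgKOH_g", "iron_ppm",
                        "peroxide_mEqO2_kg", "tau_s", "tau_PG_s",
                        "R_in_nmol_s", "R_st_nmol_s", "OSI_h"), names(df))
  for (i in seq_len(nrow(df))) {
    row_problems <- character(0)
    for (cc in pct_cols) {
      v <- df[[cc]][i]
      if (is.finite(v) && (v < 0 || v > 100))
        row_problems <- c(row_problems,
                          paste0(cc, " = ", v, " outside [0, 100]"))
    }
    if (length(pct_cols) == 4L) {
      tot <- sum(unlist(df[i, pct_cols]), na.rm = TRUE)
      if (is.finite(tot) && tot > 100 + 1)
        row_problems <- c(row_problems,
                          paste0("composition sums to ", round(tot, 2), " %"))
    }
    for (cc in nonneg) {
      v <- df[[cc]][i]
      if (is.finite(v) && v < 0)
        row_problems <- c(row_problems, paste0(cc, " = ", v, " is negative"))
    }
    if (length(row_problems)) {
      bad_rows[i] <- TRUE
      problems <- c(problems, paste0("row ", i, " (", df$oil_id[i], "): ",
                                     paste(row_problems, collapse = "; ")))
    }
  }
  if (length(problems)) {
    warning("read_panel_csv: ", path, ": rejected ", sum(bad_rows),
            " row(s):\n  ", paste(problems, collapse = "\n  "))
    df <- df[!bad_rows, , drop = FALSE]
  }
  if (all(c("tau_s", "tau_PG_s") %in% names(df))) {
    odd <- which(is.finite(df$tau_s) & is.finite(df$tau_PG_s) &
                   df$tau_PG_s < df$tau_s & !df$excluded_flag)
    if (length(odd))
      warning("read_panel_csv: tau_PG < tau on non-flagged row(s) ",
              paste(odd, collapse = ", "),
              "; kept, PG effect will be censored")
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_panel_csv
#' @param panel data.frame of oil records.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(is.data.frame(panel))
  cols <- intersect(panel_columns, names(panel))
  utils::write.csv(panel[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render an analysis result as a human-readable + JSON report
#'
#' Produces a plain-text report (every number with its units) and a
#' schema-versioned JSON document for trace features, model fits, blend
#' predictions, or a list of such results. Empty input yields an explicit
#' "no results" document.
#'
#' @param x a \code{trace_features}, \code{oxkin_fit}, \code{blend_prediction},
#'   or a (possibly empty) list of them.
#' @param ... unused.
#' @return list with \code{text} (character vector of lines) and \code{json}
#'   (a JSON string).
#' @export
render_report <- function(x, ...) UseMethod("render_report")

report_json <- function(kind, payload) {
  jsonlite::toJSON(list(schema = "oxikin-report/1", kind = kind,
                        result = payload),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

#' @export
render_report.trace_features <- function(x, ...) {
  text <- c("Oxygen-uptake trace features",
            if (x$censored) "  censored: no oxidation resolved above noise"
            else c(sprintf("  oil type: %s", x$oil_type),
                   sprintf("  induction period tau: %.6g s", x$tau_s),
                   sprintf("  initial rate R_in: %.6g nmol/s", x$R_in_nmol_s),
                   sprintf("  steady rate R_st: %.6g nmol/s", x$R_st_nmol_s)),
            sprintf("  config: dead time %g s, smoothing window %d points",
                    x$diagnostics$config$dead_time_s,
                    x$diagnostics$config$smooth_window))
  payload <- list(tau_s = x$tau_s, R_in_nmol_s = x$R_in_nmol_s,
                  R_st_nmol_s = x$R_st_nmol_s, oil_type = x$oil_type,
                  censored = x$censored,
                  config = unclass(x$diagnostics$config))
  list(text = text, json = report_json("trace_features", payload))
}

#' @export
render_report.oxkin_fit <- function(x, ...) {
  units <- switch(x$model_name,
                  unsaturation = ,
                  unsaturation_acidity = "nmol/s per unit predictor",
                  pg_effect_hyperbolic = "a: s M, b: M",
                  pg_effect_reciprocal = "slope: 1/(s M), intercept: 1/s",
                  "")
  cf_lines <- sprintf("  %s = %.6g +/- %.3g", names(x$coefficients),
                      x$coefficients, x$se)
  text <- c(sprintf("Fit '%s' (n = %d, r2 = %.4f; coefficients in %s)",
                    x$model_name, x$n_obs, x$r2, units),
            cf_lines,
            if (!is.null(x$outlier_ids) && length(x$outlier_ids))
              paste0("  outliers flagged: ",
                     paste(x$outlier_ids, collapse = ", ")))
  payload <- list(model_name = x$model_name,
                  coefficients = as.list(x$coefficients),
                  se = as.list(x$se), r2 = x$r2, n_obs = x$n_obs,
                  outlier_ids = x$outlier_ids)
  list(text = text, json = report_json("fit", payload))
}

#' @export
render_report.blend_prediction <- function(x, ...) {
  text <- c("Blend stability prediction",
            sprintf("  predicted tau: %.6g s", x$tau_s),
            if (is.finite(x$R_st_nmol_s))
              sprintf("  predicted R_st: %.6g nmol/s", x$R_st_nmol_s),
            paste0("  ", x$rationale))
  payload <- list(tau_s = x$tau_s, R_st_nmol_s = x$R_st_nmol_s,
                  rationale = x$rationale,
                  components = x$components)
  list(text = text, json = report_json("blend_prediction", payload))
}

#' @export
render_report.list <- function(x, ...) {
  if (length(x) == 0L)
    return(list(text = "No results.",
                json = report_json("empty", list(message = "no results"))))
  parts <- lapply(x, render_report)
  list(text = unlist(lapply(parts, `[[`, "text")),
       json = jsonlite::toJSON(
         list(schema = "oxikin-report/1", kind = "collection",
              results = lapply(parts, function(p)
                jsonlite::fromJSON(p$json, simplifyVector = FALSE))),
         auto_unbox = TRUE, digits = NA, na = "null"))
}
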