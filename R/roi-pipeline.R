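#' Read ROI-level MD/MK time-series tables
#'
#' Reads a delimited text file with one row per (animal, diffusion time)
#' observation and required columns `region`, `group`, `animal`,
#' `delta_ms` (diffusion time in ms), `md` (mean diffusivity, um^2/ms),
#' and `mk` (mean kurtosis). The delimiter (comma or tab) is auto-detected
#' from the header unless given. Parse problems — missing columns,
#' non-numeric cells, non-positive times or MD/MK, duplicated
#' (region, group, animal, delta_ms) rows — are reported with the
#' offending line numbers.
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Optional delimiter override (`","` or `"\t"`).
#' @return A data frame of class `"roi_timeseries"`.
#' @export
read_roi_timeseries <- function(path, delim = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(delim))
    delim <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          strip.white = TRUE)
  need <- c("region", "group", "animal", "delta_ms", "md", "mk")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1

  num <- function(col, positive = TRUE) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v)
    if (any(bad))
      stop("non-numeric '", col, "' value(s) at line(s) ",
           paste(line_no[bad], collapse = ", "), call. = FALSE)
    if (positive && any(v <= 0))
      stop("'", col, "' must be positive (log-domain fits); ",
           "violated at line(s) ",
           paste(line_no[v <= 0], collapse = ", "), call. = FALSE)
    v
  }
  out <- data.frame(region = df$region, group = df$group,
                    animal = df$animal,
                    delta_ms = num("delta_ms"),
                    md = num("md"), mk = num("mk"),
                    stringsAsFactors = FALSE)
  key <- paste(out$region, out$group, out$animal, out$delta_ms, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (region, group, animal, delta_ms) row(s) at line(s) ",
         paste(line_no[dup], collapse = ", "), call. = FALSE)
  class(out) <- c("roi_timeseries", "data.frame")
  out
}

#' Write an ROI time-series table
#'
#' Inverse of [read_roi_timeseries()]; full-precision values, comma or
#' tab delimited.
#'
#' @param data An `"roi_timeseries"` (or compatible) data frame.
#' @param path Output path.
#' @param delim Delimiter, `","` (default) or `"\t"`.
#' @export
write_roi_timeseries <- function(data, path, delim = ",") {
  cols <- c("region", "group", "animal", "delta_ms", "md", "mk")
  stopifnot(all(cols %in% names(data)))
  utils::write.table(as.data.frame(data)[cols], path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exchange-rate bound analysis of ROI time series
#'
#' For each group of pooled observations, fits the diffusion elasticity
#' `xi` (log-log OLS of MD vs time), the plain bound `R_KM^*` (-3 times
#' the semi-log OLS slope of MK vs time), the enhancement factor
#' `Ef = V(R_KM^* t^*)`, and the enhanced bound `R_hat = Ef R_KM^*`.
#' By default one OLS line is fit through all pooled animal-by-time
#' points of a group; `per_animal = TRUE` instead emits one report row
#' per animal.
#'
#' Rates are reported in 1/s (times are read in ms; the conversion
#' happens only here, at the reporting boundary). Rows where
#' `R_KM^* t^* >= 3` — outside the physical range of any Karger model —
#' are flagged invalid and their `Ef`/`rkm_hat` withheld as `NA`.
#'
#' @param data An `"roi_timeseries"` data frame.
#' @param group_by Character vector of grouping columns, default
#'   `c("region", "group")`.
#' @param t_star Either `"mean"` (arithmetic mean of the distinct design
#'   times pooled in the group, in ms) or a numeric time in ms.
#' @param per_animal If `TRUE`, fit each animal separately (the `animal`
#'   column is appended to `group_by`).
#' @return A data frame of class `"exchange_report"` with columns
#'   `region`, `group` (and `animal` when per-animal), `n_points`, `xi`,
#'   `xi_se`, `rkm_star`, `rkm_star_se` (1/s), `t_star_ms`, `x`, `Ef`,
#'   `rkm_hat`, `rkm_hat_se` (1/s), `valid`.
#' @export
analyze_group <- function(data, group_by = c("region", "group"),
                          t_star = "mean", per_animal = FALSE) {
  stopifnot(is.data.frame(data))
  if (per_animal) group_by <- unique(c(group_by, "animal"))
  miss <- setdiff(group_by, names(data))
  if (length(miss))
    stop("grouping column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  keys <- unique(as.data.frame(data)[group_by])
  keys <- keys[do.call(order, keys), , drop = FALSE]

  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- rep(TRUE, nrow(data))
    for (g in group_by) sel <- sel & data[[g]] == keys[[g]][i]
    sub <- data[sel, , drop = FALSE]
    if (length(unique(sub$delta_ms)) < 2L)
      stop("group ", paste(unlist(keys[i, ]), collapse = "/"),
           " has fewer than 2 distinct diffusion times", call. = FALSE)
    ts_ms <- if (identical(t_star, "mean")) mean(unique(sub$delta_ms))
             else as.numeric(t_star)
    el <- diffusion_elasticity(sub$delta_ms, sub$md)
    st <- estimate_rkm_star(sub$delta_ms, sub$mk)
    x <- st$rkm_star * ts_ms  # both in ms units -> dimensionless
    if (x < 3) {
      eb <- enhanced_bound(st$rkm_star, ts_ms, st$slope_se)
      ef <- eb$enhancement
      rh <- eb$rkm_hat * 1000
      rh_se <- eb$rkm_hat_se * 1000
      ok <- TRUE
    } else {
      ef <- NA_real_; rh <- NA_real_; rh_se <- NA_real_; ok <- FALSE
    }
    out <- as.data.frame(keys[i, , drop = FALSE])
    rownames(out) <- NULL
    cbind(out, data.frame(
      n_points = nrow(sub), xi = el$xi, xi_se = el$slope_se,
      rkm_star = max(st$rkm_star, 0) * 1000,
      rkm_star_se = 3 * st$slope_se * 1000,
      t_star_ms = ts_ms, x = max(x, 0), Ef = ef, rkm_hat = rh,
      rkm_hat_se = rh_se, valid = ok))
  })
  rep <- do.call(rbind, rows)
  class(rep) <- c("exchange_report", "data.frame")
  rep
}

#' @export
print.exchange_report <- function(x, ...) {
  cat("Exchange-rate bound report (rates in 1/s)\n")
  NextMethod()
}

#' Soma volume fraction from cell density and diameter
#'
#' `fraction = density * (pi/6) * diameter^3`, with density per mm^3 and
#' diameter in um. Used to judge how much tissue volume sits in cell
#' bodies too large to be fully explored over typical diffusion times.
#'
#' @param density Cell density, count per mm^3.
#' @param diameter Soma diameter in um.
#' @return Dimensionless volume fraction in \[0, 1\].
#' @export
soma_volume_fraction <- function(density, diameter) {
  if (any(density < 0)) stop("density must be non-negative", call. = FALSE)
  if (any(diameter <= 0)) stop("diameter must be positive", call. = FALSE)
  frac <- density * (pi / 6) * (diameter * 1e-3)^3  # um -> mm
  if (any(frac > 1))
    stop("computed volume fraction exceeds 1: unphysical inputs",
         call. = FALSE)
  frac
}

#' Write an exchange report to a delimited file
#'
#' Serializes an [analyze_group()] report with table-style rounding
#' (3 decimals for `xi`, 2 for `Ef` and `x`, 1 for rates and their SEs),
#' ordered by region then group, plus a full-precision JSON sidecar
#' (`<path>.json`) carrying unrounded values and standard errors.
#'
#' @param reports An `"exchange_report"` data frame (may be empty).
#' @param path Output path.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  delim <- if (format == "csv") "," else "\t"
  df <- as.data.frame(reports)
  cols <- c("region", "group",
            intersect("animal", names(df)),
            "n_points", "xi", "rkm_star", "t_star_ms", "x", "Ef",
            "rkm_hat", "valid")
  if (nrow(df)) {
    df <- df[do.call(order, df[intersect(c("region", "group", "animal"),
                                         names(df))]), , drop = FALSE]
    out <- df[cols]
    out$xi <- sprintf("%.3f", df$xi)
    out$x <- sprintf("%.2f", df$x)
    out$Ef <- ifelse(is.na(df$Ef), "NA", sprintf("%.2f", df$Ef))
    out$rkm_star <- sprintf("%.1f", df$rkm_star)
    out$rkm_hat <- ifelse(is.na(df$rkm_hat), "NA",
                          sprintf("%.1f", df$rkm_hat))
    out$t_star_ms <- sprintf("%.1f", df$t_star_ms)
  } else {
    out <- df[cols]
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(df, paste0(path, ".json"), digits = NA,
                       na = "null", dataframe = "rows", pretty = TRUE)
  invisible(path)
}
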