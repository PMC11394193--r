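#' Fit amplification efficiency from a dilution series
#'
#' Ordinary least squares of Cq on log10(relative input), replicates
#' entering as individual points. Efficiency follows the standard-curve
#' relation `E = 100 * (10^(-1/slope) - 1)` percent; a perfect doubling
#' assay has slope -3.32193 and E = 100%. The fit is flagged invalid when
#' the slope is non-negative, and flagged (but reported) when E falls
#' outside the acceptance band.
#'
#' @param d a [simulate_dilution_series()] result, or a data.frame with
#'   numeric columns `input` (relative input) and `cq`.
#' @param band efficiency acceptance band in percent, default `c(90, 110)`;
#'   flag-only, points are never dropped.
#' @return object of class `efficiency_fit`: list with `slope`,
#'   `intercept`, `efficiency_pct`, `r_squared`, `valid`, `in_band`,
#'   `band`, `n_points`.
#' @export
fit_efficiency <- function(d, band = c(90, 110)) {
  df <- if (inherits(d, "dilution_series")) d$data else as.data.frame(d)
  if (!all(c("input", "cq") %in% names(df)))
    abort("dilution data needs columns `input` and `cq`")
  if (length(unique(df$input)) < 3)
    abort("need >= 3 distinct dilution levels")
  fit <- stats::lm(cq ~ log10(input), data = df)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless series fit exactly
  valid <- is.finite(slope) && slope < 0
  eff <- if (valid) 100 * (10^(-1 / slope) - 1) else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 efficiency_pct = eff, r_squared = r2, valid = valid,
                 in_band = valid && eff >= band[1] && eff <= band[2],
                 band = band, n_points = nrow(df)),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("<efficiency_fit> slope %.4f, E = %.1f%%, R^2 = %.4f%s\n",
              x$slope, x$efficiency_pct, x$r_squared,
              if (!x$valid) " [INVALID: non-negative slope]"
              else if (!x$in_band) sprintf(" [outside %g-%g%% band]",
                                           x$band[1], x$band[2])
              else ""))
  invisible(x)
}

#' Transform Cq values to relative quantities
#'
#' Per gene, `dCq = Cq - min(Cq over samples)` and `Q = 2^(-dCq)`, so every
#' Q lies in (0, 1] and each gene's most abundant sample has Q = 1
#' exactly. This is the input scale of the geNorm and NormFinder
#' analyses. Requires technical replicates to be collapsed first.
#'
#' @param x a collapsed [cq_table()].
#' @param log_base exponent base, default 2 (each PCR cycle doubles).
#' @return object of class `rel_quant`: list with `values` (Q matrix),
#'   `dcq` (the Cq - min matrix) and `meta`.
#' @export
relative_quantity <- function(x, log_base = 2) {
  stopifnot(inherits(x, "cq_table"))
  .require_collapsed(x, "relative_quantity()")
  if (anyNA(x$values))
    abort("missing Cq entries; resolve them via the cq_table na_action policy")
  dcq <- x$values - apply(x$values, 1, min)
  q <- log_base^(-dcq)
  structure(list(values = q, dcq = dcq, meta = x$meta, log_base = log_base),
            class = "rel_quant")
}

# accept a rel_quant or a bare positive Q matrix
.as_q <- function(q) {
  if (inherits(q, "rel_quant")) return(q$values)
  if (!is.matrix(q) || !is.numeric(q)) abort("expected a rel_quant or matrix")
  if (any(!is.finite(q)) || any(q <= 0)) abort("all quantities must be > 0")
  q
}

# group labels aligned to q's samples
.q_groups <- function(q, groups = NULL) {
  if (!is.null(groups)) return(as.character(groups))
  if (inherits(q, "rel_quant")) return(q$meta$group)
  abort("`groups` must be supplied when q is a bare matrix")
}

#' Delta-delta-Ct fold changes of a target gene
#'
#' Classic relative quantification: per sample,
#' `dCt = Cq(target) - mean(Cq over reference genes)`; `ddCt = dCt -
#' mean(dCt over calibrator-group samples)`; `fold = 2^(-ddCt)`. Averaging
#' reference Cq arithmetically per sample is equivalent to normalizing by
#' the geometric mean of the reference quantities on the linear scale, the
#' standard multi-reference combination. By construction the calibrator
#' group's mean ddCt is 0, so its geometric-mean fold change is 1.
#'
#' @param x a collapsed [cq_table()] containing target and reference rows.
#' @param target target gene symbol.
#' @param refs character vector (>= 1) of reference gene symbols.
#' @param calibrator group label used as the baseline.
#' @param log_base exponent base, default 2.
#' @return object of class `fold_change_table`: list with `data`
#'   (data.frame `sample_id`, `group`, `delta_ct`, `ddct`, `fold`),
#'   `target`, `refs`, `calibrator`.
#' @export
ddct_fold_change <- function(x, target, refs, calibrator, log_base = 2) {
  stopifnot(inherits(x, "cq_table"))
  .require_collapsed(x, "ddct_fold_change()")
  if (length(refs) < 1) abort("empty reference set")
  missing <- setdiff(c(target, refs), rownames(x$values))
  if (length(missing))
    abort("gene(s) not in table: ", paste(missing, collapse = ", "))
  if (target %in% refs)
    warning("target gene is also a reference; fold changes will be ",
            "attenuated", call. = FALSE)
  cal <- x$meta$group == calibrator
  if (!any(cal)) abort("calibrator group '", calibrator, "' has no samples")
  ref_cq <- colMeans(x$values[refs, , drop = FALSE])
  dct <- x$values[target, ] - ref_cq
  ddct <- dct - mean(dct[cal])
  structure(list(data = data.frame(sample_id = x$meta$sample_id,
                                   group = x$meta$group,
                                   delta_ct = unname(dct),
                                   ddct = unname(ddct),
                                   fold = unname(log_base^(-ddct)),
                                   stringsAsFactors = FALSE),
                 target = target, refs = refs, calibrator = calibrator),
            class = "fold_change_table")
}
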