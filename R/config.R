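#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default.
#' Defaults: log base 2 for all ratio work (the Q = 2^-dCq convention), Cq
#' plausibility ceiling 45 cycles, technical-replicate SD flag 0.5 cycles,
#' geNorm pairwise-variation threshold 0.15, candidate screening at
#' mean FPKM > 100 and CV < 10% keeping the top 8 by ascending CV,
#' BestKeeper dispersion = sample SD.
#'
#' @param log_base base of all logarithms/exponentials (> 1).
#' @param cq_max Cq plausibility ceiling, cycles.
#' @param sd_flag technical-replicate SD flag threshold, cycles.
#' @param v_threshold geNorm V(n/n+1) cutoff (strict `<`).
#' @param fpkm_min,cv_max,top_k screening thresholds (strict inequalities).
#' @param fpkm_agg how "FPKM > fpkm_min" aggregates over samples.
#' @param bestkeeper_dispersion `"sd"` (sample SD) or `"mad"` (mean absolute
#'   deviation from the mean, the original BestKeeper spreadsheet's measure).
#' @param seed integer random seed recorded in run logs.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(log_base = 2, cq_max = 45, sd_flag = 0.5,
                            v_threshold = 0.15, fpkm_min = 100, cv_max = 10,
                            top_k = 8, fpkm_agg = c("mean", "min", "median"),
                            bestkeeper_dispersion = c("sd", "mad"),
                            seed = 1L) {
  fpkm_agg <- match.arg(fpkm_agg)
  bestkeeper_dispersion <- match.arg(bestkeeper_dispersion)
  if (log_base <= 1) abort("`log_base` must exceed 1")
  for (v in c(cq_max, sd_flag, v_threshold, fpkm_min, cv_max, top_k))
    if (!is.numeric(v) || v <= 0) abort("thresholds must be strictly positive")
  structure(list(log_base = log_base, cq_max = cq_max, sd_flag = sd_flag,
                 v_threshold = v_threshold, fpkm_min = fpkm_min,
                 cv_max = cv_max, top_k = as.integer(top_k),
                 fpkm_agg = fpkm_agg,
                 bestkeeper_dispersion = bestkeeper_dispersion,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path path to a YAML file whose keys mirror [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abort("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return invisibly, `config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}
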