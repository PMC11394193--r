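#' Run the full reference-gene stability pipeline
#'
#' Collapses technical replicates, transforms Cq to relative quantities,
#' runs the requested stability algorithms, aggregates them into the
#' comprehensive consensus ranking, and (optionally) screens an FPKM
#' matrix and validates target genes by delta-delta-Ct. With an output
#' directory, writes one CSV per stage plus a plain-text run log; reruns
#' with the same inputs and config produce byte-identical files.
#'
#' @param cq a [cq_table()] (wells-level or already collapsed).
#' @param config a [pipeline_config()].
#' @param methods subset of `c("genorm", "normfinder", "bestkeeper",
#'   "delta_ct")` (>= 2 of them) to aggregate.
#' @param fpkm optional [expression_matrix()] to screen.
#' @param targets optional named list for validation: each element a list
#'   with `target`, `refs`, `calibrator` passed to [ddct_fold_change()].
#' @param out_dir optional output directory (created if missing).
#' @return list with `collapsed`, `flags`, `q`, per-method results,
#'   `consensus`, and optionally `screening` and `validation`.
#' @export
run_pipeline <- function(cq, config = pipeline_config(),
                         methods = c("genorm", "normfinder", "bestkeeper",
                                     "delta_ct"),
                         fpkm = NULL, targets = NULL, out_dir = NULL) {
  stopifnot(inherits(cq, "cq_table"), inherits(config, "pipeline_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) < 2) abort("need >= 2 stability methods")
  log_lines <- c("refstab run log",
                 paste0("seed: ", config$seed),
                 paste0("methods: ", paste(methods, collapse = ", ")),
                 paste0("config: ", paste(names(unclass(config)),
                                          unlist(lapply(unclass(config),
                                                        as.character)),
                                          sep = "=", collapse = "; ")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("stage '", name, "': ", conditionMessage(e)))
  }
  col <- stage("collapse", collapse_technical_replicates(cq, config$sd_flag))
  log_lines <- c(log_lines,
                 paste0("collapsed to ", ncol(col$table$values),
                        " biological samples; ", nrow(col$flags),
                        " technical-replicate flag(s)"))
  q <- stage("relative_quantity",
             relative_quantity(col$table, config$log_base))
  res <- list()
  if ("genorm" %in% methods)
    res$genorm <- stage("genorm",
                        genorm(q, threshold = config$v_threshold,
                               log_base = config$log_base))
  if ("normfinder" %in% methods) {
    res$normfinder <- stage("normfinder", withCallingHandlers(
      normfinder_stability(q, log_base = config$log_base),
      warning = function(w) {
        log_lines <<- c(log_lines, paste0("normfinder: ",
                                          conditionMessage(w)))
        invokeRestart("muffleWarning")
      }))
  }
  if ("bestkeeper" %in% methods)
    res$bestkeeper <- stage("bestkeeper",
                            bestkeeper(col$table,
                                       config$bestkeeper_dispersion))
  if ("delta_ct" %in% methods)
    res$delta_ct <- stage("delta_ct", delta_ct_method(col$table))
  consensus <- stage("consensus", comprehensive_ranking(unname(res)))
  out <- list(collapsed = col$table, flags = col$flags, q = q,
              results = res, consensus = consensus)
  if (!is.null(fpkm))
    out$screening <- stage("screening",
                           screen_candidates(fpkm, config$fpkm_min,
                                             config$cv_max, config$top_k,
                                             config$fpkm_agg))
  if (!is.null(targets)) {
    out$validation <- lapply(targets, function(tg)
      stage("validation",
            ddct_fold_change(col$table, tg$target, tg$refs, tg$calibrator,
                             config$log_base)))
    out$group_comparison <- stage("validation",
                                  compare_normalizations(out$validation))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, file)
      utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
    if (!is.null(res$genorm)) {
      wr(data.frame(gene = res$genorm$gene, m = res$genorm$m,
                    rank = res$genorm$rank), "genorm.csv")
      wr(res$genorm$v$v, "genorm_v.csv")
    }
    if (!is.null(res$normfinder))
      wr(data.frame(gene = res$normfinder$gene,
                    stability = res$normfinder$statistic,
                    rank = res$normfinder$rank,
                    gamma2 = unname(res$normfinder$gamma2)),
         "normfinder.csv")
    if (!is.null(res$bestkeeper))
      wr(data.frame(gene = res$bestkeeper$gene,
                    mean_cq = res$bestkeeper$mean_cq,
                    sd = res$bestkeeper$sd, cv_pct = res$bestkeeper$cv_pct,
                    r = res$bestkeeper$r, rank = res$bestkeeper$rank),
         "bestkeeper.csv")
    if (!is.null(res$delta_ct))
      wr(data.frame(gene = res$delta_ct$gene,
                    mean_pairwise_sd = res$delta_ct$statistic,
                    rank = res$delta_ct$rank), "deltact.csv")
    wr(as.data.frame(consensus), "consensus.csv")
    if (!is.null(out$screening)) wr(out$screening$candidates,
                                    "candidates.csv")
    if (!is.null(out$validation))
      for (nm in names(out$validation))
        wr(out$validation[[nm]]$data,
           paste0("foldchange_", gsub("[^A-Za-z0-9_]+", "_", nm), ".csv"))
    writeLines(log_lines, file.path(out_dir, "report.log"))
  }
  out
}
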