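#' Construct a validated Cq table
#'
#' The central input container of the pipeline: a genes x samples matrix of
#' quantification-cycle (Cq) values plus per-sample metadata. Columns of
#' `values` and rows of `meta` correspond one-to-one, in order.
#'
#' @param values numeric matrix, rows = genes (rownames = unique gene
#'   symbols), columns = samples (colnames = sample ids).
#' @param meta data.frame with columns `sample_id`, `group`, `bio_rep`,
#'   `tech_rep`; one row per sample column, `sample_id` unique.
#' @param na_action `"error"` (default) rejects any missing Cq; `"drop"`
#'   removes every sample column containing a missing value (complete-case
#'   across genes). Values are never imputed.
#' @param cq_max upper plausibility bound for Cq (cycles); values must lie
#'   in `(0, cq_max]`.
#' @return object of class `cq_table`: list with `values`, `meta` and the
#'   `na_action` used.
#' @export
cq_table <- function(values, meta, na_action = c("error", "drop"), cq_max = 45) {
  na_action <- match.arg(na_action)
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix (genes x samples)")
  genes <- rownames(values)
  if (is.null(genes) || anyNA(genes))
    abort("`values` must have gene symbols as rownames")
  if (anyDuplicated(genes))
    abort("duplicate gene symbol(s): ",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "bio_rep", "tech_rep")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    abort("metadata is missing column(s): ", paste(miss, collapse = ", "))
  meta <- meta[, req]
  meta$sample_id <- as.character(meta$sample_id)
  meta$group <- as.character(meta$group)
  meta$bio_rep <- as.integer(meta$bio_rep)
  meta$tech_rep <- as.integer(meta$tech_rep)
  if (anyDuplicated(meta$sample_id))
    abort("duplicate sample_id(s): ",
          paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  if (any(meta$bio_rep < 1L) || any(meta$tech_rep < 1L) ||
      anyNA(meta$bio_rep) || anyNA(meta$tech_rep))
    abort("bio_rep and tech_rep must be positive integers")
  if (ncol(values) != nrow(meta))
    abort("matrix has ", ncol(values), " sample columns but metadata has ",
          nrow(meta), " rows")
  if (is.null(colnames(values))) colnames(values) <- meta$sample_id
  if (!identical(colnames(values), meta$sample_id)) {
    extra <- setdiff(colnames(values), meta$sample_id)
    if (length(extra))
      abort("sample(s) in matrix absent from metadata: ",
            paste(extra, collapse = ", "))
    # same set, different order: align metadata to the matrix
    meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (anyNA(values)) {
    if (na_action == "error") {
      bad <- which(is.na(values), arr.ind = TRUE)[1, ]
      abort("missing Cq at gene '", genes[bad[1]], "', sample '",
            colnames(values)[bad[2]], "'; set na_action = \"drop\" for ",
            "complete-case handling (values are never imputed)")
    }
    keep <- !apply(values, 2, anyNA)
    if (sum(keep) < 2) abort("fewer than 2 complete samples after dropping")
    values <- values[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (ncol(values) < 2) abort("need at least 2 samples")
  fin <- values[is.finite(values)]
  if (length(fin) != length(values))
    abort("non-finite Cq value(s) present")
  if (any(values <= 0) || any(values > cq_max))
    abort("Cq values must lie in (0, ", cq_max, "]")
  structure(list(values = values, meta = meta, na_action = na_action),
            class = "cq_table")
}

#' @export
print.cq_table <- function(x, ...) {
  cat("<cq_table> ", nrow(x$values), " genes x ", ncol(x$values), " samples; ",
      length(unique(x$meta$group)), " group(s): ",
      paste(unique(x$meta$group), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# infer field separator from a file extension
.sep_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a wide Cq table and its sample metadata
#'
#' The Cq file is a wide CSV/TSV with a `gene` column (or the first column)
#' holding gene symbols and one column per sample. The metadata file has
#' columns `sample_id,group,bio_rep,tech_rep` and must cover every sample
#' column. The separator is inferred from the extension (`.tsv`/`.txt` =
#' tab, otherwise comma); decimal point only.
#'
#' @param path path to the wide Cq table.
#' @param meta_path path to the sample metadata table.
#' @param na_action forwarded to [cq_table()].
#' @return a [cq_table()], gene and sample order preserved from the file.
#' @export
read_cq_table <- function(path, meta_path, na_action = "error") {
  for (p in c(path, meta_path))
    if (!file.exists(p)) abort("file not found: ", p)
  raw <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  gene_col <- if ("gene" %in% names(raw)) "gene" else names(raw)[1]
  genes <- raw[[gene_col]]
  if (anyDuplicated(genes))
    abort("duplicate gene symbol(s) in ", path, ": ",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  num <- raw[, setdiff(names(raw), gene_col), drop = FALSE]
  vals <- suppressWarnings(vapply(num, as.numeric, numeric(nrow(num))))
  if (nrow(num) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(num)))
  bad <- which(is.na(vals) & !(num == "NA" | num == ""), arr.ind = TRUE)
  if (nrow(bad))
    abort("non-numeric Cq at gene '", genes[bad[1, 1]], "', sample '",
          colnames(vals)[bad[1, 2]], "' (value '",
          num[bad[1, 1], bad[1, 2]], "')")
  vals[num == ""] <- NA_real_
  rownames(vals) <- genes
  meta <- utils::read.table(meta_path, sep = .sep_for(meta_path), header = TRUE,
                            stringsAsFactors = FALSE)
  missing_meta <- setdiff(colnames(vals), as.character(meta$sample_id))
  if (length(missing_meta))
    abort("sample(s) in matrix absent from metadata: ",
          paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(vals), as.character(meta$sample_id)), , drop = FALSE]
  cq_table(vals, meta, na_action = na_action)
}

#' Write a Cq table and its metadata to disk
#'
#' Values are serialized with 17 significant digits so that a read/write
#' round trip reproduces the table exactly.
#'
#' @param x a [cq_table()].
#' @param path,meta_path output paths; separator inferred from extension.
#' @return invisibly, `x`.
#' @export
write_cq_table <- function(x, path, meta_path) {
  stopifnot(inherits(x, "cq_table"))
  chr <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values),
                dimnames = dimnames(x$values))
  chr[is.na(x$values)] <- ""
  df <- data.frame(gene = rownames(chr), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE)
  utils::write.table(x$meta, meta_path, sep = .sep_for(meta_path),
                     row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Average technical replicates on the Cq scale
#'
#' Collapses each (gene, group, biological replicate) cell to the
#' arithmetic mean Cq of its technical replicates, the form all stability
#' algorithms expect (one observation per biological sample). Wells whose
#' technical-replicate standard deviation exceeds `sd_flag` are reported
#' for QC but still averaged; dropping is left to the caller.
#'
#' Collapsing an already-collapsed table is a no-op.
#'
#' @param x a [cq_table()].
#' @param sd_flag flag threshold for the technical-replicate SD, in cycles.
#'   Default 0.5, a common wet-lab QC convention.
#' @return list with `table` (collapsed [cq_table()], sample ids
#'   `<group>_<bio_rep>`) and `flags` (data.frame `gene`, `sample_id`, `sd`
#'   of every flagged cell).
#' @export
collapse_technical_replicates <- function(x, sd_flag = 0.5) {
  stopifnot(inherits(x, "cq_table"))
  if (sd_flag <= 0) abort("`sd_flag` must be positive")
  key <- paste(x$meta$group, x$meta$bio_rep, sep = "_")
  keys <- unique(key)
  k <- nrow(x$values)
  out <- matrix(NA_real_, k, length(keys),
                dimnames = list(rownames(x$values), keys))
  flags <- list()
  for (j in seq_along(keys)) {
    cols <- which(key == keys[j])
    sub <- x$values[, cols, drop = FALSE]
    usable <- rowSums(!is.na(sub))
    if (any(usable == 0))
      abort("no usable wells for gene '",
            rownames(sub)[which(usable == 0)[1]], "' in sample '", keys[j], "'")
    out[, j] <- rowMeans(sub, na.rm = TRUE)
    if (length(cols) >= 2) {
      sds <- apply(sub, 1, stats::sd, na.rm = TRUE)
      hit <- which(!is.na(sds) & sds > sd_flag)
      if (length(hit))
        flags[[length(flags) + 1]] <- data.frame(
          gene = rownames(sub)[hit], sample_id = keys[j], sd = sds[hit],
          stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  first <- match(keys, key)
  meta <- data.frame(sample_id = keys,
                     group = x$meta$group[first],
                     bio_rep = x$meta$bio_rep[first],
                     tech_rep = 1L,
                     stringsAsFactors = FALSE)
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(gene = character(), sample_id = character(), sd = numeric(),
               stringsAsFactors = FALSE)
  list(table = cq_table(out, meta, na_action = x$na_action), flags = flags)
}

# TRUE when every (group, bio_rep) pair occurs exactly once
.is_collapsed <- function(x) {
  !anyDuplicated(paste(x$meta$group, x$meta$bio_rep, sep = "\r"))
}

.require_collapsed <- function(x, what) {
  if (!.is_collapsed(x))
    abort(what, " expects technical replicates to be collapsed first; ",
          "see collapse_technical_replicates()")
}

#' Construct a validated FPKM expression matrix
#'
#' @param values numeric matrix of FPKM (genes x samples), non-negative,
#'   rownames = unique gene symbols, at least 2 samples.
#' @return object of class `expression_matrix` (a matrix).
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    abort("rownames must be unique gene symbols")
  if (ncol(values) < 2) abort("need at least 2 samples")
  if (anyNA(values) || any(values < 0))
    abort("FPKM values must be non-negative and non-missing")
  structure(values, class = c("expression_matrix", class(values)))
}
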