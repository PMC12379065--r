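#' Read a gene-by-cell expression matrix
#'
#' Dense TSV/CSV (first column gene IDs, header row cell IDs) or
#' MatrixMarket coordinate format with `genes.tsv` / `barcodes.tsv`
#' sidecar files next to the `.mtx` file.  Validation rejects
#' duplicate IDs and negative or non-finite values.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @return Gene-by-cell numeric matrix (stages are attached separately
#'   with [read_metadata()] and [ccne_dataset()]).
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", "tsv")
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dirn <- dirname(path)
    gf <- file.path(dirn, "genes.tsv"); bf <- file.path(dirn, "barcodes.tsv")
    if (!file.exists(gf) || !file.exists(bf))
      stop("MTX input needs 'genes.tsv' and 'barcodes.tsv' next to ", path)
    genes <- readLines(gf); cells <- readLines(bf)
    genes <- vapply(strsplit(genes, "\t"), `[`, "", 1L)
    cells <- vapply(strsplit(cells, "\t"), `[`, "", 1L)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop(sprintf("MTX is %d x %d but sidecars list %d genes and %d cells",
                   nrow(m), ncol(m), length(genes), length(cells)))
    dimnames(m) <- list(genes, cells)
  } else {
    df <- read.delim(path, sep = if (format == "csv") "," else "\t",
                     header = TRUE, row.names = NULL,
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expression table needs gene IDs plus >= 1 cell")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))[1]
      stop("non-numeric expression value near row ",
           (bad - 1) %% nrow(m) + 2, " column ", (bad - 1) %/% nrow(m) + 2)
    }
    rownames(m) <- as.character(df[[1]])
  }
  if (length(m) == 0L) stop("empty expression matrix: ", path)
  bad <- which(!is.finite(m) | m < 0)
  if (length(bad))
    stop(sprintf("invalid expression value at row %d (%s), column %d (%s)",
                 row(m)[bad[1]], rownames(m)[row(m)[bad[1]]],
                 col(m)[bad[1]], colnames(m)[col(m)[bad[1]]]))
  if (anyDuplicated(rownames(m))) stop("duplicate gene IDs in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate cell IDs in ", path)
  m
}

#' Read cell-stage metadata
#'
#' TSV with columns `cell_id`, `stage`, `stage_order` (integer rank of
#' the stage).  Row order does not matter.
#'
#' @param path File path.
#' @param cell_ids Optional cell IDs the metadata must cover (e.g.
#'   `colnames` of the expression matrix); missing cells are an error,
#'   extra metadata rows a warning.
#' @return List with `stages` (named by cell) and `stage_order`.
#' @export
read_metadata <- function(path, cell_ids = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "stage", "stage_order")
  if (!all(need %in% names(df)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id in metadata: ",
         df$cell_id[duplicated(df$cell_id)][1])
  rk <- unique(df[, c("stage", "stage_order")])
  if (anyDuplicated(rk$stage))
    stop("inconsistent stage_order for stage(s): ",
         paste(unique(rk$stage[duplicated(rk$stage)]), collapse = ", "))
  if (!is.null(cell_ids)) {
    miss <- setdiff(cell_ids, df$cell_id)
    if (length(miss))
      stop("cells missing from metadata: ",
           paste(head(miss, 5), collapse = ", "),
           if (length(miss) > 5) ", ...")
    extra <- setdiff(df$cell_id, cell_ids)
    if (length(extra)) {
      warning(length(extra), " metadata row(s) for unknown cells ignored")
      df <- df[df$cell_id %in% cell_ids, ]
    }
  }
  stages <- setNames(as.character(df$stage), df$cell_id)
  if (!is.null(cell_ids)) stages <- stages[cell_ids]
  list(stages = stages,
       stage_order = rk$stage[order(rk$stage_order)])
}

#' Read a background network edge list
#'
#' Two-column TSV of gene IDs; extra columns are ignored and `#`
#' comment lines allowed.  Duplicates (in either orientation) and
#' self-loops are dropped.
#'
#' @param path File path.
#' @return A [ccne_network].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty network file: ", path)
    return(ccne_network(matrix(character(0), 0, 2)))
  }
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L))
    stop("network lines need at least 2 tab-separated columns (line ",
         which(lengths(parts) < 2L)[1], ")")
  ccne_network(cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L)))
}

#' Write the local entropy matrix
#'
#' The gene-by-cell entropy matrix is the "CCNE matrix" used for
#' downstream clustering and embedding; written as dense TSV (genes in
#' rows) and optionally MatrixMarket with ID sidecars.
#'
#' @param lh Matrix from [local_entropy_matrix()] (or a `ccne_fit`).
#' @param dir Output directory (created if needed).
#' @param mtx Also write `ccne_matrix.mtx` + sidecars (default FALSE).
#' @return Invisibly, the paths written.
#' @export
write_entropy_matrix <- function(lh, dir, mtx = FALSE) {
  if (inherits(lh, "ccne_fit")) lh <- lh$lh
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "ccne_matrix.tsv")
  df <- data.frame(gene = rownames(lh), lh, check.names = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- tsv
  if (mtx) {
    mm <- file.path(dir, "ccne_matrix.mtx")
    Matrix::writeMM(Matrix::Matrix(unname(lh), sparse = TRUE), mm)
    writeLines(rownames(lh), file.path(dir, "genes.tsv"))
    writeLines(colnames(lh), file.path(dir, "barcodes.tsv"))
    paths <- c(paths, mm)
  }
  invisible(paths)
}

#' Run configuration
#'
#' Collects every tunable of the pipeline, validates it, and stamps a
#' content hash used to mark outputs.  Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults (see [neighbor_plan()],
#'   [ccne()]).
#' @return List of class `ccne_config` with a `hash` attribute.
#' @export
ccne_config <- function(...) {
  defaults <- list(k = NULL, k_fraction = NULL, tie_policy = "index_order",
                   exclude_self = TRUE, multi_scale = FALSE,
                   aggregation = "mean", scope = "stage", jitter_seed = 1L,
                   top_fraction = 0.05, signaling_fraction = 0.05,
                   alpha = 0.05, reference = "previous",
                   test_side = "reference_cells", correction = "sidak",
                   calibrate_reference = TRUE, dark_test = "wilcoxon", log1p = FALSE, seed = 1L)
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.list(ov[[1]])) ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, ov, keep.null = TRUE)
  structure(cfg, class = "ccne_config", hash = config_hash(cfg))
}

# stable content hash of a config (md5 of canonical JSON)
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              null = "null", digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Read/write a run configuration as JSON
#'
#' @param cfg A [ccne_config()].
#' @param path JSON file path.
#' @return `write_config()`: the path, invisibly; `read_config()`: the
#'   configuration (hash recomputed and checked against the stored one).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ccne_config"))
  out <- c(unclass(cfg), list(.hash = attr(cfg, "hash")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stored <- raw$.hash
  raw$.hash <- NULL
  if (!is.null(raw$seed)) raw$seed <- as.integer(raw$seed)
  if (!is.null(raw$jitter_seed)) raw$jitter_seed <- as.integer(raw$jitter_seed)
  if (!is.null(raw$k)) raw$k <- as.integer(raw$k)
  cfg <- do.call(ccne_config, raw)
  if (!is.null(stored) && !identical(stored, attr(cfg, "hash")))
    stop("config hash mismatch: file was edited or written by a different version")
  cfg
}

#' Run the full pipeline from files on disk
#'
#' Reads expression, metadata and background network, fits the model,
#' and writes the CCNE matrix, per-cell scores, detection report and
#' (when a stage is detected) signaling- and dark-gene tables, all
#' stamped with the configuration hash.
#'
#' @param expr_path,meta_path,network_path Input files (see
#'   [read_expression()], [read_metadata()], [read_network()]).
#' @param out_dir Output directory.
#' @param config A [ccne_config()].
#' @return The [ccne] fit, invisibly.
#' @export
run_pipeline <- function(expr_path, meta_path, network_path, out_dir,
                         config = ccne_config()) {
  stopifnot(inherits(config, "ccne_config"))
  hash <- attr(config, "hash")
  t0 <- Sys.time()
  m <- read_expression(expr_path)
  meta <- read_metadata(meta_path, colnames(m))
  net <- read_network(network_path)
  if (isTRUE(config$log1p)) m <- log1p(m)
  ds <- ccne_dataset(m, meta$stages, meta$stage_order)
  set.seed(config$seed)
  plan <- neighbor_plan(k = config$k, k_fraction = config$k_fraction,
                        tie_policy = config$tie_policy,
                        exclude_self = config$exclude_self,
                        multi_scale = config$multi_scale,
                        aggregation = config$aggregation,
                        scope = config$scope,
                        jitter_seed = config$jitter_seed)
  fit <- ccne(ds, net, top_fraction = config$top_fraction,
              signaling_fraction = config$signaling_fraction,
              alpha = config$alpha, plan = plan,
              reference = config$reference, test_side = config$test_side,
              correction = config$correction,
              calibrate_reference = config$calibrate_reference,
              dark_test = config$dark_test)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_entropy_matrix(fit$lh, out_dir)
  write.table(data.frame(cell_id = names(fit$scores$H),
                         stage = as.character(fit$scores$stages),
                         H = fit$scores$H),
              file.path(out_dir, "scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rep_out <- list(config_hash = hash,
                  version = as.character(packageVersion("ccne")),
                  config = unclass(config),
                  H_t = as.list(fit$scores$H_t),
                  candidates = fit$report$table,
                  detected = fit$report$detected,
                  alpha = fit$report$alpha,
                  alpha_per_stage = fit$report$alpha_per_stage,
                  excluded_genes = attr(fit$lh, "excluded_genes"),
                  elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE, dataframe = "rows")
  if (!is.null(fit$signaling)) {
    write.table(fit$signaling$ranking,
                file.path(out_dir, "signaling_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(fit$signaling$subgraph_edges),
                file.path(out_dir, "signaling_subgraph.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$dark))
    write.table(fit$dark, file.path(out_dir, "dark_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(config, file.path(out_dir, "config.json"))
  invisible(fit)
}

#' Write a simulated dataset to disk
#'
#' Emits the on-disk form consumed by [run_pipeline()]: `expression.tsv`,
#' `metadata.tsv`, `network.tsv` (complete background over the circuit
#' genes) and a `truth.json` sidecar with the ground-truth critical
#' stage and DNB genes.
#'
#' @param dataset A [ccne_dataset] from [generate_sweep()] /
#'   [generate_null_sweep()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(gene = rownames(dataset$values), dataset$values,
                   check.names = FALSE)
  write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_id = colnames(dataset$values),
                         stage = as.character(dataset$stages),
                         stage_order = as.integer(dataset$stages)),
              file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  net <- complete_network(rownames(dataset$values))
  write.table(as.data.frame(net$edges), file.path(dir, "network.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- attr(dataset, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
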