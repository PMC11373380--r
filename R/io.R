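# Delimited-text readers and writers for expression matrices, edge lists,
# adjacency matrices and SIF network files. Edge-list orientation follows
# the package convention: the source column causes the target column.

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV or CSV table (delimiter sniffed from the file extension)
#' whose first row and first column hold labels. With
#' `orientation = "genes_by_samples"` the table is transposed so the result
#' is always samples x genes. Missing or non-numeric cells are rejected
#' with their row/column coordinates.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param orientation `"samples_by_genes"` (default) or
#'   `"genes_by_samples"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes",
                                            "genes_by_samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty or header-only file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in ", path, ": rows have ",
         paste(unique(widths), collapse = ", "), " fields")
  header <- fields[[1L]]
  col_labels <- header[-1L]
  row_labels <- vapply(fields[-1L], `[[`, "", 1L)
  body <- fields[-1L]
  vals <- matrix(NA_real_, length(body), length(col_labels))
  for (r in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[r]][-1L]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric or missing value at row '", row_labels[r],
           "', column '", col_labels[bad[1L]], "' in ", path)
    vals[r, ] <- v
  }
  dimnames(vals) <- list(row_labels, col_labels)
  if (orientation == "genes_by_samples") vals <- t(vals)
  expression_matrix(vals)
}

#' Write a weighted graph as an edge-list TSV
#'
#' Columns `source`, `target`, `weight` (one row per nonzero entry, the
#' source causing the target), preceded by a comment line documenting the
#' orientation. Weights are written at full float precision so
#' write-then-read round-trips are exact.
#'
#' @param g A `weighted_graph` (or `ground_truth_graph`).
#' @param path Output path.
#' @param gene_set_header If `TRUE` (default) a second comment line lists
#'   the full gene set, so genes without edges survive the round-trip.
#' @return `path`, invisibly.
#' @export
write_edges <- function(g, path, gene_set_header = TRUE) {
  W <- as_weight_matrix(g)
  ids <- gene_ids_of(g)
  nz <- which(W != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# edge orientation: source causes target (row causes column)",
             con)
  if (gene_set_header)
    writeLines(paste0("# genes: ", paste(ids, collapse = ",")), con)
  writeLines("source\ttarget\tweight", con)
  if (nrow(nz))
    writeLines(paste(ids[nz[, 1L]], ids[nz[, 2L]],
                     formatC(W[nz], format = "g", digits = 17), sep = "\t"),
               con)
  invisible(path)
}

read_edge_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  genes <- NULL
  regulators <- NULL
  gl <- grep("^# genes:", lines, value = TRUE)
  if (length(gl))
    genes <- strsplit(sub("^# genes:\\s*", "", gl[[1L]]), ",")[[1L]]
  rl <- grep("^# regulators:", lines, value = TRUE)
  if (length(rl))
    regulators <- strsplit(sub("^# regulators:\\s*", "", rl[[1L]]),
                           ",")[[1L]]
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("source", "target", "weight") %in% names(tab)))
    stop("edge list must have columns source, target, weight: ", path)
  list(table = tab, genes = genes, regulators = regulators)
}

#' Read a weighted graph from an edge-list TSV
#'
#' Inverse of [write_edges()]. The gene set is taken from the `# genes:`
#' comment line if present, from `gene_ids` if supplied, otherwise from the
#' union of the source/target columns.
#'
#' @param path Edge-list file.
#' @param gene_ids Optional character vector fixing the gene set and order.
#' @return A [weighted_graph()].
#' @export
read_edges <- function(path, gene_ids = NULL) {
  parsed <- read_edge_table(path)
  tab <- parsed$table
  ids <- gene_ids %||% parsed$genes %||%
    sort(unique(c(tab$source, tab$target)))
  unknown <- setdiff(unique(c(tab$source, tab$target)), ids)
  if (length(unknown))
    stop("edge list mentions genes outside the declared gene set: ",
         paste(unknown, collapse = ", "))
  d <- length(ids)
  W <- matrix(0, d, d, dimnames = list(ids, ids))
  if (nrow(tab)) W[cbind(match(tab$source, ids), match(tab$target, ids))] <-
      tab$weight
  weighted_graph(W, ids)
}

#' Read a ground-truth graph from an edge-list TSV
#'
#' Like [read_edges()] but returns a [ground_truth_graph()]. Regulator
#' labels come from, in order of precedence: a `# regulators:` comment line
#' (as written by [write_fixture_pair()], the only encoding that preserves
#' regulators without outgoing edges), a per-edge `regulator` column
#' (0/1 flag on the source gene), or out-degree inference (a regulator is a
#' gene with at least one outgoing edge).
#'
#' @inheritParams read_edges
#' @return A [ground_truth_graph()].
#' @export
read_truth <- function(path, gene_ids = NULL) {
  parsed <- read_edge_table(path)
  tab <- parsed$table
  g <- read_edges(path, gene_ids = gene_ids)
  labels <- NULL
  if (!is.null(parsed$regulators)) {
    unknown <- setdiff(parsed$regulators, g$gene_ids)
    if (length(unknown))
      stop("regulator line mentions unknown genes: ",
           paste(unknown, collapse = ", "))
    labels <- g$gene_ids %in% parsed$regulators
  } else if ("regulator" %in% names(tab)) {
    labels <- stats::setNames(rep(FALSE, length(g$gene_ids)), g$gene_ids)
    flagged <- unique(tab$source[as.logical(tab$regulator)])
    labels[flagged] <- TRUE
    labels <- unname(labels | rowSums(g$W != 0) > 0)
  }
  ground_truth_graph(g$W, regulator_labels = labels, gene_ids = g$gene_ids)
}

#' Write a weighted graph as a dense adjacency-matrix CSV
#'
#' Genes label both rows and columns; entry `(i, j)` is the weight of
#' `i -> j`.
#'
#' @param g A `weighted_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(g, path) {
  W <- as_weight_matrix(g)
  dimnames(W) <- list(gene_ids_of(g), gene_ids_of(g))
  utils::write.csv(W, path, quote = FALSE)
  invisible(path)
}

#' Write a weighted graph in SIF format for network viewers
#'
#' One line per edge: `source  regulates  target`.
#'
#' @param g A `weighted_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path) {
  W <- as_weight_matrix(g)
  ids <- gene_ids_of(g)
  nz <- which(W != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
  writeLines(paste(ids[nz[, 1L]], "regulates", ids[nz[, 2L]], sep = "\t"),
             path)
  invisible(path)
}

#' Write fixture files for a simulated benchmark instance
#'
#' Emits a matched pair: the expression TSV and the ground-truth edge-list
#' TSV (with a `regulator` column), as used by CLI-level tests.
#'
#' @param truth A [ground_truth_graph()].
#' @param x The matching [expression_matrix()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fixture_pair <- function(truth, x, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_path <- file.path(dir, paste0(prefix, "_expression.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  tab <- cbind(gene = c("", rownames(x)),
               rbind(colnames(x), formatC(unclass(x), format = "g",
                                          digits = 17)))
  writeLines(apply(tab, 1L, paste, collapse = "\t"), expr_path)
  W <- truth$W_true
  ids <- truth$gene_ids
  nz <- which(W != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
  con <- file(truth_path, "w")
  writeLines("# edge orientation: source causes target (row causes column)",
             con)
  writeLines(paste0("# genes: ", paste(ids, collapse = ",")), con)
  writeLines(paste0("# regulators: ",
                    paste(ids[truth$regulator_labels], collapse = ",")), con)
  writeLines("source\ttarget\tweight\tregulator", con)
  if (nrow(nz))
    writeLines(paste(ids[nz[, 1L]], ids[nz[, 2L]],
                     formatC(W[nz], format = "g", digits = 17),
                     as.integer(truth$regulator_labels[nz[, 1L]]),
                     sep = "\t"), con)
  close(con)
  invisible(c(expression = expr_path, truth = truth_path))
}

#' Write a run manifest
#'
#' JSON snapshot of the configuration, seed, package version, input-file
#' checksums and timestamp, sufficient to rerun a CLI command.
#'
#' @param dir Output directory.
#' @param command CLI subcommand name.
#' @param config Named list of settings.
#' @param inputs Character vector of input file paths (checksummed).
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, config, inputs = character(0)) {
  manifest <- list(
    tool = "pcnt",
    version = as.character(utils::packageVersion("pcnt")),
    command = command,
    config = config,
    input_checksums = as.list(tools::md5sum(inputs)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
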