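#' Validate an ASV count table
#'
#' Checks the package-wide count-table contract: a numeric matrix of
#' non-negative integers, taxa as rows and samples as columns, unique
#' dimnames, at least 2 samples.
#'
#' @param counts matrix to validate.
#' @return the matrix, invisibly, with integer storage.
#' @export
validate_asv_table <- function(counts) {
  if (!is.matrix(counts)) stop("ASV table must be a matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("ASV table must carry taxon (row) and sample (column) identifiers")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (ncol(counts) < 2L) stop("ASV table must have at least 2 samples")
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("missing count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read an ASV count table from TSV
#'
#' Expects a header row and identifiers in the first column. With
#' `orientation = "samples-rows"` the file is transposed after reading so
#' the returned matrix is always taxa x samples.
#'
#' @param path TSV file path.
#' @param orientation `"taxa-rows"` (default) or `"samples-rows"`.
#' @return validated integer matrix, taxa x samples.
#' @export
read_asv_table <- function(path, orientation = c("taxa-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop(sprintf("ragged TSV '%s': rows have %s fields", path,
                 paste(unique(nf), collapse = "/")))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table must have an id column plus at least one data column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    ctx <- if (nrow(bad)) sprintf(" (e.g. row '%s', column '%s')",
                                  ids[bad[1, 1]], colnames(m)[bad[1, 2]]) else ""
    stop("non-numeric cells in count table", ctx)
  }
  rownames(m) <- ids
  if (orientation == "samples-rows") m <- t(m)
  validate_asv_table(m)
}

#' Write an ASV count table as TSV
#'
#' @param counts taxa x samples count matrix.
#' @param path output file.
#' @param id_column header for the identifier column.
#' @export
write_asv_table <- function(counts, path, id_column = "taxon_id") {
  counts <- validate_asv_table(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' @param path TSV file with a `sample_id` column and a treatment `group`
#'   column (names configurable); remaining numeric columns are covariates
#'   and outcomes.
#' @param sample_col,group_col column names holding sample ids and
#'   treatment labels.
#' @return `data.frame` with `sample_id` (character) and `group` (factor)
#'   first.
#' @export
read_metadata <- function(path, sample_col = "sample_id", group_col = "group") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(sample_col, group_col))
    if (!col %in% names(df)) stop("metadata lacks required column '", col, "'")
  if (anyDuplicated(df[[sample_col]]))
    stop("duplicate sample identifiers in metadata")
  df[[sample_col]] <- as.character(df[[sample_col]])
  df[[group_col]] <- factor(df[[group_col]], levels = unique(df[[group_col]]))
  names(df)[match(c(sample_col, group_col), names(df))] <- c("sample_id", "group")
  df[c("sample_id", "group", setdiff(names(df), c("sample_id", "group")))]
}

#' Write sample metadata as TSV
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output file.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that metadata covers exactly the samples of a count table
#'
#' @param counts taxa x samples matrix.
#' @param metadata metadata data.frame with `sample_id`.
#' @return metadata reordered to the table's sample order.
#' @export
match_metadata <- function(counts, metadata) {
  missing <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing))
    stop("metadata missing samples present in counts: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(metadata$sample_id, colnames(counts))
  if (length(extra))
    stop("metadata lists samples absent from counts: ",
         paste(extra, collapse = ", "))
  metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
}

#' Read a Newick tree
#' @param path Newick file.
#' @return `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick tree in ", path)
  tr
}

#' Reconcile a tree with a count table's taxa
#'
#' Tips absent from the table are pruned with a warning. Table taxa absent
#' from the tree are a hard error: imputing zero-length placements would
#' silently bias phylogenetic diversity.
#'
#' @param tree `phylo`.
#' @param taxa taxon identifiers the tree must cover.
#' @return pruned `phylo`.
#' @export
match_tree <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("tree lacks table taxa (required for PD): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" ... (%d total)", length(missing)) else "")
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra)) {
    warning(sprintf("pruning %d tree tips absent from the table", length(extra)))
    tree <- ape::drop.tip(tree, extra)
  }
  tree
}

#' Write a co-occurrence network to disk
#'
#' GraphML keeps all node/edge attributes; the edge-list TSV has columns
#' `source`, `target`, `rho`, `p_adj`, `sign`.
#'
#' @param net a `co_network` (see [build_network()]) or `igraph` object.
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- if (inherits(net, "co_network")) net$graph else net
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     rho = signif(igraph::E(g)$rho, 6),
                     p_adj = signif(igraph::E(g)$p_adj, 6),
                     sign = igraph::E(g)$sign,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#' @param path GraphML file.
#' @return `igraph` object.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  igraph::read_graph(path, format = "graphml")
}

#' Write a result record set as TSV or JSON
#'
#' TSV output rounds numeric columns to 6 significant digits; JSON keeps
#' full precision.
#'
#' @param x data.frame (TSV/JSON) or list (JSON only).
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(x)) stop("TSV output requires a data.frame")
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], signif, digits = 6)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(path)
}
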