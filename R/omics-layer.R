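#' Construct a single omics layer
#'
#' An omics layer is one sample-by-feature numeric matrix (e.g. gene
#' expression, DNA methylation beta values, miRNA expression) measured on a
#' patient cohort. Samples are rows, features are columns; missing entries
#' are `NA`.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_ids character vector of unique sample identifiers
#'   (default: `rownames(values)`).
#' @param feature_ids character vector of unique feature identifiers
#'   (default: `colnames(values)`).
#' @param layer_name free-text label for the layer.
#' @return An object of class `omics_layer`: a list with elements `values`
#'   (matrix with dimnames set), and `layer_name`.
#' @export
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("s", 1:4), paste0("f", 1:5)))
#' omics_layer(m, layer_name = "expression")
omics_layer <- function(values,
                        sample_ids = rownames(values),
                        feature_ids = colnames(values),
                        layer_name = "layer") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stopf("layer '%s': %d sample ids for %d rows", layer_name,
          length(sample_ids), nrow(values))
  if (length(feature_ids) != ncol(values))
    stopf("layer '%s': %d feature ids for %d columns", layer_name,
          length(feature_ids), ncol(values))
  if (anyDuplicated(sample_ids))
    stopf("layer '%s': duplicated sample ids", layer_name)
  if (anyDuplicated(feature_ids))
    stopf("layer '%s': duplicated feature ids", layer_name)
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, layer_name = layer_name),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer '%s'> %d samples x %d features, %d missing\n",
              x$layer_name, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

sample_ids <- function(layer) rownames(layer$values)
feature_ids <- function(layer) colnames(layer$values)

#' Bundle omics layers measured on the same cohort
#'
#' All layers must carry identical sample ids in identical order; this is the
#' alignment contract every downstream fusion step relies on.
#'
#' @param ... `omics_layer` objects, or a single list of them.
#' @return An object of class `multi_omics`: a list with elements `layers`
#'   and `C` (the layer count).
#' @export
multi_omics <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "omics_layer"))
    layers <- layers[[1L]]
  if (length(layers) < 1L) stopf("need at least one omics layer")
  for (l in layers)
    if (!inherits(l, "omics_layer")) stopf("all layers must be omics_layer objects")
  ref <- sample_ids(layers[[1L]])
  for (l in layers[-1L]) {
    ids <- sample_ids(l)
    if (!identical(ids, ref)) {
      bad <- union(setdiff(ids, ref), setdiff(ref, ids))
      if (length(bad) == 0L)
        stopf("layer '%s': sample ids match but are ordered differently",
              l$layer_name)
      stopf("layer '%s': sample ids differ from first layer (e.g. %s)",
            l$layer_name, paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  structure(list(layers = layers, C = length(layers)), class = "multi_omics")
}

#' @export
print.multi_omics <- function(x, ...) {
  cat(sprintf("<multi_omics> %d layers, %d samples\n", x$C,
              nrow(x$layers[[1L]]$values)))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Read an omics layer from TSV
#'
#' Expected dialect: a header row `sample_id<TAB>feature1<TAB>...`, then one
#' row per sample (`sample id` followed by numeric values). Missing values
#' are empty cells or `NA`.
#'
#' @param path path to the TSV file.
#' @param layer_name layer label; defaults to the file name without extension.
#' @return An `omics_layer`.
#' @export
read_omics_tsv <- function(path, layer_name = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("%s: expected sample_id column plus features", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  omics_layer(m, sample_ids = ids, feature_ids = colnames(df)[-1L],
              layer_name = layer_name %||%
                sub("\\.[^.]*$", "", basename(path)))
}

#' Write an omics layer to TSV
#'
#' @param layer an `omics_layer`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_omics_tsv <- function(layer, path) {
  df <- data.frame(sample_id = sample_ids(layer),
                   layer$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write a square similarity matrix as TSV
#'
#' Sample ids occupy the first row and first column.
#'
#' @param path file path.
#' @return `read_similarity_tsv`: a numeric matrix with sample ids as
#'   dimnames.
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stopf("%s: similarity matrix must be square", path)
  m
}

#' @param W similarity matrix (or `fused_similarity`).
#' @rdname read_similarity_tsv
#' @export
write_similarity_tsv <- function(W, path) {
  m <- as_similarity_matrix(W)
  ids <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  df <- data.frame(sample_id = ids, m, check.names = FALSE)
  colnames(df) <- c("sample_id", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write cluster labels as TSV (columns `sample_id`, `cluster`)
#'
#' @param path file path.
#' @return `read_labels_tsv`: a `cluster_assignment`.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cluster") %in% names(df)))
    stopf("%s: need columns sample_id, cluster", path)
  cluster_assignment(as.character(df$sample_id), as.integer(df$cluster))
}

#' @param assignment a `cluster_assignment`.
#' @rdname read_labels_tsv
#' @export
write_labels_tsv <- function(assignment, path) {
  utils::write.table(
    data.frame(sample_id = assignment$sample_ids,
               cluster = assignment$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
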