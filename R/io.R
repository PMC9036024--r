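# Plain-text interchange: regional feature tables and expression matrices
# as TSV, networks as square CSV, per-subject edge vectors as TSV keyed by
# canonical edge id, volumes as NIfTI-1.

#' Write / read a regional feature matrix as TSV
#'
#' Rows are regions (first column \code{region}), columns named features.
#'
#' @param fm regions x features matrix with row and column names.
#' @param path file path.
#' @return (read) the matrix with region row names.
#' @export
write_feature_tsv <- function(fm, path) {
  df <- data.frame(region = rownames(fm), as.data.frame(fm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write / read a square network matrix as CSV
#'
#' @param net symmetric matrix with region names.
#' @param path file path.
#' @export
write_network_csv <- function(net, path) {
  utils::write.csv(as.data.frame(net), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Write / read stacked canonical edge vectors as TSV
#'
#' One row per subject (first column \code{subject_id}), one column per
#' canonical edge id "i_j".
#'
#' @param edges subjects x edges matrix with dimnames.
#' @param path file path.
#' @export
write_edges_tsv <- function(edges, path) {
  df <- data.frame(subject_id = rownames(edges), as.data.frame(edges),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write / read a regions x genes expression matrix as TSV
#'
#' Header row carries the gene symbols; first column the region labels.
#'
#' @param expr regions x genes matrix with dimnames.
#' @param path file path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(region = rownames(expr), as.data.frame(expr),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write an intensity + parcellation volume pair as NIfTI-1
#'
#' @param vol list with \code{intensity} and \code{labels} arrays (as
#'   returned by \code{\link{generate_labeled_volume}}).
#' @param intensity_path,labels_path output .nii / .nii.gz paths.
#' @export
write_volume_nifti <- function(vol, intensity_path, labels_path) {
  RNifti::writeNifti(RNifti::asNifti(vol$intensity), intensity_path)
  RNifti::writeNifti(RNifti::asNifti(vol$labels), labels_path)
  invisible(c(intensity_path, labels_path))
}

#' Read an intensity + parcellation volume pair from NIfTI-1
#'
#' @param intensity_path,labels_path input paths.
#' @return list with \code{intensity} and \code{labels} arrays.
#' @export
read_volume_nifti <- function(intensity_path, labels_path) {
  list(intensity = array(as.numeric(RNifti::readNifti(intensity_path)),
                         dim = dim(RNifti::readNifti(intensity_path))),
       labels = array(as.integer(round(as.numeric(
         RNifti::readNifti(labels_path)))),
         dim = dim(RNifti::readNifti(labels_path))))
}
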