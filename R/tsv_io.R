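# Plain TSV import/export for profiles, maps and experimental tables.
# Convention: column 1 is always the author residue number.

#' Write a per-residue profile as TSV
#'
#' Works for `helicity_profile` and `pre_profile` objects and for plain
#' data frames whose first column is `resno`.
#'
#' @param x Object to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(x, path) {
  df <- if (inherits(x, "helicity_profile")) {
    data.frame(resno = x$resno, fraction = x$fraction,
               uncertainty = x$uncertainty)
  } else if (inherits(x, "pre_profile")) {
    data.frame(resno = x$resno, ratio = x$ratio)
  } else {
    as.data.frame(x)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue TSV table
#'
#' Expects a header line; column 1 must be the residue number.  Missing
#' values may be encoded as `NA` or an empty field.
#'
#' @param path Input path.
#' @return Data frame with at least a `resno` column.
#' @export
read_profile_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(df)[1] <- "resno"
  df
}

#' Write a contact map as dense and sparse TSV
#'
#' The dense file is a matrix with residue-number row/column headers
#' (masked entries as `NA`); the sparse file lists `i`, `j`, `probability`
#' triplets for the unmasked upper triangle.
#'
#' @param cm A `contact_map`.
#' @param dense_path,sparse_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_contact_map_tsv <- function(cm, dense_path = NULL,
                                  sparse_path = NULL) {
  if (!is.null(dense_path)) {
    m <- cm$matrix
    dimnames(m) <- list(cm$resno, cm$resno)
    write.table(data.frame(resno = cm$resno, m, check.names = FALSE),
                dense_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sparse_path)) {
    ut <- which(upper.tri(cm$matrix) & !is.na(cm$matrix), arr.ind = TRUE)
    write.table(data.frame(i = cm$resno[ut[, 1]], j = cm$resno[ut[, 2]],
                           probability = cm$matrix[ut]),
                sparse_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(dense_path, sparse_path))
}

#' Write a substate histogram as a dense TSV matrix
#'
#' @param h A `substate_histogram`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_substates_tsv <- function(h, path) {
  write.table(data.frame(start_resno = h$resno, h$matrix,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth sidecar of a synthetic ensemble
#'
#' @param ground_truth The `ground_truth` element of [generate_ensemble()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth_tsv <- function(ground_truth, path) {
  write.table(data.frame(resno = as.integer(colnames(ground_truth$states)),
                         helicity = ground_truth$helicity),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cluster assignments as TSV
#'
#' @param cs A `cluster_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters_tsv <- function(cs, path) {
  write.table(data.frame(frame = seq_len(cs$n_frames),
                         cluster = cs$assignment),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
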