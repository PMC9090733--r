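#' Covariance specification for a random effect
#'
#' A `cov_spec` bundles a labelled symmetric similarity/covariance matrix with
#' optional block-diagonal structure. It is the `V` of the model
#' `y = mu + Z x + e`, `x ~ N(0, V sigma2_x)`. Entries are similarities in
#' `[0, 1]`; the matrix must be symmetric with strictly positive diagonal.
#'
#' @param labels character vector of level identifiers (transcripts, genes,
#'   GO terms or Reactome pathway ids), one per row/column.
#' @param matrix square numeric matrix (base `matrix` or a `Matrix` sparse
#'   matrix) of similarities.
#' @param block_structure optional data.frame with columns `start`, `end`
#'   (1-based inclusive index ranges) marking exploitable diagonal blocks.
#' @param psd_repaired logical; `TRUE` when [ensure_psd()] altered the matrix.
#'
#' @return an object of class `cov_spec` with elements `labels`, `matrix`,
#'   `block_structure`, `psd_repaired`.
#' @export
cov_spec <- function(labels, matrix, block_structure = NULL,
                     psd_repaired = FALSE) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("cov_spec: empty label set")
  if (anyDuplicated(labels)) stop("cov_spec: duplicate labels")
  d <- dim(matrix)
  if (is.null(d) || d[1] != d[2] || d[1] != length(labels))
    stop("cov_spec: matrix dimensions do not match labels")
  .check_symmetric(matrix, tol = 1e-12, what = "cov_spec")
  dg <- .mat_diag(matrix)
  if (any(dg <= 0)) stop("cov_spec: diagonal entries must be > 0")
  rng <- .mat_range(matrix)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    stop("cov_spec: entries must lie in [0, 1]")
  if (!is.null(block_structure)) {
    block_structure <- as.data.frame(block_structure)
    stopifnot(all(c("start", "end") %in% names(block_structure)))
    if (block_structure$start[1] != 1L ||
        block_structure$end[nrow(block_structure)] != length(labels) ||
        any(block_structure$start[-1] != block_structure$end[-nrow(block_structure)] + 1L))
      stop("cov_spec: block_structure must tile 1..q contiguously")
  }
  structure(list(labels = labels, matrix = matrix,
                 block_structure = block_structure,
                 psd_repaired = isTRUE(psd_repaired)),
            class = "cov_spec")
}

#' @exportS3Method base::print
print.cov_spec <- function(x, ...) {
  q <- length(x$labels)
  nb <- if (is.null(x$block_structure)) 1L else nrow(x$block_structure)
  cat(sprintf("cov_spec: %d levels, %d block(s)%s\n", q, nb,
              if (x$psd_repaired) ", psd-repaired" else ""))
  invisible(x)
}

#' @export
dim.cov_spec <- function(x) dim(x$matrix)

.mat_diag <- function(m) diag(m)

.mat_range <- function(m) {
  if (inherits(m, "diagonalMatrix")) {
    x <- if (identical(m@diag, "U")) 1 else m@x
    if (nrow(m) > 1L) range(x, 0) else range(x)
  } else if (inherits(m, "sparseMatrix")) {
    # implicit zeros of a sparse matrix count as entries
    x <- m@x
    if (length(x) < length(m)) range(x, 0) else range(x)
  } else {
    range(as.matrix(m))
  }
}

.check_symmetric <- function(m, tol, what) {
  dev <- max(abs(m - t(m)))
  if (dev > tol)
    stop(sprintf("%s: matrix not symmetric (max deviation %.3g)", what, dev))
  invisible(TRUE)
}

#' Extract a dense base matrix from a cov_spec
#' @param spec a [cov_spec()].
#' @return dense base matrix with dimnames set to the labels.
#' @export
as_dense_matrix <- function(spec) {
  m <- as.matrix(spec$matrix)
  dimnames(m) <- list(spec$labels, spec$labels)
  m
}

#' Minimum eigenvalue of a cov_spec
#'
#' Computed blockwise when block structure is present (the spectrum of a
#' block-diagonal matrix is the union of the block spectra).
#' @param spec a [cov_spec()].
#' @return smallest eigenvalue (numeric scalar).
#' @export
min_eigenvalue <- function(spec) {
  if (is.null(spec$block_structure)) {
    return(min(eigen(as.matrix(spec$matrix), symmetric = TRUE,
                     only.values = TRUE)$values))
  }
  bs <- spec$block_structure
  mins <- vapply(seq_len(nrow(bs)), function(b) {
    idx <- bs$start[b]:bs$end[b]
    min(eigen(as.matrix(spec$matrix[idx, idx, drop = FALSE]),
              symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  min(mins)
}

#' Subset a cov_spec to a set of labels
#'
#' Keeps the rows/columns for `labels` in the order they appear in the spec.
#' Block structure is recomputed from the surviving indices; blocks losing all
#' members are dropped.
#' @param spec a [cov_spec()].
#' @param labels labels to retain (order ignored; spec order preserved).
#' @return a [cov_spec()] over the retained labels.
#' @export
subset_cov_spec <- function(spec, labels) {
  keep <- spec$labels %in% labels
  if (!any(keep)) stop("subset_cov_spec: no labels retained")
  if (all(keep)) return(spec)
  idx <- which(keep)
  bs <- NULL
  if (!is.null(spec$block_structure)) {
    old <- spec$block_structure
    block_of <- rep.int(seq_len(nrow(old)), old$end - old$start + 1L)
    counts <- table(factor(block_of[idx], levels = seq_len(nrow(old))))
    counts <- as.integer(counts[counts > 0])
    ends <- cumsum(counts)
    bs <- data.frame(start = c(1L, ends[-length(ends)] + 1L), end = ends)
  }
  cov_spec(spec$labels[idx], spec$matrix[idx, idx, drop = FALSE],
           block_structure = bs, psd_repaired = spec$psd_repaired)
}

#' Write / read a cov_spec as Matrix Market plus a label sidecar
#'
#' `write_cov_spec()` writes `<stem>.mtx` (MatrixMarket coordinate format) and
#' `<stem>.labels` (one label per line). `read_cov_spec()` reads them back;
#' block structure is not persisted.
#' @param spec a [cov_spec()].
#' @param stem path stem without extension.
#' @return `write_cov_spec()` the stem, invisibly; `read_cov_spec()` a
#'   [cov_spec()].
#' @export
write_cov_spec <- function(spec, stem) {
  m <- methods::as(methods::as(Matrix::Matrix(spec$matrix, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paste0(stem, ".mtx"))
  writeLines(spec$labels, paste0(stem, ".labels"))
  invisible(stem)
}

#' @rdname write_cov_spec
#' @export
read_cov_spec <- function(stem) {
  m <- Matrix::readMM(paste0(stem, ".mtx"))
  labels <- readLines(paste0(stem, ".labels"))
  m <- Matrix::forceSymmetric((m + Matrix::t(m)) / 2)
  cov_spec(labels, m)
}
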