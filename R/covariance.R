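#' Exon-composition similarity between the transcripts of one gene
#'
#' For transcripts i, j of a gene with exon sets `E_i`, `E_j`, the similarity
#' is `a / N` where `a = |E_i intersect E_j|` and `N` is the number of
#' distinct exons of the gene (the size of the union over all transcripts).
#' The formula is applied literally including the diagonal, so entry (i, i)
#' equals `|E_i| / N` and may be below 1 for transcripts that skip exons.
#' The result equals `(1/N) M M'` for the transcript-by-exon 0/1 membership
#' matrix `M`, hence is a Gram matrix and positive semidefinite by
#' construction.
#'
#' @param gene a [gene_model()].
#' @param correlation_scale logical; if `TRUE`, rescale to unit diagonal
#'   (correlation form). Default `FALSE` keeps the literal `a / N` matrix.
#' @return a [cov_spec()] with one label per transcript.
#' @export
transcript_exon_similarity <- function(gene, correlation_scale = FALSE) {
  stopifnot(inherits(gene, "gene_model"))
  tx <- gene$transcripts
  if (length(tx) == 0L) stop("transcript_exon_similarity: gene has no transcripts")
  if (any(lengths(tx) == 0L))
    stop("transcript_exon_similarity: transcript with empty exon set")
  universe <- unique(unlist(tx, use.names = FALSE))
  N <- length(universe)
  M <- matrix(unlist(lapply(tx, function(e) as.numeric(universe %in% e)),
                     use.names = FALSE), nrow = N)
  # M is N x k (exon by transcript); Gram over transcripts
  V <- crossprod(M) / N
  if (correlation_scale) {
    s <- sqrt(diag(V))
    V <- V / tcrossprod(s)
    diag(V) <- 1
  }
  V <- (V + t(V)) / 2
  cov_spec(names(tx), V)
}

#' Assemble per-gene covariance blocks into one block-diagonal cov_spec
#'
#' Independence is assumed between genes, so the full transcript covariance
#' is block diagonal with one block per gene.
#'
#' @param blocks list of [cov_spec()] objects with pairwise disjoint labels.
#' @return a [cov_spec()] whose matrix is sparse block-diagonal and whose
#'   `block_structure` records the index range of each input block.
#' @export
assemble_block_diagonal <- function(blocks) {
  stopifnot(length(blocks) >= 1L, all(vapply(blocks, inherits, logical(1), "cov_spec")))
  labels <- unlist(lapply(blocks, `[[`, "labels"), use.names = FALSE)
  if (anyDuplicated(labels))
    stop("assemble_block_diagonal: overlapping labels between blocks")
  sizes <- vapply(blocks, function(b) length(b$labels), integer(1))
  ends <- cumsum(sizes)
  bs <- data.frame(start = c(1L, ends[-length(ends)] + 1L), end = ends)
  m <- Matrix::bdiag(lapply(blocks, function(b) Matrix::Matrix(b$matrix, sparse = TRUE)))
  m <- Matrix::forceSymmetric(m)
  cov_spec(labels, m, block_structure = bs,
           psd_repaired = any(vapply(blocks, `[[`, logical(1), "psd_repaired")))
}

#' Identity covariance (independent levels)
#'
#' The gene-level model assumes no covariance between genes, so its `V` is
#' the identity.
#'
#' @param labels character vector of level identifiers.
#' @return a [cov_spec()] holding a (sparse) identity matrix; every level is
#'   its own block, so blocked solvers apply.
#' @export
identity_covariance <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("identity_covariance: empty label set")
  if (anyDuplicated(labels)) stop("identity_covariance: duplicate labels")
  q <- length(labels)
  bs <- data.frame(start = seq_len(q), end = seq_len(q))
  cov_spec(labels, Matrix::Diagonal(q), block_structure = bs)
}

#' Jaccard similarity between term gene sets
#'
#' Entry (s, t) is `|G_s intersect G_t| / |G_s union G_t|` for the gene sets
#' of two GO terms or Reactome pathways; the diagonal is exactly 1. The
#' result is symmetric but not guaranteed positive semidefinite — pass it
#' through [ensure_psd()] before model fitting.
#'
#' @param level_universe named list mapping term id to a character vector of
#'   gene ids (as in a [term_mapping()]'s `level_universe`).
#' @return a [cov_spec()] over the terms.
#' @export
term_overlap_jaccard <- function(level_universe) {
  if (length(level_universe) == 0L)
    stop("term_overlap_jaccard: no terms")
  if (is.null(names(level_universe)) || anyDuplicated(names(level_universe)))
    stop("term_overlap_jaccard: terms must be uniquely named")
  sets <- lapply(level_universe, unique)
  if (any(lengths(sets) == 0L))
    stop("term_overlap_jaccard: term with empty gene set")
  genes <- unique(unlist(sets, use.names = FALSE))
  q <- length(sets)
  j <- unlist(lapply(sets, match, table = genes), use.names = FALSE)
  i <- rep.int(seq_len(q), lengths(sets))
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(q, length(genes)))
  inter <- as.matrix(Matrix::tcrossprod(M))
  sz <- lengths(sets)
  uni <- outer(sz, sz, `+`) - inter
  J <- inter / uni
  diag(J) <- 1
  J <- (J + t(J)) / 2
  dimnames(J) <- NULL
  cov_spec(names(sets), J)
}

#' Repair a covariance spec to positive semidefiniteness
#'
#' Jaccard similarity matrices over overlapping gene sets are not guaranteed
#' positive semidefinite. If the smallest eigenvalue is below `-1e-10`,
#' negative eigenvalues are clipped to `eigen_floor`, the matrix is
#' reconstructed and re-symmetrized, and — when the input diagonal was all
#' ones — rescaled back to unit diagonal. Otherwise the input is returned
#' unchanged. Applied per block when block structure is present.
#'
#' @param spec a [cov_spec()].
#' @param eigen_floor replacement value for clipped eigenvalues (default 0).
#' @return a [cov_spec()] with `psd_repaired = TRUE` when a repair was made.
#' @export
ensure_psd <- function(spec, eigen_floor = 0) {
  stopifnot(inherits(spec, "cov_spec"), eigen_floor >= 0)
  repair <- function(m) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= -1e-10) return(NULL)
    vals <- pmax(e$values, eigen_floor)
    out <- e$vectors %*% (vals * t(e$vectors))
    out <- (out + t(out)) / 2
    if (all(abs(diag(m) - 1) < 1e-12)) {
      s <- sqrt(diag(out))
      out <- out / tcrossprod(s)
      diag(out) <- 1
    }
    # numerical clean-up: clipping can push entries epsilon outside [0, 1]
    out <- pmin(pmax(out, 0), 1)
    out
  }
  if (is.null(spec$block_structure)) {
    m <- as.matrix(spec$matrix)
    .check_symmetric(m, 1e-12, "ensure_psd")
    r <- repair(m)
    if (is.null(r)) return(spec)
    message(sprintf("ensure_psd: clipped negative eigenvalues (max entry change %.3g)",
                    max(abs(r - m))))
    return(cov_spec(spec$labels, r, psd_repaired = TRUE))
  }
  bs <- spec$block_structure
  changed <- FALSE
  m <- spec$matrix
  for (b in seq_len(nrow(bs))) {
    idx <- bs$start[b]:bs$end[b]
    mb <- as.matrix(m[idx, idx, drop = FALSE])
    .check_symmetric(mb, 1e-12, "ensure_psd")
    r <- repair(mb)
    if (!is.null(r)) {
      m[idx, idx] <- r
      changed <- TRUE
    }
  }
  if (!changed) return(spec)
  message("ensure_psd: clipped negative eigenvalues in one or more blocks")
  cov_spec(spec$labels, Matrix::forceSymmetric(Matrix::Matrix(m, sparse = TRUE)),
           block_structure = bs, psd_repaired = TRUE)
}
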