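#' Simulate gene models with overlapping exon composition
#'
#' Emulates Ensembl-style gene/transcript/exon hierarchies: each gene gets
#' an exon universe of size drawn uniformly from `exons_per_gene`, and each
#' transcript includes each exon independently with probability `sharing`
#' (forced non-empty). Genes are laid out on 20 chromosomes at
#' non-overlapping coordinates; exons are 100 bp on the + strand.
#'
#' @param n_genes number of genes (>= 1).
#' @param transcripts_per_gene integer range `c(min, max)` of transcripts
#'   per gene.
#' @param exons_per_gene integer range `c(min, max)` of distinct exons per
#'   gene.
#' @param sharing probability in `[0, 1]` that a transcript includes a given
#'   exon; 1 makes all transcripts of a gene identical.
#' @param seed integer seed; the output is deterministic given the seed.
#' @return named list of [gene_model()] objects.
#' @export
simulate_gene_models <- function(n_genes, transcripts_per_gene = c(1L, 6L),
                                 exons_per_gene = c(3L, 12L), sharing = 0.7,
                                 seed = 1L) {
  stopifnot(n_genes >= 1, sharing >= 0, sharing <= 1,
            transcripts_per_gene[1] >= 1,
            transcripts_per_gene[2] >= transcripts_per_gene[1],
            exons_per_gene[1] >= 1,
            exons_per_gene[2] >= exons_per_gene[1])
  set.seed(seed)
  models <- vector("list", n_genes)
  tx_counter <- 0L
  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("SIMG%05d", g)
    n_ex <- sample(exons_per_gene[1]:exons_per_gene[2], 1L)
    n_tx <- sample(transcripts_per_gene[1]:transcripts_per_gene[2], 1L)
    chrom <- paste0("chr", (g - 1L) %% 20L + 1L)
    offset <- ((g - 1L) %/% 20L) * 100000L
    starts <- offset + (seq_len(n_ex) - 1L) * 200L + 1L
    exons <- data.frame(chrom = chrom, start = starts, end = starts + 99L,
                        strand = "+", stringsAsFactors = FALSE)
    exons$key <- .exon_key(exons$chrom, exons$start, exons$end, exons$strand)
    tx <- lapply(seq_len(n_tx), function(t) {
      inc <- stats::runif(n_ex) < sharing
      if (!any(inc)) inc[sample.int(n_ex, 1L)] <- TRUE
      exons$key[inc]
    })
    names(tx) <- sprintf("SIMT%07d", tx_counter + seq_len(n_tx))
    tx_counter <- tx_counter + n_tx
    models[[g]] <- gene_model(gene_id, tx, exons)
  }
  stats::setNames(models, vapply(models, `[[`, character(1), "gene_id"))
}

#' Simulate many-to-many term assignments (GO/Reactome style)
#'
#' Each term receives a random gene set of size drawn from
#' `genes_per_term`; leftover genes are then attached to random terms so
#' that every gene belongs to at least one term. Transcripts inherit their
#' gene's terms through `tx2gene`.
#'
#' @param tx2gene named character vector transcript id -> gene id (e.g. from
#'   [tx2gene_map()]).
#' @param n_terms number of terms (>= 1).
#' @param genes_per_term integer range `c(min, max)` of genes per term.
#' @param kind `"go"` or `"reactome"` (label only).
#' @param prefix term-id prefix (default depends on `kind`).
#' @param seed integer seed.
#' @return a [term_mapping()].
#' @export
simulate_term_assignments <- function(tx2gene, n_terms,
                                      genes_per_term = c(5L, 50L),
                                      kind = c("go", "reactome"),
                                      prefix = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_terms >= 1, genes_per_term[1] >= 1,
            genes_per_term[2] >= genes_per_term[1])
  genes <- unique(unname(tx2gene))
  if (genes_per_term[1] > length(genes))
    stop("simulate_term_assignments: genes_per_term exceeds the gene pool")
  if (is.null(prefix))
    prefix <- if (kind == "go") "GO:91" else "R-SIM-91"
  set.seed(seed)
  term_ids <- sprintf("%s%05d", prefix, seq_len(n_terms))
  universe <- lapply(seq_len(n_terms), function(t) {
    k <- sample(genes_per_term[1]:min(genes_per_term[2], length(genes)), 1L)
    sample(genes, k)
  })
  names(universe) <- term_ids
  covered <- unique(unlist(universe, use.names = FALSE))
  leftover <- setdiff(genes, covered)
  for (g in leftover) {
    t <- sample.int(n_terms, 1L)
    universe[[t]] <- c(universe[[t]], g)
  }
  gene2terms <- lapply(
    stats::setNames(genes, genes),
    function(g) term_ids[vapply(universe, function(s) g %in% s, logical(1))])
  assignments <- lapply(tx2gene, function(g) gene2terms[[g]])
  names(assignments) <- names(tx2gene)
  term_mapping(kind, assignments, level_universe = universe,
               tx2gene = tx2gene)
}

#' Simulate a log2 fold change vector under the mixed model
#'
#' Draws `x ~ N(0, V sigma2_x)` through a symmetric eigen-factor of `V`
#' (negative eigenvalues clipped at 0, consistent with [ensure_psd()]),
#' `e ~ N(0, I sigma2_e)`, and returns `y = mu + Z x + e` together with the
#' ground truth.
#'
#' @param V a [cov_spec()] over the random-effect levels.
#' @param Z an [incidence_map()][build_incidence] whose levels match
#'   `V$labels`; `NULL` means one observation per level (`Z = I`), with
#'   observation ids equal to the level labels.
#' @param mu scalar general mean (log2FC units).
#' @param sigma2_x random-effect variance (>= 0).
#' @param sigma2_e residual variance (>= 0; 0 is allowed here for exact
#'   degenerate draws).
#' @param seed integer seed.
#' @return list with `y` (an [expression_vector()]) and `truth` (class
#'   `synthetic_truth`: `mu_true`, `x_true`, `sigma2_x_true`,
#'   `sigma2_e_true`, `labels`, `seed`).
#' @export
simulate_expression <- function(V, Z = NULL, mu = 0, sigma2_x, sigma2_e,
                                seed = 1L) {
  stopifnot(inherits(V, "cov_spec"), sigma2_x >= 0, sigma2_e >= 0)
  q <- length(V$labels)
  set.seed(seed)
  u <- stats::rnorm(q)
  x <- if (sigma2_x == 0) numeric(q) else sqrt(sigma2_x) * .cov_factor_mult(V, u)
  if (is.null(Z)) {
    obs <- V$labels
    zx <- x
  } else {
    stopifnot(inherits(Z, "incidence_map"))
    if (!identical(Z$levels, V$labels))
      stop("simulate_expression: incidence levels and covariance labels differ")
    obs <- Z$observations
    zx <- as.vector(Z$Z %*% x)
  }
  e <- if (sigma2_e == 0) numeric(length(obs)) else
    stats::rnorm(length(obs), sd = sqrt(sigma2_e))
  y <- expression_vector(obs, mu + zx + e)
  truth <- structure(list(mu_true = mu, x_true = stats::setNames(x, V$labels),
                          sigma2_x_true = sigma2_x, sigma2_e_true = sigma2_e,
                          labels = V$labels, seed = seed),
                     class = "synthetic_truth")
  list(y = y, truth = truth)
}

# multiply a symmetric PSD factor of V (eigen square root, negative
# eigenvalues clipped at 0) with a vector, blockwise when possible
.cov_factor_mult <- function(V, u) {
  fac_mult <- function(m, v) {
    e <- eigen(m, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    as.vector(e$vectors %*% (sqrt(vals) * crossprod(e$vectors, v)))
  }
  bs <- V$block_structure
  if (is.null(bs)) return(fac_mult(as.matrix(V$matrix), u))
  out <- numeric(length(u))
  for (b in seq_len(nrow(bs))) {
    idx <- bs$start[b]:bs$end[b]
    out[idx] <- fac_mult(as.matrix(V$matrix[idx, idx, drop = FALSE]), u[idx])
  }
  out
}

#' Simulate a complete synthetic study
#'
#' Generates gene models, GO-like and Reactome-like term assignments, and a
#' log2 fold change vector drawn under the transcript-based model (exon
#' similarity covariance, one observation per transcript). The defaults
#' mirror a desk-scale transcriptome: ~700 genes, a few transcripts each,
#' 100 GO-like terms, 80 pathway-like terms, and a random-effect share of
#' about 15% of the response variance.
#'
#' @param n_genes,transcripts_per_gene,exons_per_gene,sharing passed to
#'   [simulate_gene_models()].
#' @param n_go_terms,n_reactome number of GO-like / Reactome-like terms.
#' @param genes_per_term passed to [simulate_term_assignments()].
#' @param mu,sigma2_x,sigma2_e generative parameters of the expression draw.
#' @param seed integer seed controlling every stage.
#' @return list with `models`, `tx2gene`, `go`, `reactome` (term mappings),
#'   `V` (assembled block-diagonal exon-similarity covariance), `y`, `truth`.
#' @export
simulate_study <- function(n_genes = 700L, transcripts_per_gene = c(1L, 6L),
                           exons_per_gene = c(3L, 12L), sharing = 0.7,
                           n_go_terms = 100L, n_reactome = 80L,
                           genes_per_term = c(5L, 50L),
                           mu = 0, sigma2_x = 0.15, sigma2_e = 0.85,
                           seed = 1L) {
  models <- simulate_gene_models(n_genes, transcripts_per_gene,
                                 exons_per_gene, sharing, seed = seed)
  tx2gene <- tx2gene_map(models)
  go <- simulate_term_assignments(tx2gene, n_go_terms, genes_per_term,
                                  kind = "go", seed = seed + 1L)
  reactome <- simulate_term_assignments(tx2gene, n_reactome, genes_per_term,
                                        kind = "reactome", seed = seed + 2L)
  V <- assemble_block_diagonal(lapply(models, transcript_exon_similarity))
  sim <- simulate_expression(V, Z = NULL, mu = mu, sigma2_x = sigma2_x,
                             sigma2_e = sigma2_e, seed = seed + 3L)
  list(models = models, tx2gene = tx2gene, go = go, reactome = reactome,
       V = V, y = sim$y, truth = sim$truth)
}
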