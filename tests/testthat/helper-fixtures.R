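# Shared fixtures and independent oracles, all built in code.

# random similarity-like PSD matrix: Hadamard square of a random
# correlation matrix (PSD by the Schur product theorem, entries in [0, 1],
# moderate off-diagonal mass)
rand_psd <- function(q) {
  A <- matrix(stats::rnorm(q * q), q)
  V <- tcrossprod(A) / q + diag(0.5, q)
  D <- sqrt(diag(V))
  V <- V / outer(D, D)
  V <- V * V
  diag(V) <- 1
  (V + t(V)) / 2
}

# random small mixed-model instance: n observations grouped into q levels
# (every level hit at least once), a random PSD V, optionally a response
# drawn under the model
rand_instance <- function(n, q, s2x = NULL, s2e = NULL, mu = 0,
                          draw_y = TRUE) {
  stopifnot(q <= n)
  lab <- sprintf("L%03d", seq_len(q))
  grp <- sample.int(q, n, replace = TRUE)
  grp[seq_len(q)] <- seq_len(q)
  ids <- sprintf("T%04d", seq_len(n))
  mp <- term_mapping("go", stats::setNames(as.list(lab[grp]), ids),
                     level_universe = stats::setNames(as.list(lab), lab),
                     tx2gene = stats::setNames(ids, ids))
  Vm <- rand_psd(q)
  ev0 <- expression_vector(ids, stats::rnorm(n))
  Z <- build_incidence(ev0, mp)
  V <- cov_spec(Z$levels, Vm[match(Z$levels, lab), match(Z$levels, lab)])
  y <- ev0
  truth <- NULL
  if (draw_y && !is.null(s2x)) {
    sim <- simulate_expression(V, Z, mu = mu, sigma2_x = s2x, sigma2_e = s2e,
                               seed = sample.int(1e6, 1))
    y <- sim$y
    truth <- sim$truth
  }
  list(y = y, Z = Z, V = V, mapping = mp, truth = truth)
}

# brute-force dense GLS / BLUP closed forms through the marginal covariance:
# mu = (1' Vy^-1 1)^-1 1' Vy^-1 y,  x = s2x V Z' Vy^-1 (y - 1 mu),
# Vy = Z (V s2x) Z' + I s2e
oracle_gls_blup <- function(y, Zm, Vm, s2x, s2e) {
  n <- length(y)
  Vy <- s2x * Zm %*% Vm %*% t(Zm) + diag(s2e, n)
  Vyi <- solve(Vy)
  ones <- rep(1, n)
  mu <- as.numeric((t(ones) %*% Vyi %*% y) / (t(ones) %*% Vyi %*% ones))
  x <- as.vector(s2x * Vm %*% t(Zm) %*% Vyi %*% (y - mu))
  list(mu = mu, x = x)
}

# derivative-free REML maximization over (s2x, s2e) on the log scale,
# independent of the EM path
oracle_reml_optim <- function(y, Z, V) {
  s2y <- stats::var(as.numeric(y))
  fn <- function(p) -reml_loglik(y, Z, V, exp(p[1]), exp(p[2]))
  opt <- stats::optim(log(c(s2y / 2, s2y / 2)), fn,
                      control = list(reltol = 1e-14, maxit = 10000))
  exp(opt$par)
}

write_toy_gtf <- function(path, rows) {
  # rows: data.frame(chrom,start,end,strand,gene,tx)
  lines <- sprintf(
    '%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    rows$chrom, rows$start, rows$end, rows$strand, rows$gene, rows$tx)
  writeLines(lines, path)
  path
}

# minimal OBO writer: edges is a data.frame(child, parent); roots appear
# only as parents
write_toy_obo <- function(path, edges, namespace = "biological_process") {
  terms <- unique(c(edges$child, edges$parent))
  chunks <- vapply(terms, function(t) {
    isa <- edges$parent[edges$child == t]
    paste(c("[Term]", paste0("id: ", t), paste0("name: ", t),
            paste0("namespace: ", namespace),
            if (length(isa)) paste0("is_a: ", isa, " ! x"), ""),
          collapse = "\n")
  }, character(1))
  writeLines(c("format-version: 1.2", "", chunks), path)
  path
}

# gene models whose exon-similarity blocks are guaranteed nonsingular:
# each transcript carries one private exon plus a random share of a common
# exon pool, so the membership rows are linearly independent
nonsingular_gene_models <- function(n_genes, max_tx = 4L, shared_pool = 5L,
                                    sharing = 0.6, seed = 1L) {
  set.seed(seed)
  models <- list()
  counter <- 0L
  for (g in seq_len(n_genes)) {
    n_tx <- sample.int(max_tx, 1L)
    n_ex <- n_tx + shared_pool
    starts <- (seq_len(n_ex) - 1L) * 200L + 1L
    chrom <- paste0("chr", (g - 1L) %% 5L + 1L)
    exons <- data.frame(chrom = chrom, start = starts + g * 100000L,
                        end = starts + g * 100000L + 99L, strand = "+")
    exons$key <- paste0(exons$chrom, ":", exons$start, "-", exons$end, ":+")
    tx <- lapply(seq_len(n_tx), function(t) {
      shared <- which(stats::runif(shared_pool) < sharing) + n_tx
      exons$key[c(t, shared)]
    })
    names(tx) <- sprintf("NT%06d", counter + seq_len(n_tx))
    counter <- counter + n_tx
    models[[g]] <- gene_model(sprintf("NG%04d", g), tx, exons)
  }
  stats::setNames(models, vapply(models, `[[`, character(1), "gene_id"))
}
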