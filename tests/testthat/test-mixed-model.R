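test_that("incidence matrices follow the stated conventions", {
  ev <- expression_vector(c("T1", "T2", "T3", "T4"), c(0.1, -0.2, 0.3, 0))
  # transcript model: identity assignment
  Z1 <- build_incidence(ev, NULL)
  expect_equal(as.matrix(Z1$Z), diag(4), ignore_attr = TRUE)
  # gene model: 4 transcripts of 2 genes, row sums 1
  mp <- term_mapping("gene", list(T1 = "G1", T2 = "G1", T3 = "G2", T4 = "G2"))
  Z2 <- build_incidence(ev, mp)
  expect_equal(dim(Z2$Z), c(4L, 2L))
  expect_equal(unname(Matrix::rowSums(Z2$Z)), rep(1, 4))
  # a transcript with 3 terms carries three 1s
  mp3 <- term_mapping("go",
                      list(T1 = c("a", "b", "c"), T2 = "a", T3 = "b", T4 = "c"),
                      level_universe = list(a = "G1", b = "G1", c = "G2"),
                      tx2gene = c(T1 = "G1", T2 = "G1", T3 = "G2", T4 = "G2"))
  Z3 <- build_incidence(ev, mp3)
  expect_equal(unname(Matrix::rowSums(Z3$Z)[1]), 3)
  # weighted variant normalizes rows
  Zw <- build_incidence(ev, mp3, weighted = TRUE)
  expect_equal(unname(Matrix::rowSums(Zw$Z)), rep(1, 4))
  # unannotated transcripts are dropped with a message
  mp_partial <- term_mapping("gene", list(T1 = "G1", T2 = "G1", T3 = "G2"))
  expect_message(Zp <- build_incidence(ev, mp_partial), "dropped 1")
  expect_identical(Zp$dropped, "T4")
  expect_error(build_incidence(ev, term_mapping("gene", list(TX = "G9"))),
               "no overlap")
})

test_that("solve_mme reproduces the dense GLS/BLUP closed forms", {
  set.seed(401)
  worst <- 0
  for (r in 1:30) {
    inst <- rand_instance(sample(8:40, 1), sample(2:8, 1))
    s2x <- stats::runif(1, 0.2, 2)
    s2e <- stats::runif(1, 0.2, 2)
    res <- solve_mme(inst$y, inst$Z, inst$V,
                     list(sigma2_x = s2x, sigma2_e = s2e))
    orc <- oracle_gls_blup(as.numeric(inst$y), as.matrix(inst$Z$Z),
                           as.matrix(inst$V$matrix), s2x, s2e)
    worst <- max(worst, abs(res$mu_hat - orc$mu), max(abs(res$blup - orc$x)))
  }
  expect_lt(worst, 1e-8)
})

test_that("BLUPs obey the scalar shrinkage closed form when V = Z = I", {
  set.seed(402)
  y <- expression_vector(sprintf("T%02d", 1:25), stats::rnorm(25, 0.3))
  Z <- build_incidence(y, NULL)
  V <- cov_spec(Z$levels, diag(25))
  s2x <- 0.8
  s2e <- 0.5
  res <- solve_mme(y, Z, V, list(sigma2_x = s2x, sigma2_e = s2e))
  k <- s2x / (s2x + s2e)
  expect_equal(res$mu_hat, mean(y), tolerance = 1e-10)
  expect_equal(res$blup, k * (as.numeric(y) - res$mu_hat), tolerance = 1e-10)
  # sigma2_x -> 0: solutions collapse to zero, mu to the sample mean
  res0 <- solve_mme(y, Z, V, list(sigma2_x = 1e-12, sigma2_e = s2e))
  expect_lt(max(abs(res0$blup)), 1e-9)
  expect_equal(res0$mu_hat, mean(y), tolerance = 1e-8)
})

test_that("blocked and dense solves agree on nonsingular block-diagonal V", {
  set.seed(403)
  models <- nonsingular_gene_models(25, seed = 31)
  V <- assemble_block_diagonal(lapply(models, transcript_exon_similarity))
  expect_gt(min_eigenvalue(V), 1e-8)
  sim <- simulate_expression(V, NULL, 0.1, 0.4, 0.6, seed = 32)
  Z <- build_incidence(sim$y, NULL)
  est <- list(sigma2_x = 0.4, sigma2_e = 0.6)
  blocked <- solve_mme(sim$y, Z, V, est)
  dense <- solve_mme(sim$y, Z, cov_spec(V$labels, as.matrix(V$matrix)), est)
  expect_equal(blocked$mu_hat, dense$mu_hat, tolerance = 1e-8)
  expect_equal(blocked$blup, dense$blup, tolerance = 1e-8)
  expect_equal(blocked$pev, dense$pev, tolerance = 1e-8)
})

test_that("PEV equals the inverse-MME diagonal computed densely", {
  set.seed(404)
  inst <- rand_instance(20, 5)
  s2x <- 0.7
  s2e <- 1.1
  res <- solve_mme(inst$y, inst$Z, inst$V,
                   list(sigma2_x = s2x, sigma2_e = s2e))
  Zm <- as.matrix(inst$Z$Z)
  Vm <- as.matrix(inst$V$matrix)
  n <- nrow(Zm)
  lam <- s2e / s2x
  C <- rbind(cbind(n, t(rep(1, n)) %*% Zm),
             cbind(t(Zm) %*% rep(1, n), t(Zm) %*% Zm + lam * solve(Vm)))
  pev_dense <- s2e * diag(solve(C))[-1]
  expect_equal(res$pev, pev_dense, tolerance = 1e-8)
})

test_that("EM-REML maximizes the REML likelihood with a monotone trace", {
  set.seed(405)
  for (r in 1:8) {
    # enough levels that the REML optimum is interior, not at sigma2_x = 0
    inst <- rand_instance(sample(100:200, 1), sample(10:15, 1),
                          s2x = stats::runif(1, 0.5, 1.5),
                          s2e = stats::runif(1, 0.5, 1.5), mu = 0.2)
    est <- em_reml(inst$y, inst$Z, inst$V)
    expect_true(est$converged)
    expect_true(all(diff(est$loglik_trace) >= -1e-8))
    # trace values agree with the independent dense evaluation
    ll_dense <- reml_loglik(inst$y, inst$Z, inst$V, est$sigma2_x, est$sigma2_e)
    expect_equal(ll_dense, est$loglik_trace[est$n_iter], tolerance = 1e-8)
    opt <- oracle_reml_optim(inst$y, inst$Z, inst$V)
    expect_equal(est$sigma2_x, opt[1], tolerance = 1e-4)
    expect_equal(est$sigma2_e, opt[2], tolerance = 1e-4)
  }
})

test_that("a constant response gives the zero-variance boundary without error", {
  y <- expression_vector(c("a", "b", "c"), rep(1.5, 3))
  Z <- build_incidence(y, NULL)
  V <- cov_spec(Z$levels, diag(3))
  est <- em_reml(y, Z, V)
  expect_equal(est$sigma2_x, 0)
  expect_equal(est$sigma2_e, 0)
  expect_true(est$converged)
})

test_that("REML log-likelihood has the expected closed form and invariances", {
  # sigma2_x = 0, V = Z = I reduces to iid-normal REML
  y <- expression_vector(c("a", "b"), c(0.4, 1.2))
  Z <- build_incidence(y, NULL)
  V <- cov_spec(Z$levels, diag(2))
  s2e <- 0.9
  n <- 2
  r <- as.numeric(y) - mean(y)
  ll_manual <- -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2e) +
                         log(n) + sum(r^2) / s2e)
  expect_equal(reml_loglik(y, Z, V, 0, s2e), ll_manual, tolerance = 1e-12)

  # translation invariance: adding a constant to y changes nothing
  set.seed(406)
  inst <- rand_instance(15, 4)
  y2 <- expression_vector(names(inst$y), as.numeric(inst$y) + 3.7)
  expect_equal(reml_loglik(inst$y, inst$Z, inst$V, 0.5, 0.8),
               reml_loglik(y2, inst$Z, inst$V, 0.5, 0.8), tolerance = 1e-9)
})

test_that("standardization uses one empirical SD and two-sided normal tails", {
  set.seed(407)
  inst <- rand_instance(40, 10, s2x = 1, s2e = 1)
  res <- standardize_and_test(
    solve_mme(inst$y, inst$Z, inst$V, list(sigma2_x = 1, sigma2_e = 1)))
  expect_equal(res$z, (res$blup - mean(res$blup)) / stats::sd(res$blup))
  expect_equal(res$p, 2 * stats::pnorm(abs(res$z), lower.tail = FALSE))
  # constant effect-to-z ratio (up to the centring shift)
  ratio <- (res$blup - mean(res$blup)) / res$z
  expect_lt(diff(range(ratio[is.finite(ratio)])), 1e-10)
  expect_true(all(res$p > 0 & res$p <= 1))
  # reference quantiles of the standard normal
  expect_equal(2 * stats::pnorm(6.23, lower.tail = FALSE), 4.7e-10,
               tolerance = 0.05)
  expect_equal(2 * stats::pnorm(1.959964, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
})

test_that("variance proportions report the share of the sample variance", {
  y <- expression_vector(paste0("t", 1:10), stats::rnorm(10))
  s2y <- stats::var(as.numeric(y))
  expect_equal(variance_proportions(list(sigma2_x = s2y, sigma2_e = 1), y), 100)
  expect_equal(variance_proportions(list(sigma2_x = 0, sigma2_e = 1), y), 0)
  expect_equal(variance_proportions(list(sigma2_x = 1, sigma2_e = 3), y,
                                    denominator = "component_sum"), 25)
})

test_that("fit_model is deterministic and recovers strong true effects", {
  set.seed(408)
  models <- simulate_gene_models(120, c(2L, 4L), c(4L, 10L), 0.7, seed = 51)
  V <- assemble_block_diagonal(lapply(models, transcript_exon_similarity))
  sim <- simulate_expression(V, NULL, 0.1, sigma2_x = 1, sigma2_e = 1,
                             seed = 52)
  f1 <- fit_model(sim$y, NULL, V)
  f2 <- fit_model(sim$y, NULL, V)
  expect_identical(f1$effects$blup, f2$effects$blup)
  expect_identical(f1$estimates$sigma2_x, f2$estimates$sigma2_x)
  # M2 configuration: gene mapping plus identity covariance runs end to end
  tx2gene <- tx2gene_map(models)
  mp <- term_mapping("gene", as.list(tx2gene))
  Vg <- identity_covariance(sort(unique(unname(tx2gene))))
  fg <- fit_model(sim$y, mp, Vg)
  expect_length(fg$effects$blup, length(Vg$labels))
  expect_true(fg$estimates$converged)
})

test_that("BLUPs rank true level effects highly when levels pool observations", {
  # gene-level structure: ~2000 transcripts over ~500 genes, half the
  # observation variance from the random effect
  models <- simulate_gene_models(500, c(3L, 5L), c(3L, 8L), 0.7, seed = 53)
  tx2gene <- tx2gene_map(models)
  mp <- term_mapping("gene", as.list(tx2gene), tx2gene = tx2gene)
  V <- identity_covariance(sort(unique(unname(tx2gene))))
  ev <- expression_vector(names(tx2gene), numeric(length(tx2gene)))
  Z <- build_incidence(ev, mp)
  ord <- match(V$labels, Z$levels)
  Z$Z <- Z$Z[, ord, drop = FALSE]
  Z$levels <- V$labels
  sim <- simulate_expression(V, Z, mu = 0.1, sigma2_x = 1, sigma2_e = 1,
                             seed = 54)
  fit <- fit_model(sim$y, mp, V)
  rc <- stats::cor(sim$truth$x_true[fit$effects$labels], fit$effects$blup,
                   method = "spearman")
  expect_gt(rc, 0.8)
})
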