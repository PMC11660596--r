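test_that("identity kinship reduces the mixed-model scan to OLS", {
  set.seed(101)
  n <- 120
  Q <- cbind(1, rbinom(n, 1, 0.5))
  y <- drop(Q %*% c(10, 3)) + rnorm(n)
  fit <- reml_fit(y, Q, diag(n))
  dose <- matrix(rbinom(5 * n, 2, 0.3), nrow = 5)
  tab <- marker_scan(fit, dose)
  for (j in 1:5) {
    ols <- summary(lm(y ~ Q[, 2] + dose[j, ]))$coefficients[3, ]
    expect_equal(tab$beta[j], unname(ols[1]), tolerance = 1e-6)
    expect_equal(tab$p[j], unname(ols[4]), tolerance = 1e-6)
  }
  # sigma_g2 + sigma_e2 approximately the residual variance
  s2 <- summary(lm(y ~ Q[, 2]))$sigma^2
  expect_equal(fit$sigma_g2 + fit$sigma_e2, s2, tolerance = 0.02)
})

test_that("REML recovers planted variance components", {
  set.seed(202)
  n <- 300
  z <- matrix(rbinom(n * 150, 2, 0.5), n, 150)
  z <- scale(z)
  K <- tcrossprod(z) / 150
  ev <- eigen(K, symmetric = TRUE)
  est <- replicate(10, {
    g <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(n)))
    y <- 5 + g + rnorm(n)
    fit <- reml_fit(y, matrix(1, n, 1), K)
    c(fit$sigma_g2, fit$sigma_e2)
  })
  expect_equal(mean(est[1, ]), 1, tolerance = 0.25)
  expect_equal(mean(est[2, ]), 1, tolerance = 0.25)
  expect_error(reml_fit(rep(1, 50), matrix(1, 50, 1), diag(50)),
               "zero variance")
})

test_that("null phenotypes give uniform scan p-values", {
  set.seed(303)
  n <- 200
  sim_dose <- matrix(rbinom(2000 * n, 2, 0.3), nrow = 2000)
  Q <- matrix(1, n, 1)
  y <- rnorm(n) # permuted / independent phenotype
  fit <- reml_fit(y, Q, diag(n))
  tab <- marker_scan(fit, sim_dose)
  ks <- suppressWarnings(ks.test(tab$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # monomorphic marker -> NA row; out-of-range dosage -> error
  mono <- matrix(1, 1, n)
  expect_true(is.na(marker_scan(fit, mono)$p))
  expect_error(marker_scan(fit, matrix(3, 1, n)), "dosage")
})

test_that("planted marker attains the genome-wide minimum p", {
  set.seed(404)
  hits <- replicate(5, {
    n <- 200
    dose <- matrix(rbinom(200 * n, 2, 0.4), nrow = 200)
    y <- 0.8 * dose[57, ] + rnorm(n)
    fit <- reml_fit(y, matrix(1, n, 1), diag(n))
    which.min(marker_scan(fit, dose)$p)
  })
  expect_gte(sum(hits == 57), 4)
})

test_that("block LRT is a valid nested-model test", {
  sim <- small_sim()
  hbs_t <- ailhap:::subset_blocks_to(sim$hbs, sim$f9_ids)
  kin <- gamma_to_h(haplotype_gamma(hbs_t), sim$f9_ids)
  y <- sim$phen$trait
  Q <- model.matrix(~ sex + batch, sim$phen)
  cache <- assoc_cache(y, Q, kin)
  for (b in c(1, 10, 25)) {
    r <- block_lrt(cache, hbs_t, b)
    if (!is.na(r$p)) {
      expect_gte(r$stat, 0)
      expect_equal(r$df, r$n_levels - 1L)
    }
  }
  # a block where everyone carries the same combination: LRT = 0, p = 1
  hbs1 <- hbs_t
  hbs1$assign[, 1] <- 1L
  r1 <- block_lrt(cache, hbs1, 1)
  expect_equal(r1$stat, 0)
  expect_equal(r1$p, 1)
  # pooling that collapses to a single level is reported untestable
  hbs2 <- hbs_t
  set.seed(1)
  hbs2$assign[, 2] <- sample(1:10, nrow(hbs2$assign), replace = TRUE)
  r2 <- block_lrt(cache, hbs2, 2, min_count = 1e6)
  expect_true(is.na(r2$p))
  expect_match(r2$reason, "pooling")
})

test_that("block LRT matches a direct ML optimizer on toy data", {
  set.seed(505)
  n <- 40
  d <- make_dataset(list(matrix(rbinom(2 * n * 4, 1, 0.5), 2 * n, 4)))
  hbs <- build_blocks(d$variants, d$genotypes, 2)
  kin <- gamma_to_h(haplotype_gamma(hbs), d$genotypes$samples)
  kin[] <- unclass(kin) + diag(1e-6, n) # keep the toy kinship comfortably PD
  y <- rnorm(n, 10, 2)
  Q <- matrix(1, n, 1)
  cache <- assoc_cache(y, Q, kin)
  r <- block_lrt(cache, hbs, 1, min_count = 2)
  # independent oracle: direct ML over (log sg2, log se2) with dense algebra
  direct_ml <- function(X) {
    nll <- function(par) {
      V <- exp(par[1]) * unclass(kin) + exp(par[2]) * diag(n)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      ld <- 2 * sum(log(diag(ch)))
      Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
      Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
      beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
      r <- y - X %*% beta
      Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
      0.5 * (n * log(2 * pi) + ld + sum(r * Vi_r))
    }
    o <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
    -o$value
  }
  combo <- ailhap:::block_combos(hbs, 1, 2)
  Xalt <- cbind(Q, model.matrix(~ combo)[, -1, drop = FALSE])
  lrt_direct <- 2 * (direct_ml(Xalt) - direct_ml(Q))
  expect_equal(r$stat, lrt_direct, tolerance = 1e-4)
})

test_that("planted block effects reach chi-square significance", {
  set.seed(606)
  n <- 300
  d <- make_dataset(list(matrix(rbinom(2 * n * 2, 1, 0.5), 2 * n, 2)))
  hbs <- build_blocks(d$variants, d$genotypes, 2)
  combo <- ailhap:::block_combos(hbs, 1, 5)
  y <- rnorm(n)
  y[combo == levels(combo)[1]] <- y[combo == levels(combo)[1]] + 3
  cache <- assoc_cache(y, matrix(1, n, 1), diag(n))
  r <- block_lrt(cache, hbs, 1)
  expect_lt(r$p, 1e-6)
})

test_that("BH q-values and region merging follow the textbook rules", {
  tbl <- data.frame(chrom = "chr1", chrom_block = 1:3,
                    start_bp = c(1, 101, 201), end_bp = c(100, 200, 300),
                    p = c(0.001, 0.5, 0.9))
  out <- fdr_and_regions(tbl, q_threshold = 0.05)
  expect_equal(out$table$q, c(0.003, 0.75, 0.9))
  expect_true(all(out$table$q >= out$table$p))
  # all p = 1 -> nothing significant
  tbl1 <- transform(tbl, p = 1)
  expect_equal(nrow(fdr_and_regions(tbl1)$regions), 0L)
  # contiguous significant blocks merge into one region
  tbl2 <- data.frame(chrom = "chr1", chrom_block = 21:33,
                     start_bp = (21:33) * 100, end_bp = (21:33) * 100 + 99,
                     p = 1e-8)
  reg <- fdr_and_regions(tbl2)$regions
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 21)
  expect_equal(reg$end, 33)
  expect_equal(reg$n, 13)
})

test_that("marker-scan type-I error is calibrated at the null", {
  set.seed(707)
  n <- 150
  m <- 400
  rej <- replicate(8, {
    z <- matrix(rbinom(n * 100, 2, 0.5), n, 100)
    K <- tcrossprod(scale(z)) / 100
    ev <- eigen(K, symmetric = TRUE)
    g <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(n)))
    y <- g + rnorm(n)
    dose <- matrix(rbinom(m * n, 2, 0.3), nrow = m)
    fit <- reml_fit(y, matrix(1, n, 1), K)
    mean(marker_scan(fit, dose)$p < 0.05, na.rm = TRUE)
  })
  se <- sqrt(0.05 * 0.95 / (8 * m))
  expect_lt(abs(mean(rej) - 0.05), 3 * se + 0.005)
})
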