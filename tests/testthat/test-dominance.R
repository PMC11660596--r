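test_that("phenotype correction removes sex and batch means", {
  pt <- data.frame(id = paste0("S", 1:8),
                   trait = c(100, 110, 90, 100, 200, 210, 190, 200),
                   sex = rep(c("F", "M"), each = 4),
                   batch = "b1")
  r <- correct_phenotype(pt)
  expect_equal(unname(r), pt$trait - rep(c(100, 200), each = 4))
  expect_lt(abs(sum(r)), 1e-9)
  # constant trait -> all-zero residuals
  pt$trait <- 5
  expect_true(all(abs(correct_phenotype(pt)) < 1e-12))
  # residuals orthogonal to the design
  set.seed(41)
  pt2 <- data.frame(id = paste0("S", 1:60), trait = rnorm(60),
                    sex = sample(c("F", "M"), 60, TRUE),
                    batch = sample(c("b1", "b2", "b3"), 60, TRUE))
  r2 <- correct_phenotype(pt2)
  X <- model.matrix(~ sex + batch, pt2)
  expect_true(all(abs(crossprod(X, r2)) < 1e-8))
})

test_that("Kruskal-Wallis matches the hand-ranked oracle", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  cl <- rep(1:3, each = 3)
  kw <- kruskal_wallis(v, cl, min_class = 3)
  # hand computation: H = 12/(N(N+1)) * sum(R_j^2 / n_j) - 3(N+1)
  rs <- tapply(rank(v), cl, sum)
  H_hand <- 12 / (9 * 10) * sum(rs^2 / 3) - 3 * 10
  expect_equal(kw$H, H_hand)
  expect_equal(kw$H, 7.2)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-6)
  # equal rank sums -> H = 0
  kw0 <- kruskal_wallis(c(1, 2, 3, 4, 1, 2, 3, 4), rep(1:2, each = 4),
                        min_class = 4)
  expect_equal(kw0$H, 0)
  # class below the minimum size -> untestable with a reason
  kws <- kruskal_wallis(v, cl, min_class = 5)
  expect_true(is.na(kws$p))
  expect_match(kws$reason, "minimum")
})

test_that("Kruskal-Wallis holds its size under the null", {
  set.seed(42)
  p <- replicate(100, {
    kruskal_wallis(rnorm(90), rep(1:3, each = 30))$p
  })
  expect_gte(mean(p > 0.05), 0.90)
})

test_that("Steel-Dwass all-pairs test is calibrated and powered", {
  set.seed(43)
  # null: all pairwise p > 0.05 in most replicates
  clear <- replicate(100, {
    pp <- steel_dwass(rnorm(90), rep(1:3, each = 30))
    all(pp[upper.tri(pp)] > 0.05)
  })
  expect_gte(mean(clear), 0.90)
  # power: one class shifted by 5 SDs
  v <- c(rnorm(30), rnorm(30), rnorm(30, 5))
  pp <- steel_dwass(v, rep(1:3, each = 30))
  expect_lt(pp["3", "1"], 1e-4)
  expect_lt(pp["3", "2"], 1e-4)
  expect_gt(pp["1", "2"], 0.05)
})

test_that("permutation mode agrees with the asymptotic approximation", {
  set.seed(44)
  v <- c(rnorm(8), rnorm(8, 1.2), rnorm(8))
  cl <- rep(1:3, each = 8)
  pa <- steel_dwass(v, cl, mode = "asymptotic")
  pp <- steel_dwass(v, cl, mode = "permutation", n_perm = 4000)
  for (i in 1:2) for (j in (i + 1):3) {
    # tight agreement where decisions are made; looser deep in the null
    tol <- if (pa[i, j] < 0.2) 0.02 else 0.06
    expect_lt(abs(pa[i, j] - pp[i, j]), tol)
  }
})

test_that("dominance labels follow the high-/mid-parent definitions", {
  mk_p <- function(p10, p12) {
    m <- matrix(NA_real_, 3, 3, dimnames = list(0:2, 0:2))
    m["1", "0"] <- m["0", "1"] <- p10
    m["1", "2"] <- m["2", "1"] <- p12
    m
  }
  # het median above both homozygotes, both pairs significant
  expect_equal(label_dominance(c("0" = 10, "1" = 50, "2" = 20),
                               mk_p(0.01, 0.01)), "high-parent")
  # het exactly at the homozygote midpoint: not mid-parent (strict)
  expect_equal(label_dominance(c("0" = 10, "1" = 15, "2" = 20),
                               mk_p(0.01, 0.01)), "none")
  # het above midpoint, one heterozygote comparison significant
  expect_equal(label_dominance(c("0" = 10, "1" = 18, "2" = 20),
                               mk_p(0.01, 0.5)), "mid-parent")
  # significance missing -> no label
  expect_equal(label_dominance(c("0" = 10, "1" = 50, "2" = 20),
                               mk_p(0.5, 0.5)), "none")
  # a high-parent call always satisfies the mid-parent conditions
  set.seed(45)
  for (i in 1:50) {
    med <- setNames(runif(3, 0, 10), c("0", "1", "2"))
    pm <- mk_p(runif(1), runif(1))
    lab <- label_dominance(med, pm)
    if (lab == "high-parent") {
      expect_gt(med[["1"]], (med[["0"]] + med[["2"]]) / 2)
      expect_true(pm["1", "0"] < 0.05 || pm["1", "2"] < 0.05)
    }
  }
})

test_that("dominance scan detects planted overdominance and controls the null", {
  set.seed(46)
  cfg <- sim_config(seed = 77,
                    chromosomes = list(c(snps = 100, cm = 100),
                                       c(snps = 100, cm = 100)),
                    n_intermediate = 100, n_final = 400,
                    trait = list(dominance = list(list(block = 12,
                      het_bonus = 90)), residual_var = 3600))
  sim <- simulate_ail(cfg)
  yc <- correct_phenotype(sim$phen)
  dom <- dominance_scan(yc, sim$truth_code, sim$hbs$blocks)
  expect_equal(dom$label[12], "high-parent")
  # nesting invariant on every labeled block
  hp <- which(dom$label == "high-parent")
  for (b in hp) {
    expect_gt(dom$med01[b], (dom$med00[b] + dom$med11[b]) / 2)
  }
  # a purely additive architecture yields high-parent labels at <= FDR rate
  cfg0 <- sim_config(seed = 78,
                     chromosomes = list(c(snps = 100, cm = 100),
                                        c(snps = 100, cm = 100)),
                     n_intermediate = 100, n_final = 400,
                     trait = list(causal = list(list(block = 12,
                       by_origin = c(0, 40))), residual_var = 3600))
  sim0 <- simulate_ail(cfg0)
  dom0 <- dominance_scan(correct_phenotype(sim0$phen), sim0$truth_code,
                         sim0$hbs$blocks)
  n_tested <- sum(dom0$label != "untested")
  expect_lte(sum(dom0$label == "high-parent"), max(1, 0.05 * n_tested))
})
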