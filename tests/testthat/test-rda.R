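test_that("spatial polynomial basis is orthogonal and rank-preserving", {
  set.seed(1)
  lon <- runif(60, -10, 50); lat <- runif(60, 30, 70)
  sp <- standardize_and_polynomials(lon, lat)
  expect_equal(ncol(sp), 9)
  expect_equal(colnames(sp)[c(1, 2, 7)], c("x", "y", "x^2y"))
  cp <- crossprod(sp)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_lt(max(abs(colMeans(sp))), 1e-10)
  expect_equal(unname(apply(sp, 2, sd)), rep(1, 9), tolerance = 1e-10)
  # grid symmetric about 0: raw x and x^3 correlated, basis orthogonal
  g <- expand.grid(x = seq(-2, 2, length.out = 6), y = seq(-2, 2, length.out = 6))
  spg <- standardize_and_polynomials(g$x, g$y)
  expect_gt(abs(cor(scale(g$x)[, 1], scale(g$x)[, 1]^3)), 0.9)
  expect_lt(abs(sum(spg[, "x"] * spg[, "x^3"])), 1e-8)
  # rank preservation: raw monomials reproduced exactly from the basis
  zx <- scale(lon)[, 1]; zy <- scale(lat)[, 1]
  raw <- cbind(zx, zy, zx^2, zx * zy, zy^2, zx^3, zx^2 * zy, zx * zy^2, zy^3)
  fitted <- cbind(1, sp) %*% qr.coef(qr(cbind(1, sp)), raw)
  expect_equal(fitted, raw, tolerance = 1e-8, ignore_attr = TRUE)
  # degenerate coordinate: degenerate columns dropped with warning
  w <- capture_warnings(spd <- standardize_and_polynomials(rep(1, 20), rnorm(20)))
  expect_true(any(grepl("degenerate", w)))
  expect_lt(ncol(spd), 9)
})

test_that("correlation screen flags strong pairs but drops nothing", {
  set.seed(2)
  a <- rnorm(50); cl <- cbind(v1 = a, v2 = a, v3 = rnorm(50), v4 = rnorm(50))
  sc <- correlation_screen(cl, 0.5)
  expect_true(any(sc$flagged$var1 == "v1" & sc$flagged$var2 == "v2"))
  expect_equal(sc$flagged$r[1], 1)
  expect_equal(sc$retained, colnames(cl))
  sc2 <- correlation_screen(cl, 1.1)
  expect_equal(nrow(sc2$flagged), 0)
})

test_that("partial RDA decomposes variance exactly and hits its limits", {
  set.seed(3)
  n <- 50
  Y <- matrix(rnorm(n * 3), n)
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("x", 1:4)))
  Z <- rbinom(n, 1, 0.5)
  fit <- partial_rda(Y, X, Z)
  expect_equal(sum(fit$components), 100, tolerance = 1e-10)
  expect_equal(sum(fit$var[1:3]), unname(fit$var["total"]), tolerance = 1e-10)
  # Y exactly linear in X, no condition: constrained 100%
  Y2 <- X %*% matrix(rnorm(12), 4)
  f2 <- partial_rda(Y2, X, NULL)
  expect_equal(unname(f2$components["constrained"]), 100, tolerance = 1e-8)
  expect_equal(unname(f2$components["residual"]), 0, tolerance = 1e-8)
  # X orthogonal to Y by construction: constrained ~ 0
  Y3 <- resid_on_test <- qr.resid(qr(cbind(1, X)), Y)
  f3 <- partial_rda(Y3, X, NULL)
  expect_lt(unname(f3$components["constrained"]), 1e-8)
  # empty X: constrained 0; empty condition equals plain RDA
  f4 <- partial_rda(Y, NULL, Z)
  expect_equal(unname(f4$components["constrained"]), 0)
  expect_equal(partial_rda(Y, X, NULL)$components,
               partial_rda(Y, X, matrix(nrow = n, ncol = 0))$components)
})

test_that("partial RDA agrees with the vegan oracle", {
  set.seed(4)
  n <- 60
  Y <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("a", 1:3)))
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("x", 1:3)))
  Z <- rbinom(n, 1, 0.5)
  # plain RDA
  fit <- partial_rda(Y, X, NULL)
  v <- vegan::rda(Y ~ x1 + x2 + x3, data = as.data.frame(X))
  expect_equal(unname(fit$components["constrained"]) / 100,
               unname(v$CCA$tot.chi / v$tot.chi), tolerance = 1e-8)
  expect_equal(fit$axes$variance, unname(v$CCA$eig), tolerance = 1e-8)
  # partial RDA with condition
  dfv <- data.frame(X, z = Z)
  fitp <- partial_rda(Y, X, Z)
  vp <- vegan::rda(Y ~ x1 + x2 + x3 + Condition(z), data = dfv)
  expect_equal(unname(fitp$components["conditional"]) / 100,
               unname(vp$pCCA$tot.chi / vp$tot.chi), tolerance = 1e-8)
  expect_equal(unname(fitp$components["constrained"]) / 100,
               unname(vp$CCA$tot.chi / vp$tot.chi), tolerance = 1e-8)
  # whole-model pseudo-F against vegan's
  av <- vegan::anova.cca(vp, permutations = 9)
  expect_equal(unname(fitp$F_whole["F"]), av$F[1], tolerance = 1e-6)
})

test_that("pseudo-F matches brute-force recomputation from the variance table", {
  set.seed(5)
  Y <- matrix(rnorm(40 * 2), 40)
  X <- matrix(rnorm(40 * 3), 40)
  fit <- partial_rda(Y, X, NULL)
  F_brute <- (fit$fit_ss / fit$df_model) / (fit$resid_ss / fit$df_resid)
  expect_equal(unname(pseudo_F(fit)["F"]), F_brute)
  # constrained == residual with equal dfs -> F = 1 (constructed)
  expect_equal(unname(pseudo_F(fit)["df1"]), 3)
  # residual -> 0 flagged as infinite
  Yp <- X %*% matrix(rnorm(6), 3)
  expect_true(is.infinite(partial_rda(Yp, X, NULL)$F_whole[["F"]]))
})

test_that("permutation test: perfect fit, reproducibility, calibration", {
  set.seed(6)
  n <- 40
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x1", "x2")))
  Yp <- X %*% matrix(rnorm(4), 2)
  pt <- permutation_test(Yp, X, NULL, n_perm = 99, seed = 1)
  expect_equal(pt$p, 1 / 100)
  expect_identical(pt$p, permutation_test(Yp, X, NULL, n_perm = 99, seed = 1)$p)
  # type-I calibration at alpha = 0.01 over 300 null datasets
  set.seed(7)
  rejections <- 0
  for (i in 1:300) {
    Y0 <- matrix(rnorm(30 * 2), 30)
    X0 <- matrix(rnorm(30 * 2), 30)
    Z0 <- rbinom(30, 1, 0.5)
    p <- permutation_test(Y0, X0, Z0, n_perm = 199, seed = i)$p
    if (p <= 0.01) rejections <- rejections + 1
  }
  band <- qbinom(c(0.025, 0.975), 300, 0.01)
  expect_gte(rejections, band[1])
  expect_lte(rejections, band[2] + 1)
})

test_that("forward selection: planted term found, alpha=1 exhausts, null empty", {
  set.seed(8)
  n <- 80
  lon <- runif(n, 0, 40); lat <- runif(n, 30, 70)
  sp <- standardize_and_polynomials(lon, lat)
  clim <- scale(matrix(rnorm(n * 2), n, dimnames = list(NULL, c("b1", "b2"))))
  cand <- candidate_terms(sp, clim)
  # planted strong y effect
  hits <- 0
  for (i in 1:20) {
    Y <- outer(sp[, "y"], c(1, 0.5)) + matrix(rnorm(n * 2, sd = 0.4), n)
    sel <- forward_select(Y, cand, NULL, alpha = 0.01, n_perm = 199,
                          seed = 100 + i)
    if (nrow(sel) > 0 && sel$term[1] == "y") hits <- hits + 1
  }
  expect_gte(hits, 19)
  # alpha = 1: every candidate eventually enters
  Yr <- matrix(rnorm(n * 2), n)
  sel_all <- forward_select(Yr, cand[, 1:5], NULL, alpha = 1, n_perm = 19,
                            seed = 9)
  expect_setequal(sel_all$term, colnames(cand)[1:5])
  # deterministic under fixed seed
  s1 <- forward_select(Yr, cand[, 1:6], NULL, alpha = 0.05, n_perm = 99, seed = 3)
  s2 <- forward_select(Yr, cand[, 1:6], NULL, alpha = 0.05, n_perm = 99, seed = 3)
  expect_identical(s1, s2)
})

test_that("VIF: orthogonal design, aliased column, and lm oracle", {
  set.seed(9)
  Q <- poly(1:30, 3)  # centered orthonormal columns
  colnames(Q) <- paste0("q", 1:3)
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)
  dup <- cbind(Q, q4 = Q[, 1])
  expect_true(is.infinite(vif(dup)[["q4"]]))
  # correlated 3-column toy against an lm-based oracle
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- X[, 1] * 0.8 + X[, 2] * 0.3
  v <- vif(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-9)
  }
})

test_that("axis tests: one-dimensional signal loads on axis 1, shares sum to 100", {
  set.seed(10)
  n <- 60
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("x", 1:3)))
  Y <- outer(X %*% c(1, 1, 0), c(2, 1, 0.5))[, 1, ] + matrix(rnorm(n * 3, sd = 0.1), n)
  at <- axis_tests(Y, X, NULL, n_perm = 99, seed = 1)
  expect_equal(sum(at$pct_constrained), 100, tolerance = 1e-8)
  expect_gt(at$pct_constrained[1], 95)
  expect_lt(at$p[1], 0.05)
  # two planted orthogonal signals: two axes carry the constrained variance
  Y2 <- outer(X[, 1], c(1, 0, 0)) + outer(X[, 2], c(0, 1, 0)) +
    matrix(rnorm(n * 3, sd = 0.05), n)
  at2 <- axis_tests(Y2, X, NULL, n_perm = 99, seed = 2)
  expect_gt(sum(at2$pct_constrained[1:2]), 99)
  expect_true(all(at2$p[1:2] < 0.05))
})

test_that("sequential term table reconstitutes the full decomposition", {
  set.seed(11)
  n <- 50
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("t1", "t2", "t3")))
  Y <- X %*% matrix(rnorm(6), 3) + matrix(rnorm(n * 2, sd = 0.5), n)
  Z <- rbinom(n, 1, 0.5)
  tab <- rda_term_table(Y, X, Z, n_perm = 49, seed = 1)
  fit <- partial_rda(Y, X, Z)
  expect_equal(sum(tab$variance[1:3]), unname(fit$var["constrained"]),
               tolerance = 1e-10)
  expect_equal(tab$pct_total[tab$term == "total"], 100)
  expect_equal(sum(tab$pct_total[1:5]) + tab$pct_total[6], 200, tolerance = 1e-8)
  expect_equal(tab$variance[tab$term == "residual"],
               unname(fit$var["residual"]), tolerance = 1e-10)
})

test_that("landscape generator with planted partition is recovered by partial RDA", {
  spec <- synthetic_spec(1)
  spec$landscape$n <- 100
  l1 <- make_landscape(spec)
  sp1 <- standardize_and_polynomials(l1$coords$lon, l1$coords$lat)
  f1 <- partial_rda(l1$Y, sp1, l1$condition)
  spec$landscape$n <- 400
  l4 <- make_landscape(spec)
  sp4 <- standardize_and_polynomials(l4$coords$lon, l4$coords$lat)
  f4 <- partial_rda(l4$Y, sp4, l4$condition)
  # estimates converge toward the planted values as n grows
  err1 <- abs(unname(f1$components[c("conditional", "constrained")]) - c(25, 25))
  err4 <- abs(unname(f4$components[c("conditional", "constrained")]) - c(25, 25))
  expect_lt(max(err4), 5)
  expect_lte(sum(err4), sum(err1) + 1)
  # zero noise: residual ~ 0
  spec$landscape$fractions <- c(condition = 0.5, spatial = 0.5, climate = 0,
                                noise = 0)
  spec$landscape$n <- 100
  l0 <- make_landscape(spec)
  sp0 <- standardize_and_polynomials(l0$coords$lon, l0$coords$lat)
  f0 <- partial_rda(l0$Y, sp0, l0$condition)
  expect_lt(unname(f0$components["residual"]), 1)
})
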