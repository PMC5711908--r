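test_that("AFLP matrix io round-trips and validates entries", {
  set.seed(1)
  m <- matrix(rbinom(40, 1, 0.5), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("L", 1:10)))
  obj <- toy_aflp(m, replicates = data.frame(sample_id = "s1",
                                             replicate_id = "s2"))
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.csv"); md <- file.path(dir, "m.tsv")
  rp <- file.path(dir, "r.tsv")
  write_aflp(obj, mp, md, rp)
  back <- read_aflp(mp, md, rp)
  expect_identical(back$data, obj$data)
  expect_equal(back$replicates$replicate_id, "s2")
  # non-binary entry rejected
  m2 <- m; m2[1, 1] <- 2L
  expect_error(toy_aflp(m2), "0/1/NA")
  # orphan replicate id rejected
  expect_error(toy_aflp(m, replicates = data.frame(sample_id = "s1",
                                                   replicate_id = "zz")),
               "replicate ids")
})

test_that("synthetic AFLP dataset loads with study-scale dimensions", {
  af <- make_aflp_dataset(synthetic_spec(2))
  expect_equal(ncol(af$aflp$data), 404)
  expect_gte(nrow(af$aflp$data), 134)
  expect_true(all(af$aflp$data %in% c(0L, 1L)))
  expect_true(all(unlist(af$aflp$replicates) %in% rownames(af$aflp$data)))
})

test_that("replicate error rate: identical, hand-counted and simulated", {
  m <- matrix(0L, 4, 10, dimnames = list(paste0("s", 1:4), paste0("L", 1:10)))
  m[2, ] <- m[1, ]                 # identical pair
  m[4, ] <- m[3, ]; m[4, 1] <- 1L  # one mismatch
  reps <- data.frame(sample_id = c("s1", "s3"), replicate_id = c("s2", "s4"))
  expect_equal(replicate_error_rate(toy_aflp(m[1:2, ],
                                             replicates = reps[1, ])), 0)
  # 2 pairs x 10 loci with 1 and 3 mismatches -> 4/20
  m[4, 2:3] <- 1L
  m[2, 1] <- 1L
  expect_equal(replicate_error_rate(toy_aflp(m, replicates = reps)), 4 / 20)
  # binomial flip simulation: 500 pairs x 400 loci at rate 0.011
  set.seed(10)
  base <- matrix(rbinom(500 * 400, 1, 0.4), 500, 400)
  flip <- matrix(rbinom(500 * 400, 1, 0.011), 500, 400)
  dup <- abs(base - flip)
  data <- rbind(base, dup)
  rownames(data) <- c(paste0("a", 1:500), paste0("b", 1:500))
  colnames(data) <- paste0("L", 1:400)
  obj <- toy_aflp(data, replicates = data.frame(sample_id = paste0("a", 1:500),
                                                replicate_id = paste0("b", 1:500)))
  expect_equal(replicate_error_rate(obj), 0.011, tolerance = 0.003 / 0.011)
})

test_that("replicate error estimator is unbiased over repeated simulations", {
  set.seed(77)
  est <- replicate(200, {
    base <- matrix(rbinom(20 * 100, 1, 0.5), 20, 100)
    flip <- matrix(rbinom(20 * 100, 1, 0.02), 20, 100)
    data <- rbind(base, abs(base - flip))
    rownames(data) <- c(paste0("a", 1:20), paste0("b", 1:20))
    colnames(data) <- paste0("L", 1:100)
    replicate_error_rate(toy_aflp(data,
      replicates = data.frame(sample_id = paste0("a", 1:20),
                              replicate_id = paste0("b", 1:20))))
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.02), 2 * se + 1e-6)
})

test_that("fragment counts are row sums over scored loci", {
  m <- rbind(s1 = c(1L, 0L, 1L, NA), s2 = c(0L, 0L, 0L, 0L),
             s3 = c(1L, 1L, 1L, 1L))
  colnames(m) <- paste0("L", 1:4)
  fc <- fragment_counts(toy_aflp(m))
  expect_equal(unname(fc), c(2, 0, 4))
})

test_that("Brown-Forsythe equals ANOVA on |x - median| (oracle) and car", {
  set.seed(3)
  g1 <- rnorm(15, sd = 1); g2 <- rnorm(20, sd = 3); g3 <- rnorm(10, sd = 2)
  bf <- brown_forsythe(list(g1, g2, g3))
  # brute-force oracle
  z <- c(abs(g1 - median(g1)), abs(g2 - median(g2)), abs(g3 - median(g3)))
  f <- factor(rep(1:3, c(15, 20, 10)))
  zg <- split(z, f)
  k <- 3; N <- 45
  ssb <- sum(sapply(zg, function(v) length(v) * (mean(v) - mean(z))^2))
  ssw <- sum(sapply(zg, function(v) sum((v - mean(v))^2)))
  F_oracle <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(bf$F, F_oracle, tolerance = 1e-9)
  expect_equal(bf$df, c(2, 42))
  lev <- car::leveneTest(c(g1, g2, g3), f, center = median)
  expect_equal(bf$F, lev$`F value`[1], tolerance = 1e-9)
  expect_equal(bf$p, lev$`Pr(>F)`[1], tolerance = 1e-9)
  # identical spread: F near zero
  same <- brown_forsythe(list(c(1, 2, 3, 4), c(11, 12, 13, 14)))
  expect_lt(same$F, 1e-20)
})

test_that("Brown-Forsythe p-values are calibrated under label permutation", {
  set.seed(21)
  x <- rnorm(40)
  ps <- replicate(500, {
    g <- sample(rep(1:2, 20))
    brown_forsythe(x, g)$p
  })
  expect_equal(mean(ps < 0.1), 0.1, tolerance = 0.5)
  expect_gt(mean(ps), 0.35)  # roughly uniform, mean near 0.5
})

test_that("degradation screening flags old herbarium material", {
  set.seed(12)
  sig <- 0
  spec <- synthetic_spec(1)
  spec$aflp$degradation_slope <- 0.006   # planted effect size for the power check
  for (i in 1:30) {
    af <- make_aflp_dataset(spec, seed = 500 + i)
    m <- af$aflp
    bf <- brown_forsythe(fragment_counts(m), m$meta$year >= 2003)
    if (bf$p < 0.001) sig <- sig + 1
  }
  expect_gte(sig, 27)
})

test_that("fragment filter removes band-count outliers and is idempotent", {
  set.seed(4)
  # every sample carries 24-26 bands: all inside the reference band
  m <- t(replicate(30, sample(rep(c(1L, 0L), 25))[1:50]))
  m[, 1] <- 1L
  m <- m[, 1:50]
  dimnames(m) <- list(paste0("s", 1:30), paste0("L", 1:50))
  obj <- toy_aflp(m, year = rep(2010L, 30))
  f1 <- fragment_filter(obj)
  expect_equal(nrow(f1$data), 30)  # all within band
  # plant an extreme low-count sample
  m2 <- m; m2[1, ] <- 0L
  obj2 <- toy_aflp(m2, year = c(1960L, rep(2010L, 29)))
  f2 <- fragment_filter(obj2)
  expect_false("s1" %in% rownames(f2$data))
  rep2 <- attr(f2, "filter_report")
  expect_true(rep2$removed[rep2$sample_id == "s1"])
  # idempotent on its own output
  f3 <- fragment_filter(f2)
  expect_identical(f3$data, f2$data)
})

test_that("filter on synthetic herbarium data removes heavily degraded samples", {
  af <- make_aflp_dataset(synthetic_spec(33))
  filtered <- fragment_filter(af$aflp)
  removed <- setdiff(rownames(af$aflp$data), rownames(filtered$data))
  years <- af$aflp$meta$year[match(removed, af$aflp$meta$sample_id)]
  # removals concentrate in the pre-cutoff (degraded) era
  expect_gt(length(removed), 0)
  expect_true(mean(years < 2003) > 0.9)
  # the oldest, most degraded tail is gone
  old <- af$aflp$meta$sample_id[af$aflp$meta$year <= 1955]
  counts <- fragment_counts(af$aflp)
  worst <- old[which.min(counts[old])]
  expect_true(worst %in% removed)
})

test_that("euclidean distance and metric properties", {
  m <- rbind(s1 = rep(1L, 8), s2 = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  colnames(m) <- paste0("L", 1:8)
  d <- euclidean_distance(toy_aflp(m))
  expect_equal(d["s1", "s2"], 2)  # sqrt(4 differing loci)
  expect_equal(d["s1", "s1"], 0)
  set.seed(5)
  r <- matrix(rbinom(60, 1, 0.5), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("L", 1:10)))
  dr <- euclidean_distance(toy_aflp(r))
  for (i in 1:4) for (j in (i + 1):5) for (k in (j + 1):6) {
    expect_lte(dr[i, k], dr[i, j] + dr[j, k] + 1e-12)
  }
})

test_that("PCoA: closed form, Euclidean exactness and rank", {
  # 2 points at distance delta
  delta <- 3
  d <- matrix(c(0, delta, delta, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- pcoa(d)
  expect_equal(p$n_positive, 1)
  expect_equal(p$eigenvalues[1], delta^2 / 2)
  expect_equal(sort(abs(p$coordinates[, 1])), c(delta / 2, delta / 2),
               ignore_attr = TRUE)
  # Euclidean input: distances reproduced exactly
  set.seed(6)
  x <- matrix(rnorm(20 * 5), 20)
  dx <- as.matrix(dist(x)); dimnames(dx) <- list(paste0("s", 1:20), paste0("s", 1:20))
  px <- pcoa(dx)
  expect_equal(as.matrix(dist(px$coordinates)), dx, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(px$explained), 100, tolerance = 1e-8)
  # agreement with the classical-scaling oracle
  cs <- cmdscale(dx, k = 5, eig = TRUE)
  expect_equal(px$eigenvalues[1:5], cs$eig[1:5], tolerance = 1e-8)
})

test_that("broken stick proportions and significant axis counting", {
  expect_equal(broken_stick(1), 1)
  expect_equal(round(broken_stick(3), 4), c(0.6111, 0.2778, 0.1111))
  for (p in c(2, 7, 30)) expect_equal(sum(broken_stick(p)), 1)
  fake <- structure(list(explained = c(55, 30, 10, 5),
                         broken_stick = broken_stick(4)), class = "pcoa_result")
  expect_equal(significant_axes(fake), 2)
})

test_that("band statistics count private fragments per region", {
  m <- rbind(a1 = c(1L, 1L, 0L, 0L), a2 = c(1L, 0L, 0L, 0L),
             b1 = c(1L, 0L, 1L, 0L), b2 = c(1L, 0L, 1L, 1L))
  colnames(m) <- paste0("L", 1:4)
  obj <- toy_aflp(m, pool = c("A", "A", "B", "B"))
  bs <- band_statistics(obj)
  expect_equal(bs$unique_fragments[bs$region == "A"], 1)  # L2
  expect_equal(bs$unique_fragments[bs$region == "B"], 2)  # L3, L4
  # single region: all present loci are "unique"
  one <- band_statistics(toy_aflp(m, pool = "A"))
  expect_equal(one$unique_fragments, one$fragments)
  # pool with higher planted private-band rate has more unique fragments
  af <- make_aflp_dataset(synthetic_spec(8))
  bs2 <- band_statistics(af$aflp, group_by = "pool")
  expect_true(all(bs2$unique_fragments >= 0))
})

test_that("AMOVA: perfect structure, brute-force oracle and null behaviour", {
  # two internally identical, mutually distinct groups
  m <- rbind(a1 = rep(0L, 10), a2 = rep(0L, 10),
             b1 = rep(1L, 10), b2 = rep(1L, 10))
  colnames(m) <- paste0("L", 1:10)
  d <- euclidean_distance(toy_aflp(m))
  am <- amova(d, c("A", "A", "B", "B"), permutations = 99, seed = 1)
  expect_equal(am$Phi_ST, 1)
  # hand-computable toy against an independent sums-of-squares oracle
  set.seed(7)
  x <- matrix(rnorm(4 * 3), 4); dx <- as.matrix(dist(x))
  dimnames(dx) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- c("A", "A", "B", "B")
  am2 <- amova(dx, g, permutations = 99, seed = 2)
  ss_tot <- sum(dx[upper.tri(dx)]^2) / 4
  ss_w <- dx[1, 2]^2 / 2 + dx[3, 4]^2 / 2
  ss_a <- ss_tot - ss_w
  ms_a <- ss_a / 1; ms_w <- ss_w / 2
  n0 <- (4 - (4 + 4) / 4) / 1
  s2a <- (ms_a - ms_w) / n0
  expect_equal(am2$Phi_ST, s2a / (s2a + ms_w), tolerance = 1e-9)
  expect_equal(unname(am2$SS["among"]), ss_a, tolerance = 1e-9)
  # homogeneous data: Phi near 0, p not extreme; seed-reproducible
  set.seed(8)
  y <- matrix(rnorm(20 * 5), 20); dy <- as.matrix(dist(y))
  dimnames(dy) <- list(paste0("s", 1:20), paste0("s", 1:20))
  gl <- rep(c("A", "B"), 10)
  am3 <- amova(dy, gl, permutations = 199, seed = 3)
  expect_lt(abs(am3$Phi_ST), 0.2)
  expect_gt(am3$p, 0.05)
  expect_identical(am3$p, amova(dy, gl, permutations = 199, seed = 3)$p)
})

test_that("Evanno delta-K finds a planted kink and handles degeneracies", {
  mk <- function(means, sds = rep(1, length(means)), reps = 3) {
    do.call(rbind, lapply(seq_along(means), function(i) {
      data.frame(K = i, rep = 1:reps,
                 lnP = means[i] + sds[i] * scale(seq_len(reps))[, 1])
    }))
  }
  # linear lnP: interior delta-K all zero
  lin <- evanno_delta_k(mk(c(-500, -400, -300, -200)))
  expect_equal(lin$delta_K[2:3], c(0, 0))
  expect_true(is.na(lin$delta_K[1]) && is.na(lin$delta_K[4]))
  # kink at K = 2
  kink <- evanno_delta_k(mk(c(-500, -300, -280, -260)))
  expect_equal(kink$K[which.max(kink$delta_K)], 2)
  expect_equal(kink$delta_K[2], abs(-280 - 2 * -300 + -500) / kink$sd_lnP[2])
  # zero replicate variance -> NA with warning
  zero <- mk(c(-500, -300, -280), sds = c(1, 0, 1))
  expect_warning(ez <- evanno_delta_k(zero), "zero replicate variance")
  expect_true(is.na(ez$delta_K[2]))
  expect_error(evanno_delta_k(mk(c(-1, -2))), ">= 3")
})
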