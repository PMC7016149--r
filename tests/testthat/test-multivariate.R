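test_that("the collinearity screen drops the right variables", {
  set.seed(71)
  v <- rnorm(30)
  env <- data.frame(a = v, b = v, c = rnorm(30))
  out <- collinearityFilter(env)
  expect_length(out$retained, 2)
  expect_true("c" %in% out$retained)
  expect_length(out$dropped, 1)

  # a pair just under the threshold is kept
  set.seed(72)
  x <- rnorm(200)
  y <- 0.69 * x + sqrt(1 - 0.69^2) * rnorm(200)
  y <- as.numeric(scale(resid(lm(y ~ x)))) * sqrt(1 - 0.69^2) +
    0.69 * as.numeric(scale(x))            # exact r = 0.69
  env2 <- data.frame(x = as.numeric(scale(x)), y = y)
  expect_equal(abs(cor(env2$x, env2$y)), 0.69, tolerance = 1e-10)
  expect_length(collinearityFilter(env2)$retained, 2)

  const <- data.frame(a = rep(1, 10), b = rnorm(10), c = rnorm(10))
  expect_warning(out3 <- collinearityFilter(const), "constant")
  expect_false("a" %in% out3$retained)
})

test_that("greedy collinearity removal matches exhaustive search on toys", {
  # three mutually collinear variables plus one independent: the largest
  # admissible subset keeps the independent one and exactly one of the
  # collinear triplet
  set.seed(73)
  base <- rnorm(60)
  env <- data.frame(a = base + rnorm(60, 0, 0.1),
                    b = base + rnorm(60, 0, 0.1),
                    c = base + rnorm(60, 0, 0.1),
                    d = rnorm(60))
  got <- collinearityFilter(env)$retained
  vars <- names(env)
  admissible <- function(sub) {
    if (length(sub) < 2) return(TRUE)
    r <- abs(cor(env[, sub])); diag(r) <- 0
    max(r) <= 0.7
  }
  sizes <- vapply(seq_along(vars), function(k)
    any(vapply(combn(vars, k, simplify = FALSE), admissible, logical(1))),
    logical(1))
  expect_equal(length(got), max(which(sizes)))
  expect_true(admissible(got))
})

test_that("PERMANOVA pseudo-F equals the hand-computed partition", {
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 4, 4, 5, 4, 4, 5), 6, 2, byrow = TRUE)
  rownames(pts) <- paste0("p", 1:6)
  d <- as.matrix(dist(pts))
  groups <- rep(c("g1", "g2"), each = 3)
  res <- permanova(d, groups, reps = 199, seed = 1)
  expect_equal(res$statistic, bruteForcePseudoF(d, groups),
               tolerance = 1e-12)
  # only 20 distinct label arrangements exist for 3+3, so the smallest
  # attainable two-group p is 0.1
  expect_lte(res$p, 0.15)
  expect_error(permanova(d, rep("g", 6)), "2 groups")
})

test_that("duplicated points give maximal separation and the minimal p", {
  pts <- rbind(matrix(0, 8, 2), matrix(5, 8, 2))
  rownames(pts) <- paste0("p", 1:16)
  d <- as.matrix(dist(pts))
  res <- permanova(d, rep(c("a", "b"), each = 8), reps = 199, seed = 2)
  expect_equal(res$p, 1 / 200)
  expect_true(!is.finite(res$statistic) || res$statistic > 1e6)
})

test_that("Mantel r equals the Pearson correlation of lower triangles", {
  set.seed(74)
  d1 <- as.matrix(dist(matrix(rnorm(20), 10)))
  d2 <- as.matrix(dist(matrix(rnorm(20), 10)))
  res <- mantelTest(d1, d2, reps = 99, seed = 1)
  expect_equal(res$statistic,
               cor(d1[lower.tri(d1)], d2[lower.tri(d2)]),
               tolerance = 1e-12)
  expect_equal(mantelTest(d1, d1, reps = 99, seed = 1)$statistic, 1)
})

test_that("partial Mantel matches brute-force residual correlation", {
  set.seed(75)
  d1 <- as.matrix(dist(matrix(rnorm(24), 12)))
  d2 <- as.matrix(dist(matrix(rnorm(24), 12)))
  d3 <- as.matrix(dist(matrix(rnorm(24), 12)))
  res <- partialMantelTest(d1, d2, d3, reps = 99, seed = 1)
  v1 <- d1[lower.tri(d1)]; v2 <- d2[lower.tri(d2)]; v3 <- d3[lower.tri(d3)]
  oracle <- cor(resid(lm(v1 ~ v3)), resid(lm(v2 ~ v3)))
  expect_equal(res$statistic, oracle, tolerance = 1e-10)
  # a covariate uncorrelated with both leaves r essentially unchanged
  plain <- mantelTest(d1, d2, reps = 99, seed = 1)$statistic
  expect_equal(res$statistic, plain, tolerance = 0.2)
  # controlling for a matrix that carries the shared structure strips
  # most of the plain correlation
  set.seed(76)
  shared <- as.matrix(dist(matrix(rnorm(24), 12)))
  e1 <- as.matrix(dist(matrix(rnorm(24), 12)))
  e2 <- as.matrix(dist(matrix(rnorm(24), 12)))
  da <- shared + 0.2 * e1
  db <- shared + 0.2 * e2
  plain <- mantelTest(da, db, reps = 99, seed = 1)$statistic
  partial <- partialMantelTest(da, db, shared, reps = 99,
                               seed = 1)$statistic
  expect_gt(plain, 0.8)
  expect_lt(abs(partial), 0.5)
})

test_that("permutation tests hold their type-I error rate", {
  rejM <- rejP <- 0
  n <- 60
  for (s in 1:n) {
    set.seed(s)
    d1 <- as.matrix(dist(matrix(rnorm(20), 10)))
    d2 <- as.matrix(dist(matrix(rnorm(20), 10)))
    rejM <- rejM + (mantelTest(d1, d2, reps = 99, seed = s)$p <= 0.05)
    rejP <- rejP + (permanova(d1, rep(c("a", "b"), 5), reps = 99,
                              seed = s)$p <= 0.05)
  }
  expect_lte(rejM / n, 0.12)
  expect_lte(rejP / n, 0.12)
})

test_that("PERMDISP distinguishes equal from unequal dispersion", {
  hits <- 0
  for (s in 1:30) {
    set.seed(s)
    pts <- rbind(matrix(rnorm(16), 8), matrix(rnorm(16), 8))
    d <- as.matrix(dist(pts))
    hits <- hits + (permdisp(d, rep(c("a", "b"), each = 8), reps = 99,
                             seed = s)$p > 0.05)
  }
  expect_gte(hits / 30, 0.85)

  set.seed(99)
  pts <- rbind(matrix(rnorm(20), 10), 4 * matrix(rnorm(20), 10))
  d <- as.matrix(dist(pts))
  expect_lte(permdisp(d, rep(c("a", "b"), each = 10), reps = 199,
                      seed = 1)$p, 0.05)

  # a group of identical points contributes zero dispersion
  pts2 <- rbind(matrix(1, 4, 2), matrix(rnorm(8), 4))
  d2 <- as.matrix(dist(pts2))
  bd <- vegan::betadisper(as.dist(d2), rep(c("a", "b"), each = 4),
                          type = "median")
  expect_equal(unname(bd$distances[1:4]), rep(0, 4), tolerance = 1e-9)
})

test_that("forward selection finds the generating gradient and stops on noise", {
  cfg <- scenarioConfig(nSites = 16, nTaxa = 60, nTimepoints = 1,
                        split = 2, seed = 31, nicheBreadth = 0.8,
                        envSd = c(dry = 2, wet = 2), depth = 800,
                        nNuisanceEnv = 3)
  sim <- simulateMetacommunity(cfg)
  Y <- hellingerTransform(countsAt(sim, 1))
  res <- rdaForwardSelect(Y, envAt(sim, 1), reps = 199, seed = 1)
  expect_equal(res$selected[1], "env1")
  expect_gt(res$r2, 0)

  # pure-noise predictors are rarely retained
  retained <- 0
  for (s in 1:25) {
    set.seed(s)
    Yn <- matrix(rnorm(16 * 10), 16)
    Xn <- data.frame(a = rnorm(16), b = rnorm(16))
    r <- rdaForwardSelect(Yn, Xn, reps = 99, seed = s)
    retained <- retained + (length(r$selected) > 0)
  }
  expect_lte(retained / 25, 0.2)

  # responses orthogonal to the predictors explain nothing
  X <- data.frame(a = rep(c(-1, 1), 8))
  Yo <- matrix(rnorm(16 * 6), 16)
  Yo <- resid(lm(Yo ~ X$a))
  r0 <- rdaForwardSelect(Yo, X, reps = 99, seed = 2)
  expect_length(r0$selected, 0)
})

test_that("period comparisons match textbook Kruskal-Wallis values", {
  # identical rank patterns in both periods
  res <- comparePeriods(c(1, 2, 3, 1, 2, 3),
                        c("dry", "dry", "dry", "wet", "wet", "wet"))
  expect_equal(res$kruskal$p, 1)
  # hand-computed H for 6 untied values split 3|3:
  # H = 12/(n(n+1)) * sum Ri^2/ni - 3(n+1), R_dry = 1+2+4, R_wet = 3+5+6
  vals <- c(10, 20, 40, 30, 50, 60)
  per <- c("dry", "dry", "dry", "wet", "wet", "wet")
  H <- 12 / (6 * 7) * ((7^2) / 3 + (14^2) / 3) - 3 * 7
  res2 <- comparePeriods(vals, per)
  expect_equal(res2$kruskal$statistic, H, tolerance = 1e-12)
  expect_equal(res2$kruskal$direction, "wet > dry")
  expect_warning(comparePeriods(rep(1, 6), per), "tied")
  expect_error(comparePeriods(1:3, c("dry", "dry", "wet")), "2 values")
})

test_that("location shifts of two pooled SDs are reliably detected", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    vals <- c(rnorm(5), rnorm(5, mean = 2))
    p <- comparePeriods(vals, rep(c("dry", "wet"), each = 5))$kruskal$p
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 100, 0.5)
})
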