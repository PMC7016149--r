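nestedInc <- function() {
  m <- rbind(s1 = c(1, 1, 1), s2 = c(1, 1, 0), s3 = c(1, 0, 0))
  colnames(m) <- c("a", "b", "c")
  m
}

# a larger nested staircase (the 3x3 case is too small for the null to
# have any variance)
nestedStaircase <- function(n = 8) {
  m <- outer(seq_len(n), seq_len(n), function(i, j)
    as.integer(j <= n + 1 - i))
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("o", seq_len(n)))
  m
}

# mutually exclusive species pairs, each on its own random bipartition
# of the sites, so no ordering can reconcile them
checkerboardInc <- function(nPairs = 24, nSites = 12, seed = 2) {
  set.seed(seed)
  m <- matrix(0L, nSites, 2 * nPairs,
              dimnames = list(paste0("s", 1:nSites),
                              paste0("o", 1:(2 * nPairs))))
  for (p in seq_len(nPairs)) {
    h <- sample(nSites, nSites / 2)
    m[h, 2 * p - 1] <- 1L
    m[-h, 2 * p] <- 1L
  }
  m
}

test_that("ordination finds the gap-free arrangement of a nested matrix", {
  ord <- ordinateMatrix(nestedInc())
  expect_equal(countEmbeddedAbsences(ord), 0)
  # exhaustive check: 0 is the attainable minimum over all 3! x 3! orders
  perms <- function(v) if (length(v) == 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  minEA <- min(vapply(perms(1:3), function(rp)
    min(vapply(perms(1:3), function(cp)
      bruteForceEmbeddedAbsences(nestedInc()[rp, cp]), numeric(1))),
    numeric(1)))
  expect_equal(minEA, 0)
})

test_that("ordination is idempotent and reflection-invariant", {
  m <- randomCommunity(6, 8, seed = 31, lambda = 0.9)
  inc <- (m > 0) * 1L
  inc <- inc[rowSums(inc) > 0, colSums(inc) > 0]
  o1 <- ordinateMatrix(inc)
  o2 <- ordinateMatrix(o1)
  expect_equal(countEmbeddedAbsences(o1), countEmbeddedAbsences(o2))
  # reversing both axes (a reflection of the first axis) changes nothing
  rev1 <- o1[nrow(o1):1, ncol(o1):1]
  expect_equal(countEmbeddedAbsences(rev1), countEmbeddedAbsences(o1))
})

test_that("embedded-absence counts match a brute-force scan", {
  expect_equal(countEmbeddedAbsences(cbind(c(1, 0, 1))), 1)
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(rbinom(48, 1, 0.45), 6, 8)
    expect_equal(countEmbeddedAbsences(m), bruteForceEmbeddedAbsences(m))
    expect_equal(countEmbeddedAbsences(m, mode = "columns"),
                 bruteForceEmbeddedAbsences(m, mode = "columns"))
  }
})

test_that("coherence separates nested, checkerboard and r1-random structure", {
  coh <- coherence(nestedStaircase(), reps = 199, seed = 1)
  expect_gt(coh$z, 1.96)
  cb <- coherence(checkerboardInc(), reps = 199, seed = 1)
  expect_lt(cb$z, 0)
  expect_true(cb$p < 0.05)
})

test_that("the r1 null preserves site richness in every replicate", {
  m <- randomCommunity(8, 20, seed = 32, lambda = 0.6)
  inc <- (m > 0) * 1L
  inc <- inc[rowSums(inc) > 0, colSums(inc) > 0]
  nm <- vegan::nullmodel(inc, "r1")
  sims <- simulate(nm, nsim = 20, seed = 9)
  for (k in 1:20)
    expect_equal(unname(rowSums(sims[, , k])), unname(rowSums(inc)))
})

test_that("turnover counts replacements and keeps the published sign", {
  # identical ranges contribute nothing; fully distinct singletons one each
  two <- cbind(a = c(1, 0, 0), b = c(0, 1, 0))
  rownames(two) <- paste0("s", 1:3)
  tr <- turnover(rbind(two, two), reps = 99, seed = 1)
  expect_true(is.finite(tr$observed))
  expect_equal(metanull:::.replacements(c(1, 2), c(1, 2)), 1)
  expect_equal(metanull:::.replacements(c(1, 1), c(2, 2)), 0)
  # nested matrix: zero replacements, so z cannot be positive
  tn <- turnover(nestedInc(), reps = 199, seed = 2)
  expect_equal(tn$observed, 0)
  expect_lte(tn$z, 0)
})

test_that("Morisita boundary clumping matches hand-computed cases", {
  # two species confined to the first ordered site: b = (4, 0, 0), S = 3
  m1 <- cbind(a = c(1, 0, 0), b = c(1, 0, 0))
  rownames(m1) <- paste0("s", 1:3)
  expect_equal(morisitaBoundary(m1)$index, 3)
  expect_equal(morisitaBoundary(m1)$boundaries, c(4, 0, 0))
  # three singleton species at distinct sites: b = (2, 2, 2)
  m2 <- diag(3)
  dimnames(m2) <- list(paste0("s", 1:3), letters[1:3])
  expect_equal(morisitaBoundary(m2)$index, 0.6)
  # maximum: all boundaries on one site gives I = S
  m3 <- cbind(a = c(1, 0, 0, 0), b = c(1, 0, 0, 0))
  rownames(m3) <- paste0("s", 1:4)
  expect_equal(morisitaBoundary(m3)$index, 4)
})

test_that("metacommunity classification implements the threshold tree", {
  mk <- function(zc, zt = 0, I = 1, pI = 1)
    list(coherence = list(z = zc, p = 0),
         turnover = list(z = zt, p = 0),
         clumping = list(index = I, p = pI))
  expect_equal(classifyMetacommunity(mk(-3.1)), "checkerboard")
  expect_equal(classifyMetacommunity(mk(0.4)), "random")
  expect_equal(classifyMetacommunity(mk(2.5, zt = -2.2, I = 2.4,
                                        pI = 0.001)),
               "nested (clumped species loss)")
  expect_equal(classifyMetacommunity(mk(2.5, zt = 2.2, I = 2.4,
                                        pI = 0.001)), "Clementsian")
  expect_equal(classifyMetacommunity(mk(2.5, zt = 2.2, I = 0.4,
                                        pI = 0.001)), "evenly spaced")
  expect_equal(classifyMetacommunity(mk(2.5, zt = 2.2, I = 1.2, pI = 0.6)),
               "Gleasonian")
  expect_equal(classifyMetacommunity(mk(2.5, zt = 0.5, I = 1.2, pI = 0.6)),
               "quasi-Gleasonian")
  # total function: every grid combination yields exactly one known label
  labels <- c("checkerboard", "random", "indeterminate",
              "nested (clumped species loss)",
              "nested (over-dispersed species loss)",
              "nested (random species loss)", "Clementsian", "Gleasonian",
              "evenly spaced", "quasi-Clementsian", "quasi-Gleasonian",
              "quasi-evenly spaced", "quasi-nested (clumped species loss)",
              "quasi-nested (over-dispersed species loss)",
              "quasi-nested (random species loss)")
  for (zc in c(-3, -1, 0, 1, 3)) for (zt in c(-3, -0.5, 0.5, 3))
    for (I in c(0.3, 1.5)) for (pI in c(0.001, 0.5)) {
      lab <- classifyMetacommunity(mk(zc, zt, I, pI))
      expect_true(lab %in% labels)
    }
  expect_error(classifyMetacommunity(list(coherence = list(z = 1))),
               "needs")
})

test_that("a full EMS analysis returns a classified EMSResult", {
  sim <- neutralScenario(seed = 8, nSites = 10, nTaxa = 40, depth = 150)
  res <- emsAnalysis(countsAt(sim, 1), reps = 99, seed = 4)
  expect_s4_class(res, "EMSResult")
  expect_true(res@type %in% c("random", "checkerboard") ||
                grepl("nested|Clementsian|Gleasonian|spaced", res@type))
  expect_output(show(res), "coherence")
  expect_equal(res@meta$null, "r1")
})
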