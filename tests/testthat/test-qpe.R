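test_that("betaMNTD matches hand values and the brute-force oracle", {
  pd <- patristicDistances(balancedTree4())
  a <- c(A = 1, B = 0, C = 0, D = 0)
  b <- c(A = 0, B = 1, C = 0, D = 0)
  expect_equal(betaMNTD(a, b, pd), 2)       # 0.5 * (2 + 2)
  expect_equal(betaMNTD(a, a, pd), 0)       # nearest neighbour is itself

  for (seed in 1:25) {
    set.seed(seed)
    tr <- ape::rtree(10)
    pd <- patristicDistances(tr)
    x <- setNames(rpois(10, 2), tr$tip.label)
    y <- setNames(rpois(10, 2), tr$tip.label)
    if (sum(x) == 0) x[1] <- 1
    if (sum(y) == 0) y[2] <- 1
    ix <- match(names(x), rownames(pd))
    expect_equal(betaMNTD(x, y, pd),
                 bruteForceBetaMNTD(x[rownames(pd)], y[rownames(pd)], pd),
                 tolerance = 1e-10)
  }
})

test_that("unweighted betaMNTD equals the plain mean nearest-taxon distance", {
  set.seed(77)
  tr <- ape::rtree(12)
  pd <- patristicDistances(tr)
  x <- setNames(rpois(12, 3), tr$tip.label)
  y <- setNames(rpois(12, 3), tr$tip.label)
  x[1] <- max(x[1], 1); y[2] <- max(y[2], 1)
  expect_equal(betaMNTD(x, y, pd, weighted = FALSE),
               bruteForceBetaMNTD(x[rownames(pd)], y[rownames(pd)], pd,
                                  weighted = FALSE),
               tolerance = 1e-10)
})

test_that("betaMNTD agrees with picante's between-community MNTD", {
  skip_if_not_installed("picante")
  set.seed(13)
  tr <- ape::rtree(15)
  m <- randomCommunity(4, 15, seed = 14, lambda = 2)
  colnames(m) <- tr$tip.label
  m[rowSums(m) == 0, 1] <- 1L
  ref <- as.matrix(picante::comdistnt(m, ape::cophenetic.phylo(tr),
                                      abundance.weighted = TRUE))
  pd <- patristicDistances(tr)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(betaMNTD(m[i, ], m[j, ], pd), ref[i, j],
                 tolerance = 1e-10)
})

test_that("betaNTI flags pairs with a degenerate null and stays symmetric", {
  # zero internal edges make every tip equidistant: the tip shuffle
  # cannot change betaMNTD
  tr <- ape::read.tree(text = "((A:1,B:1):0,(C:1,D:1):0);")
  m <- rbind(s1 = c(2L, 1L, 0L, 0L), s2 = c(0L, 0L, 2L, 1L),
             s3 = c(1L, 0L, 1L, 0L))
  colnames(m) <- c("A", "B", "C", "D")
  expect_warning(z <- betaNTI(m, tr, reps = 99, seed = 1), "degenerate")
  expect_true(all(is.na(z[lower.tri(z)])))

  sim <- neutralScenario(seed = 5, nSites = 6, nTaxa = 30, depth = 200)
  m2 <- countsAt(sim, 1)
  z2 <- betaNTI(m2, seriesTree(sim), reps = 99, seed = 3)
  expect_true(isSymmetric(unname(z2)))
  expect_identical(z2, betaNTI(m2, seriesTree(sim), reps = 99, seed = 3))
  # site relabelling permutes rows/columns only
  perm <- c(3, 1, 2, 6, 5, 4)
  z3 <- betaNTI(m2[perm, ], seriesTree(sim), reps = 99, seed = 3)
  expect_equal(unname(attr(z3, "bMNTD")),
               unname(attr(z2, "bMNTD")[perm, perm]), tolerance = 1e-12)
})

test_that("OTUs missing from the tree are a hard error unless pruned", {
  tr <- balancedTree4()
  m <- randomCommunity(3, 5, seed = 15, lambda = 3)
  colnames(m) <- c("A", "B", "C", "D", "X")
  expect_error(betaNTI(m, tr, reps = 99), "absent from the tree")
  z <- suppressWarnings(betaNTI(m, tr, reps = 99, seed = 1, prune = TRUE))
  expect_equal(dim(z), c(3, 3))
})

test_that("the beta_RCbray null conserves richness and total abundance", {
  m <- randomCommunity(6, 25, seed = 16, lambda = 2)
  occw <- as.numeric(colSums(m > 0))
  regp <- colSums(m) / sum(m)
  res <- metanull:::cpp_rcbray_null(10L, 60L, 14L, 80L, occw, regp,
                                    50L, TRUE)
  nulls <- res$nulls
  odd <- nulls[seq(1, 99, by = 2), ]
  even <- nulls[seq(2, 100, by = 2), ]
  expect_true(all(rowSums(odd > 0) == 10))
  expect_true(all(rowSums(odd) == 60))
  expect_true(all(rowSums(even > 0) == 14))
  expect_true(all(rowSums(even) == 80))
  expect_equal(as.numeric(res$bc),
               rowSums(abs(odd - even)) / (60 + 80), tolerance = 1e-12)
})

test_that("beta_RCbray hits its formula bounds for forced communities", {
  # near-disjoint pair whose overlap the pigeonhole principle forces on
  # every null draw (rich 6 + 6 from a 10-taxon pool): the observed
  # dissimilarity exceeds every null value
  m <- rbind(
    s1 = c(30L, 30L, 30L, 30L, 1L, 1L, 0L, 0L, 0L, 0L),
    s2 = c(0L, 0L, 0L, 0L, 1L, 1L, 30L, 30L, 30L, 30L))
  colnames(m) <- paste0("o", 1:10)
  rc <- betaRCBray(m, reps = 199, seed = 1)
  expect_equal(rc["s1", "s2"], 1)
  # identical diverse communities: observed BC (=0) is below every null
  set.seed(2)
  base <- as.integer(rmultinom(1, 200, rep(1 / 8, 8)))
  m2 <- rbind(s1 = base, s2 = base,
              s3 = as.integer(rmultinom(1, 200, rep(1 / 8, 8))),
              s4 = as.integer(rmultinom(1, 200, rep(1 / 8, 8))))
  colnames(m2) <- paste0("o", 1:8)
  rc2 <- betaRCBray(m2, reps = 199, seed = 3)
  expect_equal(rc2["s1", "s2"], -1)
})

test_that("pair classification reproduces the published threshold logic", {
  mk <- function(z, rc) {
    b <- matrix(c(0, z, z, 0), 2, 2, dimnames = list(c("s1", "s2"),
                                                     c("s1", "s2")))
    r <- matrix(c(0, rc, rc, 0), 2, 2, dimnames = dimnames(b))
    classifyPairs(b, r)$process
  }
  expect_equal(as.character(mk(2.5, 0)), "variable selection")
  expect_equal(as.character(mk(-2.5, 0)), "homogeneous selection")
  expect_equal(as.character(mk(0.8, 0.97)),
               "dispersal limitation or historical contingency")
  expect_equal(as.character(mk(0.8, 0.10)), "drift")
  expect_equal(as.character(mk(0.8, -0.97)), "homogenizing dispersal")
  # boundary values fall away from selection / towards drift
  expect_equal(as.character(mk(2, 0.1)), "drift")
  expect_equal(as.character(mk(-2, 0.1)), "drift")
  expect_equal(as.character(mk(0, 0.95)), "drift")
  expect_equal(as.character(mk(0, -0.95)), "drift")
  expect_true(is.na(mk(NA, 0.5)))
  expect_error(classifyPairs(matrix(0, 2, 2), matrix(0, 3, 3)),
               "share site labels")
})

test_that("process fractions sum to one and ignore site labels", {
  sim <- neutralScenario(seed = 7, nSites = 16, nTaxa = 30, depth = 150)
  m <- countsAt(sim, 1)
  z <- suppressWarnings(betaNTI(m, seriesTree(sim), reps = 99, seed = 2))
  rc <- betaRCBray(m, reps = 99, seed = 3)
  cls <- classifyPairs(z, rc)
  expect_equal(nrow(cls), choose(16, 2))
  fr <- processFractions(cls)
  procCols <- intersect(metanull:::.processLabels, colnames(fr))
  expect_equal(sum(unlist(fr[1, procCols])), 1, tolerance = 1e-9)
  perm <- sample(16)
  cls2 <- classifyPairs(z[perm, perm], rc[perm, perm])
  expect_equal(sort(table(cls2$process)), sort(table(cls$process)))
  # undefined pairs are excluded but counted
  z[2, 1] <- z[1, 2] <- NA
  frx <- processFractions(classifyPairs(z, rc))
  expect_equal(frx$nExcluded, 1)
  expect_equal(frx$nPairs, choose(16, 2) - 1)
})
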