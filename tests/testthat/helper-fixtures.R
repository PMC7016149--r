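# shared fixtures and independent oracles, all built in code

balancedTree4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# brute-force patristic distances: sum edge lengths along the node path
bruteForcePatristic <- function(tree) {
  n <- length(tree$tip.label)
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      path <- setdiff(unlist(ape::nodepath(tree, i, j)),
                      ape::getMRCA(tree, c(i, j)))
      out[i, j] <- out[j, i] <- sum(elen[path])
    }
  }
  out
}

# independent double-loop betaMNTD oracle
bruteForceBetaMNTD <- function(a, b, pd, weighted = TRUE) {
  ia <- which(a > 0)
  ib <- which(b > 0)
  fa <- if (weighted) a[ia] / sum(a) else rep(1 / length(ia), length(ia))
  fb <- if (weighted) b[ib] / sum(b) else rep(1 / length(ib), length(ib))
  s <- 0
  for (k in seq_along(ia)) {
    dmin <- Inf
    for (l in seq_along(ib)) dmin <- min(dmin, pd[ia[k], ib[l]])
    s <- s + fa[k] * dmin
  }
  for (l in seq_along(ib)) {
    dmin <- Inf
    for (k in seq_along(ia)) dmin <- min(dmin, pd[ib[l], ia[k]])
    s <- s + fb[l] * dmin
  }
  unname(s / 2)
}

# brute-force embedded-absence scan (independent of the implementation)
bruteForceEmbeddedAbsences <- function(m, mode = "both") {
  scan1 <- function(x) {
    tot <- 0
    for (j in seq_len(ncol(x))) {
      occ <- which(x[, j] > 0)
      if (length(occ) < 2) next
      for (i in (min(occ)):(max(occ)))
        if (x[i, j] == 0) tot <- tot + 1
    }
    tot
  }
  if (mode == "both") scan1(m) + scan1(t(m)) else scan1(m)
}

# exact incidence Raup-Crick under uniform weighting: the shared count of
# two independent uniform draws of sizes n1, n2 from N taxa is
# hypergeometric(n1, N - n1, n2)
exactBetaRCUniform <- function(n1, n2, N, obs) {
  k <- 0:min(n1, n2)
  p <- stats::dhyper(k, n1, N - n1, n2)
  2 * (sum(p[k > obs]) + 0.5 * sum(p[k == obs])) - 1
}

# one-factor PERMANOVA pseudo-F computed directly from its definition
bruteForcePseudoF <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.factor(groups)
  sst <- sum(d[lower.tri(d)]^2) / n
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- d[idx, idx]
    ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  a <- nlevels(groups)
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

randomCommunity <- function(nSites, nOtus, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(nSites * nOtus, lambda), nSites, nOtus,
              dimnames = list(paste0("s", seq_len(nSites)),
                              paste0("o", seq_len(nOtus))))
  storage.mode(m) <- "integer"
  m
}
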