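#' Scenario configuration for the metacommunity simulator
#'
#' Bundles (and validates) every knob of the generative model: a Yule
#' phylogeny scaled to unit height; per-taxon environmental optima
#' evolved by Brownian motion (rate `bmRate`, so phylogenetic signal in
#' the niche exists whenever `bmRate > 0`); Gaussian environmental
#' filtering with niche breadth `nicheBreadth` (selection off when
#' `selection = FALSE`); a log-normal regional abundance distribution; a
#' dry-to-wet regime shift at `split` that changes the among-site mean
#' and spread of the environmental variable; dispersal limitation via
#' site-specific colonist weights decaying as `exp(-dispersalDecay *
#' distance)` from each taxon's home site; homogenizing dispersal via
#' mixing each site's expected composition with the regional mean at rate
#' `migration`; and demographic drift as per-site log-normal noise of sd
#' `driftSd` on expected abundances. Sites sit on a fixed grid at unit
#' spacing (16 sites = a 4x4 grid). Counts are multinomial at `depth` per
#' site, so every emitted row sums exactly to `depth`.
#'
#' @param nSites,nTaxa,nTimepoints,split series dimensions; time points
#'   `>= split` are the wet period.
#' @param seed master seed.
#' @param bmRate Brownian rate (variance per unit tree height) of niche
#'   optima.
#' @param nicheBreadth Gaussian niche breadth (environmental units).
#' @param selection apply environmental filtering.
#' @param envMean,envSd named lists/vectors with elements `dry` and
#'   `wet`: per-period mean of the site environmental values and their
#'   among-site sd.
#' @param abundMu,abundSigma log-normal parameters of regional
#'   abundances.
#' @param migration homogenizing-dispersal mixing rate in `[0, 1]`.
#' @param dispersalDecay distance-decay rate of colonist weights (>= 0;
#'   0 disables dispersal limitation).
#' @param driftSd sd of per-site log-normal demographic noise (0
#'   disables drift).
#' @param depth sequencing depth per site.
#' @param nNuisanceEnv number of extra environmental variables
#'   uncorrelated with composition.
#' @param envPattern among-site layout of the environmental variable:
#'   a random `"gradient"` (default) or two spatially coherent
#'   `"clusters"` at minus/plus one `envSd`.
#' @param traitConservatism niche-conservatism exponent in `(0, 1]`.
#'   1 evolves the optima by plain Brownian motion on the emitted Yule
#'   tree; values below 1 evolve them on a copy whose node heights are
#'   raised to this power, concentrating trait change on the deep
#'   branches (an accelerating/decelerating-rates, "early-burst" clock)
#'   so that niches are conserved within clades, as in real 16S
#'   phylogenies where habitat preference is a deep trait.
#' @param poolFraction fraction of the regional taxon pool that can
#'   colonize each site (a per-site founder lottery drawn once per
#'   site); 1 disables the lottery.
#' @param anchorClade when TRUE, `envMean` entries are treated as
#'   offsets from the mean niche optimum of an automatically selected
#'   compact, trait-isolated clade of the simulated tree, so the
#'   environment is guaranteed to favour a phylogenetically coherent
#'   set of taxa (trees without such a clade are re-drawn
#'   deterministically from the seed).
#' @return a validated config list of class `scenarioConfig`.
#' @export
scenarioConfig <- function(nSites = 16, nTaxa = 200, nTimepoints = 10,
                           split = 6, seed = 1L, bmRate = 4,
                           nicheBreadth = 1, selection = TRUE,
                           envMean = c(dry = 0, wet = 0),
                           envSd = c(dry = 2, wet = 0.5),
                           abundMu = 0, abundSigma = 1.5, migration = 0,
                           dispersalDecay = 0, driftSd = 0,
                           depth = 2000, nNuisanceEnv = 0,
                           envPattern = c("gradient", "clusters"),
                           traitConservatism = 1, poolFraction = 1,
                           anchorClade = FALSE) {
  envPattern <- match.arg(envPattern)
  cfg <- list(nSites = nSites, nTaxa = nTaxa, nTimepoints = nTimepoints,
              split = split, seed = as.integer(seed), bmRate = bmRate,
              nicheBreadth = nicheBreadth, selection = selection,
              envMean = envMean, envSd = envSd, abundMu = abundMu,
              abundSigma = abundSigma, migration = migration,
              dispersalDecay = dispersalDecay, driftSd = driftSd,
              depth = depth, nNuisanceEnv = nNuisanceEnv,
              envPattern = envPattern,
              traitConservatism = traitConservatism,
              poolFraction = poolFraction, anchorClade = anchorClade)
  stopifnot(nTaxa >= 4, nSites >= 2, nTimepoints >= 1,
            split >= 1, split <= nTimepoints + 1,
            bmRate >= 0, nicheBreadth > 0, migration >= 0, migration <= 1,
            dispersalDecay >= 0, driftSd >= 0, depth > 0,
            traitConservatism > 0, traitConservatism <= 1,
            poolFraction > 0, poolFraction <= 1)
  if (!all(c("dry", "wet") %in% names(envMean)) ||
      !all(c("dry", "wet") %in% names(envSd)))
    stop("envMean and envSd need 'dry' and 'wet' entries")
  class(cfg) <- "scenarioConfig"
  cfg
}

#' Simulate a Yule tree and Brownian niche optima
#'
#' Pure-birth tree with `nTaxa` tips rescaled to unit root-to-tip height,
#' and niche optima evolved along its branches by Brownian motion from a
#' root value of 0 at rate `bmRate` (trait variance per unit height).
#' Brownian evolution guarantees that phylogenetically close taxa have
#' similar optima — the phylogenetic signal the quantitative process
#' estimates require.
#'
#' @param nTaxa number of tips (>= 4).
#' @param bmRate Brownian rate (>= 0; 0 gives all optima equal to 0).
#' @param seed integer seed.
#' @param conservatism niche-conservatism exponent in `(0, 1]`; see
#'   [scenarioConfig()]. 1 is plain Brownian motion.
#' @return list with `tree` (`phylo`, unit height) and `optima` (named
#'   numeric).
#' @export
simulateTreeAndOptima <- function(nTaxa, bmRate = 4, seed = 1L,
                                  conservatism = 1) {
  if (nTaxa < 4) stop("need at least 4 taxa")
  if (bmRate < 0) stop("bmRate must be non-negative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tree <- phytools::pbtree(n = nTaxa, scale = 1, quiet = TRUE)
  tree$tip.label <- sprintf("otu%03d", seq_len(nTaxa))
  traitTree <- if (conservatism < 1)
    .compressCrown(tree, conservatism) else tree
  optima <- if (bmRate == 0) {
    stats::setNames(rep(0, nTaxa), tree$tip.label)
  } else {
    phytools::fastBM(traitTree, a = 0, sig2 = bmRate)
  }
  list(tree = tree, optima = optima[tree$tip.label])
}

# raise node heights (root-to-node distance, scaled to [0,1]) to a
# power < 1: deep branches lengthen, crowns compress; topology and tip
# set unchanged
.compressCrown <- function(tree, gamma) {
  d <- ape::node.depth.edgelength(tree)
  d <- d / max(d)
  d2 <- d^gamma
  tree$edge.length <- d2[tree$edge[, 2]] - d2[tree$edge[, 1]]
  tree
}

# pick the most compact, trait-isolated clade of intermediate size;
# returns NULL when none qualifies
.anchorClade <- function(tree, optima, nicheBreadth,
                         sizeRange = c(0.25, 0.45)) {
  n <- length(tree$tip.label)
  pd <- ape::cophenetic.phylo(tree)
  lo <- max(8, floor(sizeRange[1] * n))
  hi <- ceiling(sizeRange[2] * n)
  best <- NULL
  for (nd in (n + 2):(n + tree$Nnode)) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    if (length(tips) < lo || length(tips) > hi) next
    mu <- mean(optima[tips])
    w <- exp(-(optima - mu)^2 / (2 * nicheBreadth^2))
    outs <- setdiff(tree$tip.label, tips)
    dmin <- apply(pd[outs, tips, drop = FALSE], 1, min)
    leak <- sum(w[outs] * dmin) / sum(w[tips])
    sub <- pd[tips, tips]
    diag(sub) <- Inf
    # typical nearest present neighbour when ~30% of the clade occurs
    nnd <- mean(apply(sub, 1, function(r)
      sort(r)[ceiling(0.3 * length(tips))]))
    score <- 3 * leak + nnd
    if (is.null(best) || score < best$score)
      best <- list(tips = tips, mu = mu, leak = leak, score = score)
  }
  best
}

# near-square unit-spacing grid of site coordinates
.siteGrid <- function(nSites) {
  nx <- ceiling(sqrt(nSites))
  g <- expand.grid(x = seq_len(nx), y = seq_len(ceiling(nSites / nx)))
  g <- g[seq_len(nSites), ]
  rownames(g) <- sprintf("site%02d", seq_len(nSites))
  g
}

#' Simulate a metacommunity series with known assembly processes
#'
#' The expected relative abundance of taxon `i` at site `s` is
#' `lambda_is proportional to A_i * exp(-(E_s - mu_i)^2 / (2 sigma_w^2))
#' * exp(-dispersalDecay * d(s, home_i)) * exp(drift noise)`, optionally
#' mixed with the regional mean at the migration rate, and counts are a
#' multinomial draw of `depth` individuals per site. See
#' [scenarioConfig()] for the meaning of every term.
#'
#' @param config a [scenarioConfig()].
#' @return a [SimulatedMetacommunity-class] (series + tree + per-time
#'   point environment + coordinates + true optima and scenario label).
#' @export
simulateMetacommunity <- function(config) {
  stopifnot(inherits(config, "scenarioConfig"))
  cfg <- config
  anchorMu <- 0
  if (cfg$anchorClade) {
    # deterministic rejection over tree sub-seeds until the pool holds a
    # compact, trait-isolated clade the environment can anchor on
    best <- NULL
    for (k in 0:19) {
      to <- simulateTreeAndOptima(cfg$nTaxa, cfg$bmRate,
                                  seed = cfg$seed + k,
                                  conservatism = cfg$traitConservatism)
      a <- .anchorClade(to$tree, to$optima, cfg$nicheBreadth)
      if (is.null(a)) next
      if (is.null(best) || a$score < best$anchor$score)
        best <- list(anchor = a, to = to)
      if (a$leak < 0.1 && length(a$tips) >= 0.26 * cfg$nTaxa) break
    }
    if (is.null(best)) stop("no candidate clade found in 20 tree draws")
    if (is.null(a) ||
        !(a$leak < 0.1 && length(a$tips) >= 0.26 * cfg$nTaxa)) {
      warning("no fully isolated clade found; anchoring on the ",
              "best-scoring candidate")
      a <- best$anchor
      to <- best$to
    }
    anchorMu <- a$mu
  } else {
    to <- simulateTreeAndOptima(cfg$nTaxa, cfg$bmRate, seed = cfg$seed,
                                conservatism = cfg$traitConservatism)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)
  taxa <- to$tree$tip.label
  A <- stats::rlnorm(cfg$nTaxa, cfg$abundMu, cfg$abundSigma)
  coords <- .siteGrid(cfg$nSites)
  dgeo <- as.matrix(stats::dist(coords))
  home <- sample.int(cfg$nSites, cfg$nTaxa, replace = TRUE)
  sitePool <- if (cfg$poolFraction < 1) {
    # per-site founder lottery, drawn once and kept for the whole series
    nAvail <- max(2L, round(cfg$poolFraction * cfg$nTaxa))
    t(vapply(seq_len(cfg$nSites), function(s) {
      avail <- numeric(cfg$nTaxa)
      avail[sample.int(cfg$nTaxa, nAvail)] <- 1
      avail
    }, numeric(cfg$nTaxa)))
  } else NULL
  sitePattern <- if (cfg$envPattern == "clusters") {
    # two spatially coherent site clusters at -1 and +1 (times envSd)
    ifelse(coords$x <= stats::median(coords$x), -1, 1)
  } else stats::rnorm(cfg$nSites)           # fixed site identity
  counts <- vector("list", cfg$nTimepoints)
  env <- vector("list", cfg$nTimepoints)
  period <- ifelse(seq_len(cfg$nTimepoints) >= cfg$split, "wet", "dry")
  for (t in seq_len(cfg$nTimepoints)) {
    p <- period[t]
    E <- anchorMu + cfg$envMean[[p]] + cfg$envSd[[p]] * sitePattern +
      stats::rnorm(cfg$nSites, 0, 0.05 * max(cfg$envSd[[p]], 1e-6))
    lam <- matrix(rep(A, each = cfg$nSites), cfg$nSites, cfg$nTaxa)
    if (cfg$selection)
      lam <- lam * exp(-outer(E, to$optima, "-")^2 /
                         (2 * cfg$nicheBreadth^2))
    if (cfg$dispersalDecay > 0)
      lam <- lam * exp(-cfg$dispersalDecay *
                         dgeo[, home, drop = FALSE])
    if (cfg$driftSd > 0)
      lam <- lam * exp(matrix(stats::rnorm(length(lam), 0, cfg$driftSd),
                              nrow(lam)))
    if (!is.null(sitePool)) {
      masked <- lam * sitePool
      # a lottery that wiped a site out entirely falls back to the
      # unmasked expectation (an empty pool is not a community)
      bad <- rowSums(masked) <= 0
      masked[bad, ] <- lam[bad, ]
      lam <- masked
    }
    lam <- lam / rowSums(lam)
    if (cfg$migration > 0)
      lam <- (1 - cfg$migration) * lam +
        cfg$migration * matrix(rep(colMeans(lam), each = cfg$nSites),
                               cfg$nSites)
    cnt <- t(vapply(seq_len(cfg$nSites), function(s)
      as.integer(stats::rmultinom(1, cfg$depth, lam[s, ])),
      integer(cfg$nTaxa)))
    dimnames(cnt) <- list(rownames(coords), taxa)
    counts[[t]] <- cnt
    ed <- data.frame(env1 = E, row.names = rownames(coords))
    if (cfg$nNuisanceEnv > 0)
      for (k in seq_len(cfg$nNuisanceEnv))
        ed[[paste0("nuisance", k)]] <- stats::rnorm(cfg$nSites)
    env[[t]] <- ed
  }
  new("SimulatedMetacommunity",
      counts = counts, timepoints = paste0("t", seq_len(cfg$nTimepoints)),
      period = period, tree = to$tree, env = env, coords = coords,
      optima = to$optima, scenario = "custom", config = unclass(cfg))
}

#' Canonical five-process scenario suite
#'
#' One scenario per assembly process of the quantitative process
#' estimates, each built so that the intended process dominates the
#' eligible site pairs, plus a composite `"dry-wet shift"` scenario whose
#' among-site environmental variance collapses at the split: a spread
#' environmental gradient (variable selection and drift) in the dry
#' period, then a homogeneous environment anchored on one clade (strong
#' homogeneous selection) in the wet period.
#'
#' * `variable selection`: two site clusters with environmental values
#'   several niche breadths apart, strong filtering.
#' * `homogeneous selection`: identical environment at every site,
#'   anchored on a compact clade of the (niche-conserved) phylogeny and
#'   combined with per-site founder lotteries, so every site assembles a
#'   different subset of the same phylogenetically coherent pool.
#' * `dispersal limitation`: selection off, strong distance decay of
#'   colonist weights around per-taxon home sites.
#' * `homogenizing dispersal`: selection off, full mixing with the
#'   regional pool (`migration = 1`).
#' * `drift`: selection off, independent per-site log-normal demographic
#'   noise.
#'
#' @param seed master seed; each scenario derives its own sub-seed.
#' @param nSites,nTaxa,depth,nTimepoints,split series dimensions shared
#'   by all scenarios.
#' @return named list of [SimulatedMetacommunity-class] objects.
#' @export
makeScenarioSuite <- function(seed = 1L, nSites = 16, nTaxa = 200,
                              depth = 2000, nTimepoints = 2, split = 2) {
  base <- function(name, ...) {
    cfg <- scenarioConfig(nSites = nSites, nTaxa = nTaxa, depth = depth,
                          nTimepoints = nTimepoints, split = split,
                          seed = stageSeed(seed, name), ...)
    sim <- simulateMetacommunity(cfg)
    sim@scenario <- name
    sim
  }
  list(
    "variable selection" = base("variable selection",
      bmRate = 9, nicheBreadth = 0.6, envPattern = "clusters",
      envMean = c(dry = 0, wet = 0), envSd = c(dry = 2, wet = 2)),
    "homogeneous selection" = base("homogeneous selection",
      bmRate = 25, traitConservatism = 0.15, nicheBreadth = 0.4,
      abundSigma = 0.25, poolFraction = 0.53, anchorClade = TRUE,
      envMean = c(dry = 0, wet = 0), envSd = c(dry = 0, wet = 0)),
    "dispersal limitation" = base("dispersal limitation",
      selection = FALSE, dispersalDecay = 3),
    "homogenizing dispersal" = base("homogenizing dispersal",
      selection = FALSE, migration = 1),
    "drift" = base("drift",
      selection = FALSE, driftSd = 0.25),
    "dry-wet shift" = base("dry-wet shift",
      bmRate = 25, traitConservatism = 0.15, nicheBreadth = 0.4,
      abundSigma = 0.25, poolFraction = 0.53, anchorClade = TRUE,
      envPattern = "clusters",
      envMean = c(dry = 0, wet = 0), envSd = c(dry = 3, wet = 0))
  )
}

#' Neutral calibration scenario
#'
#' Selection, dispersal limitation and homogenizing mixing all off, with
#' strong independent demographic stochasticity per site (as expected
#' for drift-dominated assembly in small, isolated habitats): every site
#' is a multinomial draw around its own noisy realization of the shared
#' regional pool. Used to check that betaNTI and the incidence
#' Raup-Crick are centred when no deterministic process operates.
#'
#' @inheritParams makeScenarioSuite
#' @export
neutralScenario <- function(seed = 1L, nSites = 16, nTaxa = 200,
                            depth = 2000, nTimepoints = 1, split = 2) {
  cfg <- scenarioConfig(nSites = nSites, nTaxa = nTaxa, depth = depth,
                        nTimepoints = nTimepoints, split = split,
                        seed = stageSeed(seed, "neutral"),
                        selection = FALSE, driftSd = 3)
  sim <- simulateMetacommunity(cfg)
  sim@scenario <- "neutral"
  sim
}

#' Derive a deterministic sub-seed from a master seed and a stage name
#'
#' Stage-level reproducibility survives pipeline edits: the sub-stream of
#' a stage depends only on the master seed and the stage's name.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return an integer in `[0, 2^31)`.
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 69621) %% 2147483647)
}
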