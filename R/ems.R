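#' Ordinate an incidence matrix by reciprocal averaging
#'
#' Permutes sites (rows) and OTUs (columns) by their first-axis
#' correspondence-analysis scores — the reciprocal-averaging ordination
#' the elements-of-metacommunity-structure framework prescribes. Empty
#' rows and columns are removed first. The axis sign is fixed so that row
#' scores correlate non-negatively with the input row order (pure
#' convention; every EMS statistic is invariant to axis reflection).
#'
#' @param inc site-by-OTU 0/1 matrix.
#' @param warnEmpty warn when empty rows/columns are dropped.
#' @return the permuted incidence matrix, with attributes `rowOrder` and
#'   `colOrder` giving the permutation of the retained rows/columns.
#' @export
ordinateMatrix <- function(inc, warnEmpty = TRUE) {
  keepR <- rowSums(inc) > 0
  keepC <- colSums(inc) > 0
  if (warnEmpty && (!all(keepR) || !all(keepC)))
    warning("dropping ", sum(!keepR), " empty rows and ", sum(!keepC),
            " empty columns before ordination")
  inc <- inc[keepR, keepC, drop = FALSE]
  if (nrow(inc) < 2 || ncol(inc) < 2)
    stop("ordination needs at least 2 non-empty rows and columns")
  sc <- .caScores(inc)
  ro <- order(sc$row, seq_len(nrow(inc)))
  co <- order(sc$col, seq_len(ncol(inc)))
  out <- inc[ro, co, drop = FALSE]
  attr(out, "rowOrder") <- ro
  attr(out, "colOrder") <- co
  out
}

# first-axis correspondence analysis scores via the chi-square SVD
.caScores <- function(x) {
  P <- x / sum(x)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / outer(sqrt(r), sqrt(cc))
  sv <- svd(S)
  if (sv$d[1] < 1e-12) {
    # degenerate (e.g. all-ones) matrix: keep input order
    return(list(row = seq_len(nrow(x)), col = seq_len(ncol(x))))
  }
  rs <- sv$u[, 1] / sqrt(r)
  cs <- sv$v[, 1] / sqrt(cc)
  # deterministic reflection
  if (stats::cor(rs, seq_along(rs)) < 0) {
    rs <- -rs
    cs <- -cs
  }
  list(row = rs, col = cs)
}

#' Count embedded absences in an ordinated incidence matrix
#'
#' An embedded absence is a 0 lying strictly inside the first-to-last
#' occurrence span of a column (a gap in a species' range over the ordered
#' sites) or, in the default `"both"` mode, also of a row (a gap in a
#' site's species range). The count is the EMS coherence statistic.
#'
#' @param inc ordinated 0/1 matrix (see [ordinateMatrix()]).
#' @param mode count gaps over `"both"` axes (canonical) or `"columns"`
#'   only.
#' @return integer gap count.
#' @export
countEmbeddedAbsences <- function(inc, mode = c("both", "columns")) {
  mode <- match.arg(mode)
  n <- .gapCount(inc)
  if (mode == "both") n <- n + .gapCount(t(inc))
  n
}

.gapCount <- function(x) {
  tot <- 0L
  for (j in seq_len(ncol(x))) {
    occ <- which(x[, j] > 0)
    if (length(occ) > 1)
      tot <- tot + (occ[length(occ)] - occ[1] + 1L) - length(occ)
  }
  as.integer(unname(tot))
}

# fill range gaps per column (the "range perspective")
.fillRanges <- function(inc) {
  for (j in seq_len(ncol(inc))) {
    occ <- which(inc[, j] > 0)
    if (length(occ) > 1) inc[occ[1]:occ[length(occ)], j] <- 1L
  }
  inc
}

# column range limits of a filled, ordinated matrix
.rangeLimits <- function(inc) {
  lo <- hi <- integer(ncol(inc))
  for (j in seq_len(ncol(inc))) {
    occ <- which(inc[, j] > 0)
    lo[j] <- occ[1]
    hi[j] <- occ[length(occ)]
  }
  list(lo = lo, hi = hi)
}

#' Coherence test against the fixed-proportional (r1) null
#'
#' Ordinates the matrix, counts embedded absences, and compares the count
#' with a null distribution of r1 matrices (site richness fixed; species
#' drawn with probability proportional to their occurrence frequency),
#' each re-ordinated before counting. z = (null mean - observed)/null sd,
#' so fewer gaps than expected (coherent species distributions) is
#' positive and a checkerboard-like excess of gaps is negative.
#'
#' @param inc site-by-OTU 0/1 matrix.
#' @param reps number of null matrices (>= 99).
#' @param seed integer seed for the null stream.
#' @param mode gap counting mode, see [countEmbeddedAbsences()].
#' @param exactP also report the rank-based two-tailed p (`pExact`).
#' @return list with `observed`, `nullMean`, `nullSd`, `z`, `p` (normal
#'   approximation, two-tailed) and optionally `pExact`.
#' @export
coherence <- function(inc, reps = 999, seed = 1L, mode = "both",
                      exactP = FALSE) {
  if (reps < 99) stop("coherence null needs reps >= 99")
  ordObs <- ordinateMatrix(inc, warnEmpty = FALSE)
  obs <- countEmbeddedAbsences(ordObs, mode = mode)
  inc2 <- inc[rowSums(inc) > 0, colSums(inc) > 0, drop = FALSE]
  nm <- vegan::nullmodel(inc2, "r1")
  sims <- stats::simulate(nm, nsim = reps, seed = seed)
  nullStat <- vapply(seq_len(reps), function(k) {
    countEmbeddedAbsences(ordinateMatrix(sims[, , k], warnEmpty = FALSE),
                          mode = mode)
  }, numeric(1))
  .zTest(obs, nullStat, sign = "coherence", exactP = exactP)
}

.zTest <- function(obs, nullStat, sign = c("coherence", "turnover"),
                   exactP = FALSE) {
  sign <- match.arg(sign)
  mu <- mean(nullStat)
  sdv <- stats::sd(nullStat)
  if (!is.finite(sdv) || sdv == 0) {
    warning("degenerate null distribution (sd = 0); z undefined")
    z <- NA_real_
    p <- NA_real_
  } else {
    z <- if (sign == "coherence") (mu - obs) / sdv else (obs - mu) / sdv
    p <- 2 * stats::pnorm(-abs(z))
  }
  out <- list(observed = obs, nullMean = mu, nullSd = sdv, z = z, p = p)
  if (exactP) {
    reps <- length(nullStat)
    lo <- (sum(nullStat <= obs) + 1) / (reps + 1)
    hi <- (sum(nullStat >= obs) + 1) / (reps + 1)
    out$pExact <- min(1, 2 * min(lo, hi))
  }
  out
}

# species replacements between all site pairs of a filled, ordinated
# matrix: for species ranges R1, R2 (intervals over ordered sites) the
# pair contributes |R1 \ R2| * |R2 \ R1|
.replacements <- function(lo, hi) {
  n <- length(lo)
  if (n < 2) return(0)
  len <- hi - lo + 1
  tot <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    ov <- pmax(0, pmin(hi[i], hi[j]) - pmax(lo[i], lo[j]) + 1)
    tot <- tot + sum((len[i] - ov) * (len[j] - ov))
  }
  tot
}

#' Species turnover test against a range-shift null
#'
#' Applied to the ordinated matrix with species ranges filled (embedded
#' absences set to 1). The observed statistic counts species replacements:
#' over all species pairs and site pairs, the combinations in which each
#' species' range includes exactly one site of the pair, different ones.
#' The null relocates each species' filled range block uniformly among the
#' ordered sites, preserving its length (the Leibold-Mikkelson range-shift
#' randomization). z = (observed - null mean)/null sd: positive z means an
#' excess of replacements, negative z nested species loss.
#'
#' @inheritParams coherence
#' @return list as in [coherence()].
#' @export
turnover <- function(inc, reps = 999, seed = 1L, exactP = FALSE) {
  if (reps < 99) stop("turnover null needs reps >= 99")
  ordObs <- ordinateMatrix(inc, warnEmpty = FALSE)
  filled <- .fillRanges(ordObs)
  rl <- .rangeLimits(filled)
  obs <- .replacements(rl$lo, rl$hi)
  n <- nrow(filled)
  len <- rl$hi - rl$lo + 1
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nullStat <- vapply(seq_len(reps), function(k) {
    lo <- vapply(len, function(L) sample.int(n - L + 1L, 1L), integer(1))
    .replacements(lo, lo + len - 1L)
  }, numeric(1))
  .zTest(obs, nullStat, sign = "turnover", exactP = exactP)
}

#' Boundary clumping: Morisita's index over range boundaries
#'
#' Counts, for each ordered site, the number of species range boundaries
#' falling there (both the first and the last site of each filled range
#' contribute one boundary) and summarizes their clustering with
#' Morisita's index `I = S * sum(b*(b-1)) / (B*(B-1))` where `S` is the
#' number of ordered sites and `B = sum(b)`. `I > 1` indicates clumped
#' boundaries, `I < 1` over-dispersed boundaries; a chi-square test of the
#' boundary counts against a uniform distribution gives the p-value.
#'
#' @param inc ordinated 0/1 matrix (ranges are filled internally).
#' @return list with `index`, `boundaries` (per-site counts), `chisq`,
#'   `df`, `p`.
#' @export
morisitaBoundary <- function(inc) {
  filled <- .fillRanges(inc)
  rl <- .rangeLimits(filled)
  S <- nrow(filled)
  b <- tabulate(c(rl$lo, rl$hi), nbins = S)
  B <- sum(b)
  if (B < 2) {
    warning("fewer than 2 range boundaries; Morisita index undefined")
    return(list(index = NA_real_, boundaries = b, chisq = NA_real_,
                df = NA_integer_, p = NA_real_))
  }
  I <- S * sum(b * (b - 1)) / (B * (B - 1))
  ch <- suppressWarnings(stats::chisq.test(b, p = rep(1 / S, S)))
  list(index = I, boundaries = b, chisq = unname(ch$statistic),
       df = unname(ch$parameter), p = ch$p.value)
}

#' Classify a metacommunity from its EMS tests
#'
#' Implements the hierarchical decision tree over coherence, turnover and
#' boundary clumping (Presley-style): significantly negative coherence is
#' a checkerboard; non-significant coherence is random; positive coherence
#' branches on the turnover z sign/significance (negative = nested species
#' loss, positive = species replacements, non-significant = the "quasi"
#' variants) and on Morisita's index (clumped / random / over-dispersed
#' boundaries).
#'
#' @param result an [EMSResult-class] or a list with elements `coherence`,
#'   `turnover`, `clumping` as produced by the corresponding functions.
#' @param alpha significance level (two-tailed z threshold
#'   `qnorm(1 - alpha/2)`, i.e. 1.96 at the default 0.05).
#' @return a single type label.
#' @export
classifyMetacommunity <- function(result, alpha = 0.05) {
  if (is(result, "EMSResult"))
    result <- list(coherence = result@coherence, turnover = result@turnover,
                   clumping = result@clumping)
  need <- c("coherence", "turnover", "clumping")
  if (!all(need %in% names(result)) ||
      any(vapply(result[need], function(x) is.null(x$z %||% x$index),
                 logical(1))))
    stop("classification needs coherence, turnover and clumping results")
  zcrit <- stats::qnorm(1 - alpha / 2)
  zc <- result$coherence$z
  if (is.na(zc)) return("indeterminate")
  if (zc < -zcrit) return("checkerboard")
  if (abs(zc) <= zcrit) return("random")
  zt <- result$turnover$z
  I <- result$clumping$index
  pI <- result$clumping$p
  clump <- if (is.na(I) || is.na(pI) || pI >= alpha) "random"
           else if (I > 1) "clumped" else "over-dispersed"
  if (is.na(zt)) return("indeterminate")
  if (zt < -zcrit)
    return(paste0("nested (", clump, " species loss)"))
  if (zt > zcrit)
    return(switch(clump, clumped = "Clementsian",
                  `over-dispersed` = "evenly spaced", "Gleasonian"))
  if (zt <= 0)
    return(paste0("quasi-nested (", clump, " species loss)"))
  switch(clump, clumped = "quasi-Clementsian",
         `over-dispersed` = "quasi-evenly spaced", "quasi-Gleasonian")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full elements-of-metacommunity-structure analysis
#'
#' Runs ordination, coherence, turnover and boundary clumping on one
#' incidence matrix and classifies the metacommunity type.
#'
#' @param inc site-by-OTU 0/1 matrix (counts are accepted and converted).
#' @param reps null-model replicates for coherence and turnover.
#' @param seed integer seed.
#' @param alpha significance level for classification.
#' @param mode embedded-absence counting mode.
#' @return an [EMSResult-class].
#' @export
emsAnalysis <- function(inc, reps = 999, seed = 1L, alpha = 0.05,
                        mode = "both") {
  inc <- (inc > 0) * 1L
  inc <- inc[rowSums(inc) > 0, colSums(inc) > 0, drop = FALSE]
  coh <- coherence(inc, reps = reps, seed = seed, mode = mode)
  trn <- turnover(inc, reps = reps, seed = seed + 1L)
  clp <- morisitaBoundary(ordinateMatrix(inc, warnEmpty = FALSE))
  res <- new("EMSResult", coherence = coh, turnover = trn, clumping = clp,
             meta = list(reps = reps, seed = seed, null = "r1",
                         turnoverNull = "range-shift", mode = mode))
  res@type <- classifyMetacommunity(res, alpha = alpha)
  res
}
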