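#' Incidence-based Raup-Crick beta-diversity for one site pair
#'
#' Compares the observed number of shared taxa with a null in which each
#' community is reassembled by drawing its observed richness from the
#' species pool without replacement, with probability proportional to
#' pool occurrence frequency (or uniformly). Scaled to `[-1, 1]`:
#' `beta_RC = 2 * ((#[shared_null > shared_obs] + 0.5 * ties) / reps) - 1`,
#' so values near -1 mean the two communities share more taxa than chance
#' (deterministically similar), values near +1 fewer (deterministically
#' dissimilar), and values near 0 stochastic assembly.
#'
#' @param a,b incidence (0/1) vectors over the same taxon pool.
#' @param poolFreq per-taxon occurrence counts defining the pool and the
#'   sampling weights; taxa with zero frequency are excluded from draws.
#' @param reps null replicates (>= 999 recommended for reported results).
#' @param weighting `"occurrence-frequency"` (default) or `"uniform"`.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return a number in `[-1, 1]`.
#' @export
betaRCPair <- function(a, b, poolFreq, reps = 999,
                       weighting = c("occurrence-frequency", "uniform"),
                       seed = NULL) {
  weighting <- match.arg(weighting)
  pool <- which(poolFreq > 0)
  n1 <- sum(a > 0)
  n2 <- sum(b > 0)
  if (n1 < 1 || n2 < 1) stop("both communities must have richness >= 1")
  if (any((a > 0 | b > 0) & poolFreq == 0))
    stop("pool must cover both communities")
  if (n1 > length(pool) || n2 > length(pool))
    stop("community richness exceeds pool size")
  obs <- sum(a > 0 & b > 0)
  w <- if (weighting == "uniform") NULL else poolFreq[pool]
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  npool <- length(pool)
  gt <- eq <- 0L
  memb <- logical(npool)
  for (r in seq_len(reps)) {
    s1 <- sample.int(npool, n1, prob = w)
    s2 <- sample.int(npool, n2, prob = w)
    memb[s1] <- TRUE
    sh <- sum(memb[s2])
    memb[s1] <- FALSE
    if (sh > obs) gt <- gt + 1L else if (sh == obs) eq <- eq + 1L
  }
  2 * ((gt + 0.5 * eq) / reps) - 1
}

#' Incidence Raup-Crick beta-diversity matrix
#'
#' Computes [betaRCPair()] for every site pair of one incidence matrix.
#' The pool is all OTUs present at at least one site of the matrix (the
#' per-time-point pool), with occurrence frequencies taken across its
#' sites.
#'
#' @param inc site-by-OTU incidence (counts accepted and converted).
#' @inheritParams betaRCPair
#' @return symmetric matrix with zero diagonal; the mean over the lower
#'   triangle is attached as attribute `meanBetaRC`.
#' @export
betaRCMatrix <- function(inc, reps = 999,
                         weighting = c("occurrence-frequency", "uniform"),
                         seed = 1L) {
  weighting <- match.arg(weighting)
  inc <- (inc > 0) * 1L
  nonEmpty <- rowSums(inc) > 0
  if (sum(nonEmpty) < 2) stop("need at least 2 non-empty sites")
  inc <- inc[nonEmpty, , drop = FALSE]
  freq <- colSums(inc)
  n <- nrow(inc)
  out <- matrix(0, n, n, dimnames = list(rownames(inc), rownames(inc)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- betaRCPair(inc[i, ], inc[j, ], freq, reps = reps,
                      weighting = weighting, seed = NULL)
      out[i, j] <- out[j, i] <- v
    }
  }
  attr(out, "meanBetaRC") <- mean(out[lower.tri(out)])
  out
}

#' Interpret a Raup-Crick value
#'
#' Thresholds at +/-0.95: values below -0.95 indicate deterministic
#' assembly towards similarity, above +0.95 deterministic assembly
#' towards dissimilarity, and values in between stochastic assembly.
#'
#' @param value a number (or vector) in `[-1, 1]`.
#' @return character vector over
#'   `{"stochastic", "deterministic-similar", "deterministic-dissimilar"}`.
#' @export
interpretBetaRC <- function(value) {
  if (any(value < -1 | value > 1, na.rm = TRUE))
    stop("Raup-Crick values must lie in [-1, 1]")
  ifelse(value < -0.95, "deterministic-similar",
         ifelse(value > 0.95, "deterministic-dissimilar", "stochastic"))
}
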