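#' Attribute the dispersal-limitation fraction: spatial and environmental
#' Mantel tests per time point
#'
#' For each time point, correlates the abundance-based Raup-Crick
#' dissimilarities (beta_RCbray) with geographic distances (Euclidean on
#' site coordinates) and with environmental distances (Euclidean on
#' standardized variables). A significant geographic correlation supports
#' true dispersal limitation; a significant environmental correlation
#' supports selection by factors without phylogenetic signal
#' ("phylogenetically non-conserved selection"). When both are
#' significant at a time point, both partial Mantel tests (each with the
#' other matrix as covariate) are run to separate spatially
#' autocorrelated environmental variation from pure distance effects.
#'
#' @param brcList list of per-time-point beta_RCbray matrices (site
#'   labels matching `coords`).
#' @param coords data.frame with columns `x`, `y` (one row per site).
#' @param envList list of per-time-point environmental data.frames (or a
#'   single data.frame reused for all time points).
#' @param alpha significance level.
#' @param reps Mantel permutations.
#' @param seed integer seed (one sub-seed per time point and test).
#' @return data.frame, one row per time point: Mantel r and p against
#'   geographic and environmental distance, partial r and p (NA unless
#'   both plain tests are significant), and logical support flags.
#' @export
attributeDispersalFraction <- function(brcList, coords, envList,
                                       alpha = 0.05, reps = 999,
                                       seed = 1L) {
  if (is.data.frame(envList))
    envList <- rep(list(envList), length(brcList))
  if (length(envList) != length(brcList))
    stop("need one environmental table per time point")
  dgeo <- as.matrix(stats::dist(coords[, c("x", "y")]))
  rows <- lapply(seq_along(brcList), function(t) {
    brc <- as.matrix(brcList[[t]])
    sites <- rownames(brc)
    dg <- dgeo[sites, sites]
    denv <- as.matrix(stats::dist(scale(envList[[t]][sites, ,
                                                     drop = FALSE])))
    mg <- mantelTest(brc, dg, reps = reps,
                     seed = stageSeed(seed, paste0("geo", t)))
    me <- mantelTest(brc, denv, reps = reps,
                     seed = stageSeed(seed, paste0("env", t)))
    both <- mg$p < alpha && me$p < alpha
    pg <- pe <- list(statistic = NA_real_, p = NA_real_)
    if (both) {
      pg <- partialMantelTest(brc, dg, denv, reps = reps,
                              seed = stageSeed(seed, paste0("pgeo", t)))
      pe <- partialMantelTest(brc, denv, dg, reps = reps,
                              seed = stageSeed(seed, paste0("penv", t)))
    }
    data.frame(timepoint = t, rGeo = mg$statistic, pGeo = mg$p,
               rEnv = me$statistic, pEnv = me$p,
               rGeoPartial = pg$statistic, pGeoPartial = pg$p,
               rEnvPartial = pe$statistic, pEnvPartial = pe$p,
               geoSignificant = mg$p < alpha,
               envSignificant = me$p < alpha)
  })
  do.call(rbind, rows)
}

#' Per-site temporal composition shift (dry vs wet)
#'
#' For every site with at least two samples per period, tests whether the
#' site's community composition over time differs between the dry and
#' wet period (PERMANOVA on Bray-Curtis among that site's time samples)
#' and whether its within-period dispersion differs (PERMDISP). Each time
#' point is treated as one multivariate observation of the site. Low
#' per-site turnover despite an environmental shift is the signature of
#' historical contingency (e.g. priority effects).
#'
#' @param series a [MetacommunitySeries-class].
#' @param alpha significance level.
#' @param reps permutations.
#' @param seed integer seed.
#' @return list with `table` (per-site F and p for both tests),
#'   `nShifted`, `nTested` and `summary` (a "k out of n" string).
#' @export
perSiteTemporalShift <- function(series, alpha = 0.05, reps = 999,
                                 seed = 1L) {
  per <- periods(series)
  if (min(table(factor(per, c("dry", "wet")))) < 2)
    stop("each period needs at least 2 time points")
  sites <- siteIds(series)
  nt <- nTimepoints(series)
  rows <- list()
  for (s in sites) {
    m <- t(vapply(seq_len(nt), function(k) countsAt(series, k)[s, ],
                  numeric(length(otuIds(series)))))
    rownames(m) <- paste0("t", seq_len(nt))
    keep <- rowSums(m) > 0
    if (min(table(factor(per[keep], c("dry", "wet")))) < 2) {
      message("skipping site ", s, ": fewer than 2 samples per period")
      next
    }
    d <- brayCurtis(m[keep, , drop = FALSE])
    pa <- permanova(d, per[keep], reps = reps,
                    seed = stageSeed(seed, paste0("pa", s)))
    pd <- permdisp(d, per[keep], reps = reps,
                   seed = stageSeed(seed, paste0("pd", s)))
    rows[[s]] <- data.frame(site = s, Fpermanova = pa$statistic,
                            pPermanova = pa$p, Fpermdisp = pd$statistic,
                            pPermdisp = pd$p,
                            shifted = pa$p < alpha)
  }
  tab <- do.call(rbind, rows)
  nShifted <- sum(tab$shifted)
  list(table = tab, nShifted = nShifted, nTested = nrow(tab),
       summary = sprintf("%d out of %d", nShifted, nrow(tab)))
}

#' Verdict on the dispersal-limitation-or-historical-contingency fraction
#'
#' Deterministic rule table over the attribution evidence: if the
#' geographic Mantel correlation is significant at more than
#' `mantelMajority` of the time points, true dispersal limitation is
#' supported; else if the environmental Mantel correlation is, selection
#' by phylogenetically non-conserved factors is supported; otherwise the
#' per-site temporal turnover decides between historical contingency
#' (at most `shiftThreshold` of sites shifted composition between the
#' periods — communities resist the environmental shift, as priority
#' effects would make them) and unmeasured factors (most sites shifted).
#'
#' @param mantelReport data.frame from [attributeDispersalFraction()].
#' @param siteShift list from [perSiteTemporalShift()].
#' @param shiftThreshold proportion of shifted sites separating
#'   "historical contingency" from "unmeasured factors" (default 0.5).
#' @param mantelMajority proportion of time points whose Mantel test must
#'   be significant to count as support (default 0.5).
#' @return list with `verdict` (one of `"dispersal limitation
#'   supported"`, `"non-conserved selection supported"`, `"historical
#'   contingency plausible"`, `"unmeasured factors plausible"`) and
#'   `evidence` (named lines).
#' @export
assemblyVerdict <- function(mantelReport, siteShift,
                            shiftThreshold = 0.5, mantelMajority = 0.5) {
  nT <- nrow(mantelReport)
  fGeo <- mean(mantelReport$geoSignificant)
  fEnv <- mean(mantelReport$envSignificant)
  fShift <- siteShift$nShifted / siteShift$nTested
  verdict <- if (fGeo > mantelMajority) {
    "dispersal limitation supported"
  } else if (fEnv > mantelMajority) {
    "non-conserved selection supported"
  } else if (fShift <= shiftThreshold) {
    "historical contingency plausible"
  } else {
    "unmeasured factors plausible"
  }
  list(verdict = verdict,
       evidence = c(
         geographicMantel = sprintf(
           "geographic Mantel significant at %d of %d time points",
           sum(mantelReport$geoSignificant), nT),
         environmentalMantel = sprintf(
           "environmental Mantel significant at %d of %d time points",
           sum(mantelReport$envSignificant), nT),
         siteShifts = sprintf(
           "%s sites shifted composition between periods",
           siteShift$summary)))
}
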