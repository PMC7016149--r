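#' Beta mean-nearest-taxon distance between two communities
#'
#' `betaMNTD = 0.5 * (sum_i f_ia * min_j d_ij + sum_j f_jb * min_i d_ij)`
#' where `f` are within-site relative abundances and `d` patristic
#' distances; each taxon of one community contributes the distance to its
#' phylogenetically nearest taxon in the other community. With
#' `weighted = FALSE` every present taxon gets equal weight `1/richness`,
#' reducing the statistic to the unweighted mean nearest-taxon distance.
#'
#' @param a,b abundance vectors named by OTU (or aligned with `pd`).
#' @param pd symmetric patristic distance matrix covering all taxa present
#'   in `a` or `b`.
#' @param weighted use relative-abundance weights (default TRUE).
#' @return a non-negative number; 0 for identical supports with matching
#'   nearest neighbours (in particular for identical communities).
#' @export
betaMNTD <- function(a, b, pd, weighted = TRUE) {
  if (is.null(names(a)) || is.null(names(b))) {
    if (length(a) != nrow(pd) || length(b) != nrow(pd))
      stop("unnamed abundance vectors must align with the distance matrix")
    names(a) <- names(b) <- rownames(pd)
  }
  if (!setequal(names(a), names(b)))
    stop("a and b must be defined over the same taxon set")
  if (sum(a) == 0 || sum(b) == 0) stop("communities must be non-empty")
  supp <- union(names(a)[a > 0], names(b)[b > 0])
  miss <- setdiff(supp, rownames(pd))
  if (length(miss))
    stop("taxa missing from the distance matrix: ",
         paste(miss, collapse = ", "))
  rel <- rbind(.relWeights(a[supp], weighted),
               .relWeights(b[supp], weighted))
  cpp_bmntd(unname(rel), pd[supp, supp, drop = FALSE])[1, 2]
}

.relWeights <- function(x, weighted) {
  if (weighted) x / sum(x) else (x > 0) / sum(x > 0)
}

# align matrix OTUs with tree tips per the prune policy
.alignTree <- function(m, tree, prune) {
  miss <- setdiff(colnames(m), tree$tip.label)
  if (length(miss)) {
    if (!prune)
      stop("OTUs absent from the tree: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5),
           "; set prune = TRUE to drop them")
    m <- m[, setdiff(colnames(m), miss), drop = FALSE]
  }
  extra <- setdiff(tree$tip.label, colnames(m))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  list(m = m, tree = tree)
}

#' Beta nearest-taxon index (betaNTI) for all site pairs
#'
#' Standardized effect size of betaMNTD against a tip-shuffle null:
#' taxon identities are permuted across the tips of the phylogeny
#' (equivalently, the patristic matrix labels are permuted) and betaMNTD
#' recomputed per replicate;
#' `betaNTI = (observed - null mean) / null sd` per pair. Values > +2
#' indicate variable selection, < -2 homogeneous selection.
#'
#' @param m site-by-OTU count matrix.
#' @param tree rooted `phylo` covering the matrix OTUs (extra tips are
#'   pruned; missing OTUs raise an error unless `prune = TRUE`, which
#'   drops them from the matrix).
#' @param reps null replicates (>= 99).
#' @param seed integer seed.
#' @param weighted abundance weighting of betaMNTD.
#' @param prune drop matrix OTUs absent from the tree instead of erroring.
#' @return symmetric betaNTI matrix (NA for pairs whose null sd is 0, with
#'   a warning); the observed betaMNTD matrix is attached as attribute
#'   `bMNTD`.
#' @export
betaNTI <- function(m, tree, reps = 999, seed = 1L, weighted = TRUE,
                    prune = FALSE) {
  if (reps < 99) stop("betaNTI null needs reps >= 99")
  al <- .alignTree(m, tree, prune)
  m <- al$m
  pd <- patristicDistances(al$tree)
  pd <- pd[colnames(m), colnames(m)]
  if (any(rowSums(m) == 0)) stop("all-zero site rows present")
  rel <- t(apply(m, 1, .relWeights, weighted = weighted))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perms <- t(replicate(reps, sample.int(ncol(m)))) - 1L
  res <- cpp_bnti_null(rel, pd, perms)
  z <- (res$obs - res$nullMean) / res$nullSd
  # relative threshold: a permutation-invariant pair leaves only
  # floating-point residue in the null sd
  degen <- res$nullSd <= 1e-7 * pmax(res$obs, 1)
  diag(degen) <- FALSE
  if (any(degen)) {
    warning(sum(degen) / 2, " pair(s) with degenerate null (sd = 0); ",
            "betaNTI set to NA")
    z[degen] <- NA_real_
  }
  diag(z) <- 0
  dimnames(z) <- list(rownames(m), rownames(m))
  obs <- res$obs
  dimnames(obs) <- dimnames(z)
  attr(z, "bMNTD") <- obs
  z
}

#' Abundance-based Raup-Crick beta-diversity (beta_RCbray)
#'
#' For each site pair, compares the observed Bray-Curtis dissimilarity
#' with a null in which each community is probabilistically reassembled
#' from the regional pool: its observed richness is drawn without
#' replacement with probability proportional to occurrence frequency,
#' each drawn taxon receives one individual, and the community's
#' remaining observed total abundance is distributed in proportion to
#' regional relative abundances. Scaled to `[-1, 1]`:
#' `2 * ((#[BC_null < BC_obs] + 0.5 * ties) / reps) - 1`, so +1 means the
#' pair is more dissimilar than the null (dispersal limitation or
#' historical contingency), -1 more similar (homogenizing dispersal).
#'
#' @param m site-by-OTU count matrix; the regional pool is all its sites.
#' @param reps null replicates (>= 99).
#' @param seed integer seed.
#' @return symmetric matrix in `[-1, 1]` with zero diagonal.
#' @export
betaRCBray <- function(m, reps = 999, seed = 1L) {
  if (reps < 99) stop("beta_RCbray null needs reps >= 99")
  if (nrow(m) < 2) stop("need at least 2 sites")
  if (any(rowSums(m) == 0)) stop("all-zero site rows present")
  occw <- colSums(m > 0)
  regp <- colSums(m) / sum(m)
  bcObs <- brayCurtis(m)
  rich <- rowSums(m > 0)
  tot <- rowSums(m)
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      bcNull <- cpp_rcbray_null(rich[i], tot[i], rich[j], tot[j],
                                as.numeric(occw), regp, reps)
      lt <- sum(bcNull < bcObs[i, j] - 1e-12)
      eq <- sum(abs(bcNull - bcObs[i, j]) <= 1e-12)
      out[i, j] <- out[j, i] <- 2 * ((lt + 0.5 * eq) / reps) - 1
    }
  }
  out
}

.processLabels <- c("variable selection", "homogeneous selection",
                    "dispersal limitation or historical contingency",
                    "homogenizing dispersal", "drift")

#' Classify site pairs into assembly processes
#'
#' Two-step quantitative process estimate: pairs with `betaNTI > 2` are
#' assembled by variable selection and pairs with `betaNTI < -2` by
#' homogeneous selection; the remaining pairs branch on `beta_RCbray`:
#' `> +0.95` dispersal limitation or historical contingency, `< -0.95`
#' homogenizing dispersal, otherwise drift. Values exactly at a threshold
#' fall to the non-selection / drift side. Pairs with undefined betaNTI
#' (degenerate null) are excluded and counted separately.
#'
#' @param bnti symmetric betaNTI matrix from [betaNTI()].
#' @param brcbray symmetric beta_RCbray matrix from [betaRCBray()], with
#'   identical site labels.
#' @return data.frame with one row per unordered site pair: `site1`,
#'   `site2`, `bNTI`, `bRCbray`, `process` (factor over the five labels,
#'   NA for excluded pairs).
#' @export
classifyPairs <- function(bnti, brcbray) {
  if (is.null(dimnames(bnti)) ||
      !identical(dimnames(bnti), dimnames(brcbray)))
    stop("betaNTI and beta_RCbray matrices must share site labels")
  n <- nrow(bnti)
  idx <- which(lower.tri(bnti), arr.ind = TRUE)
  z <- bnti[idx]
  rc <- brcbray[idx]
  proc <- ifelse(is.na(z), NA_character_,
          ifelse(z > 2, "variable selection",
          ifelse(z < -2, "homogeneous selection",
          ifelse(rc > 0.95, "dispersal limitation or historical contingency",
          ifelse(rc < -0.95, "homogenizing dispersal", "drift")))))
  data.frame(site1 = rownames(bnti)[idx[, 2]],
             site2 = rownames(bnti)[idx[, 1]],
             bNTI = z, bRCbray = rc,
             process = factor(proc, levels = .processLabels),
             stringsAsFactors = FALSE)
}

#' Per-group assembly-process fractions
#'
#' @param cls a classification data.frame from [classifyPairs()], or a
#'   list of them (one per time point).
#' @return data.frame with one row per group: the fraction of eligible
#'   pairs per process (summing to 1) and `nExcluded` pairs with
#'   undefined betaNTI.
#' @export
processFractions <- function(cls) {
  if (is.data.frame(cls)) cls <- list(cls)
  if (is.null(names(cls))) names(cls) <- paste0("t", seq_along(cls))
  rows <- lapply(names(cls), function(g) {
    p <- cls[[g]]$process
    ok <- !is.na(p)
    if (!any(ok)) stop("no eligible pairs in group ", g)
    tab <- table(p[ok]) / sum(ok)
    out <- as.data.frame(as.list(tab), check.names = FALSE)
    cbind(data.frame(group = g, stringsAsFactors = FALSE), out,
          data.frame(nPairs = sum(ok), nExcluded = sum(!ok)))
  })
  do.call(rbind, rows)
}
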