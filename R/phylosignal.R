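#' Abundance-weighted OTU niche values
#'
#' The niche value of an OTU for an environmental variable is the mean of
#' that variable over the sites it occupies, weighted by the OTU's
#' relative abundance across sites:
#' `niche_i = sum_s (x_is / sum_s x_is) * E_s`. OTUs absent from every
#' site are excluded with a message.
#'
#' @param m site-by-OTU count matrix.
#' @param env data.frame of environmental variables (sites as rows,
#'   aligned with `m`).
#' @param variables variables to use (default: all columns of `env`).
#' @return matrix of niche values, OTUs as rows, one column per variable.
#' @examples
#' m <- matrix(c(1L, 3L), 2, 1, dimnames = list(c("s1", "s2"), "o1"))
#' env <- data.frame(temp = c(0, 8), row.names = c("s1", "s2"))
#' otuNiche(m, env)  # 0.25*0 + 0.75*8 = 6
#' @export
otuNiche <- function(m, env, variables = colnames(env)) {
  if (!all(variables %in% colnames(env)))
    stop("variables missing from the environmental table: ",
         paste(setdiff(variables, colnames(env)), collapse = ", "))
  if (!is.null(rownames(m)) && !is.null(rownames(env))) {
    if (!all(rownames(m) %in% rownames(env)))
      stop("environmental table does not cover all sites")
    env <- env[rownames(m), , drop = FALSE]
  }
  empty <- colSums(m) == 0
  if (any(empty)) {
    message("excluding ", sum(empty), " OTU(s) absent from every site")
    m <- m[, !empty, drop = FALSE]
  }
  w <- sweep(m, 2, colSums(m), "/")
  out <- t(w) %*% as.matrix(env[, variables, drop = FALSE])
  colnames(out) <- variables
  out
}

#' Mantel correlogram of niche distance against phylogenetic distance
#'
#' Tests the prerequisite of the quantitative process estimates: that
#' phylogenetic distance carries information about ecological niches.
#' Between-OTU niche distances (Euclidean on the abundance-weighted niche
#' values) are correlated with membership in equal-width phylogenetic
#' distance classes (Mantel correlogram, permutation p-values with
#' progressive Bonferroni correction). A phylogenetic signal is declared
#' when the shortest distance class has a significantly positive Mantel
#' correlation (phylogenetically close OTUs have more similar niches than
#' expected).
#'
#' @param nicheDist symmetric matrix of between-OTU niche distances.
#' @param phyloDist symmetric patristic distance matrix with the same OTU
#'   labels.
#' @param nClasses number of distance classes; `NULL` uses Sturges' rule
#'   on the number of pairs (the correlogram default).
#' @param reps permutations per class.
#' @param seed integer seed.
#' @param alpha significance level for the signal verdict.
#' @return list with `classes` (data.frame: class midpoint, n pairs,
#'   Mantel r, p, corrected p) and `signal` (logical).
#' @export
mantelCorrelogram <- function(nicheDist, phyloDist, nClasses = NULL,
                              reps = 999, seed = 1L, alpha = 0.05) {
  if (!identical(dimnames(nicheDist), dimnames(phyloDist)))
    stop("niche and phylogenetic distance matrices must share labels")
  if (!is.null(nClasses) && nClasses < 3)
    stop("need at least 3 distance classes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mc <- vegan::mantel.correlog(stats::as.dist(nicheDist),
                               D.geo = stats::as.dist(phyloDist),
                               n.class = if (is.null(nClasses)) 0
                                         else nClasses,
                               nperm = reps, mult = "bonferroni",
                               progressive = TRUE)
  cl <- as.data.frame(mc$mantel.res)
  names(cl) <- c("classMid", "nPairs", "r", "p", "pCorrected")
  tested <- which(!is.na(cl$r))
  signal <- length(tested) > 0 &&
    cl$r[tested[1]] > 0 &&
    !is.na(cl$pCorrected[tested[1]]) &&
    cl$pCorrected[tested[1]] < alpha
  list(classes = cl, signal = signal)
}

#' Phylogenetic-signal test from raw inputs
#'
#' Convenience wrapper: computes OTU niche values ([otuNiche()]) for one
#' variable, their Euclidean distances, the patristic distances, and the
#' Mantel correlogram ([mantelCorrelogram()]).
#'
#' @inheritParams otuNiche
#' @param tree rooted `phylo` covering the matrix OTUs.
#' @param variable single environmental variable name.
#' @inheritParams mantelCorrelogram
#' @param prune drop matrix OTUs absent from the tree.
#' @export
phyloSignalTest <- function(m, env, tree, variable, nClasses = NULL,
                            reps = 999, seed = 1L, alpha = 0.05,
                            prune = FALSE) {
  al <- .alignTree(m, tree, prune)
  niche <- otuNiche(al$m, env, variable)
  pd <- patristicDistances(al$tree)[rownames(niche), rownames(niche)]
  nd <- as.matrix(stats::dist(niche))
  mantelCorrelogram(nd, pd, nClasses = nClasses, reps = reps,
                    seed = seed, alpha = alpha)
}
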