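#' Collinearity screen on environmental variables
#'
#' Greedy removal: while any variable pair has Pearson `|r|` above the
#' threshold, the member of the worst pair with the larger mean absolute
#' correlation against everything else is dropped. Constant variables are
#' dropped first with a warning.
#'
#' @param env data.frame of numeric environmental variables.
#' @param threshold `|r|` above which a pair is collinear (default 0.7;
#'   a pair at exactly the threshold is kept).
#' @return list with `retained` and `dropped` variable names.
#' @export
collinearityFilter <- function(env, threshold = 0.7) {
  if (ncol(env) < 2) stop("need at least 2 variables")
  vars <- colnames(env)
  const <- vars[vapply(env, function(v) stats::var(v) == 0, logical(1))]
  if (length(const)) {
    warning("dropping constant variables: ", paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
  }
  dropped <- const
  while (length(vars) > 1) {
    r <- abs(stats::cor(env[, vars, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- vars[worst]
    meanAbs <- rowMeans(r[pair, , drop = FALSE])
    out <- pair[which.max(meanAbs)]
    dropped <- c(dropped, out)
    vars <- setdiff(vars, out)
  }
  list(retained = vars, dropped = dropped)
}

.permResult <- function(statistic, p, permutations, seed, method) {
  structure(list(statistic = statistic, p = p,
                 permutations = permutations, seed = seed,
                 method = method),
            class = "permTestResult")
}

#' @export
print.permTestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%d permutations, seed %s)\n",
              x$method, x$statistic, x$p, x$permutations,
              format(x$seed)))
  invisible(x)
}

#' PERMANOVA (one-factor) on a distance matrix
#'
#' Permutational multivariate analysis of variance: pseudo-F from the
#' distance-based partition of the total sum of squares, with a
#' permutation p-value over group labels (vegan's `adonis2`).
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param groups factor-like group labels, one per object (>= 2 groups,
#'   each with >= 2 members).
#' @param reps permutations.
#' @param seed integer seed.
#' @return a `permTestResult` (statistic = pseudo-F); the R2 is attached
#'   as `$r2`.
#' @export
permanova <- function(d, groups, reps = 999, seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("PERMANOVA needs at least 2 groups")
  if (any(table(groups) < 2))
    stop("every group needs at least 2 members")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(as.matrix(d)) ~ groups,
                        permutations = reps)
  out <- .permResult(fit$F[1], fit$`Pr(>F)`[1], reps, seed, "PERMANOVA")
  out$r2 <- fit$R2[1]
  out
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Principal-coordinate embedding of the distance matrix (with
#' negative-eigenvalue correction), distance of each object to its group
#' centre (spatial median by default, as in vegan's `betadisper`), and a
#' permutation F-test on those distances.
#'
#' @inheritParams permanova
#' @param center `"median"` (spatial median, default) or `"centroid"`.
#' @export
permdisp <- function(d, groups, reps = 999, seed = 1L,
                     center = c("median", "centroid")) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("PERMDISP needs at least 2 groups")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bd <- vegan::betadisper(stats::as.dist(as.matrix(d)), groups,
                          type = center)
  pt <- vegan::permutest(bd, permutations = reps)
  .permResult(pt$tab$F[1], pt$tab$`Pr(>F)`[1], reps, seed, "PERMDISP")
}

#' Mantel and partial Mantel tests
#'
#' Pearson correlation between the lower triangles of two distance
#' matrices, with a permutation p-value obtained by permuting one
#' matrix's labels; the partial variant correlates the residuals after
#' removing a third (covariate) matrix.
#'
#' @param d1,d2,d3 symmetric distance matrices with matching labels
#'   (`d3` is the covariate of the partial test).
#' @inheritParams permanova
#' @return a `permTestResult` (statistic = Mantel r).
#' @export
mantelTest <- function(d1, d2, reps = 999, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(as.matrix(d1)),
                      stats::as.dist(as.matrix(d2)),
                      permutations = reps)
  .permResult(mt$statistic, mt$signif, reps, seed, "Mantel")
}

#' @rdname mantelTest
#' @export
partialMantelTest <- function(d1, d2, d3, reps = 999, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mt <- vegan::mantel.partial(stats::as.dist(as.matrix(d1)),
                              stats::as.dist(as.matrix(d2)),
                              stats::as.dist(as.matrix(d3)),
                              permutations = reps)
  .permResult(mt$statistic, mt$signif, reps, seed, "partial Mantel")
}

#' RDA with alpha-based forward selection of environmental variables
#'
#' Redundancy analysis of a (Hellinger-transformed) community matrix on
#' standardized environmental variables. At each step the candidate
#' adding the most constrained variance is tested by permutation
#' (residuals under the reduced model, vegan's `anova.cca`); it is
#' retained if `p < alpha`, otherwise selection stops.
#'
#' @param Y response matrix (e.g. from [hellingerTransform()]).
#' @param X data.frame of candidate environmental variables.
#' @param alpha retention level (default 0.05).
#' @param reps permutations per test.
#' @param seed integer seed.
#' @param standardize scale `X` to zero mean / unit sd first.
#' @return list with `selected` (ordered names), `steps` (data.frame of
#'   per-step F and p) and `r2` (constrained proportion of the final
#'   model, NA when nothing is selected).
#' @export
rdaForwardSelect <- function(Y, X, alpha = 0.05, reps = 999, seed = 1L,
                             standardize = TRUE) {
  X <- as.data.frame(X)
  if (standardize)
    X[] <- lapply(X, function(v) as.numeric(scale(v)))
  keepVar <- vapply(X, function(v) is.finite(stats::var(v)) &&
                      stats::var(v) > 0, logical(1))
  X <- X[, keepVar, drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  selected <- character()
  steps <- data.frame(variable = character(), F = numeric(),
                      p = numeric())
  repeat {
    cand <- setdiff(colnames(X), selected)
    if (length(cand) == 0 || nrow(Y) <= length(selected) + 2) break
    gain <- vapply(cand, function(v) {
      f <- if (length(selected))
        stats::as.formula(paste("Y ~", v, "+ Condition(",
                                paste(selected, collapse = "+"), ")"))
      else stats::as.formula(paste("Y ~", v))
      mod <- try(vegan::rda(f, data = X), silent = TRUE)
      if (inherits(mod, "try-error")) return(NA_real_)
      mod$CCA$tot.chi
    }, numeric(1))
    if (all(is.na(gain))) break
    best <- cand[which.max(gain)]
    f <- if (length(selected))
      stats::as.formula(paste("Y ~", best, "+ Condition(",
                              paste(selected, collapse = "+"), ")"))
    else stats::as.formula(paste("Y ~", best))
    mod <- vegan::rda(f, data = X)
    an <- stats::anova(mod, permutations = reps)
    Fv <- an$F[1]
    pv <- an$`Pr(>F)`[1]
    if (is.na(pv) || pv >= alpha) break
    selected <- c(selected, best)
    steps <- rbind(steps, data.frame(variable = best, F = Fv, p = pv))
  }
  r2 <- NA_real_
  if (length(selected)) {
    full <- vegan::rda(stats::as.formula(
      paste("Y ~", paste(selected, collapse = "+"))), data = X)
    r2 <- full$CCA$tot.chi / full$tot.chi
  }
  list(selected = selected, steps = steps, r2 = r2)
}

#' Compare period location and spread of a per-time-point metric
#'
#' Kruskal-Wallis test for a location difference and Levene's test
#' (Brown-Forsythe variant, centred on the median) for a spread
#' difference between the dry and wet period values of a metric.
#'
#' @param values numeric vector (one value per time point).
#' @param period `"dry"`/`"wet"` label per value (>= 2 values per
#'   period).
#' @return list with `kruskal` (statistic H, df, p, direction of change
#'   as `"wet > dry"`/`"wet < dry"`) and `levene` (F, p). With all-tied
#'   values the Kruskal-Wallis H is undefined and flagged NA.
#' @export
comparePeriods <- function(values, period) {
  period <- factor(period, levels = c("dry", "wet"))
  if (any(table(period) < 2))
    stop("need at least 2 values per period")
  if (length(unique(values)) == 1) {
    warning("all values tied; Kruskal-Wallis statistic undefined")
    kw <- list(statistic = NA_real_, df = 1L, p = NA_real_,
               direction = "none")
  } else {
    k <- stats::kruskal.test(values, period)
    med <- tapply(values, period, stats::median)
    kw <- list(statistic = unname(k$statistic),
               df = unname(k$parameter), p = k$p.value,
               direction = if (med["wet"] > med["dry"]) "wet > dry"
                           else if (med["wet"] < med["dry"]) "wet < dry"
                           else "none")
  }
  lv <- tryCatch({
    l <- car::leveneTest(values ~ period, center = stats::median)
    list(statistic = l$`F value`[1], p = l$`Pr(>F)`[1])
  }, error = function(e) list(statistic = NA_real_, p = NA_real_))
  list(kruskal = kw, levene = lv)
}
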