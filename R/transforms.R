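#' Rarefy a community matrix to even depth
#'
#' Subsamples each site's counts without replacement to a common depth.
#' Sites whose total is below `depth` are dropped with a warning. The
#' alternative reading of "subsampling" — trimming the OTU registry to the
#' most abundant taxa — is provided by [trimToTopOtus()].
#'
#' @param m site-by-OTU count matrix.
#' @param depth target per-site total (> 0).
#' @param seed integer seed controlling the subsample.
#' @return integer matrix whose retained rows each sum to `depth`.
#' @examples
#' m <- matrix(c(10L, 0L, 0L), 1, 3,
#'             dimnames = list("s1", c("a", "b", "c")))
#' rarefy(m, 5, seed = 1)  # (5, 0, 0)
#' @export
rarefy <- function(m, depth, seed = 1L) {
  if (depth <= 0) stop("rarefaction depth must be positive")
  tot <- rowSums(m)
  low <- tot < depth
  if (any(low)) {
    warning("dropping sites below depth ", depth, ": ",
            paste(rownames(m)[low], collapse = ", "))
    m <- m[!low, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no sites at or above rarefaction depth")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    # rrarefy's small-count heuristic misfires on legitimate low counts
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  out
}

# save/restore the RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Trim a community matrix to its most abundant OTUs
#'
#' @param m site-by-OTU count matrix.
#' @param nOtus number of OTUs to keep, ranked by total abundance
#'   (ties broken by column order).
#' @export
trimToTopOtus <- function(m, nOtus) {
  if (nOtus <= 0 || nOtus > ncol(m)) stop("nOtus out of range")
  keep <- order(colSums(m), decreasing = TRUE)[seq_len(nOtus)]
  m[, sort(keep), drop = FALSE]
}

#' Convert counts to incidence (presence/absence)
#'
#' @param m site-by-OTU count matrix (idempotent on 0/1 input).
#' @return integer 0/1 matrix with the same dimnames. All-zero rows are
#'   kept but flagged with a warning.
#' @export
toIncidence <- function(m) {
  inc <- (m > 0) * 1L
  dimnames(inc) <- dimnames(m)
  if (any(rowSums(inc) == 0))
    warning("incidence matrix has all-zero site rows: ",
            paste(rownames(inc)[rowSums(inc) == 0], collapse = ", "))
  inc
}

#' Pairwise Bray-Curtis dissimilarity
#'
#' @param m site-by-OTU count matrix with no all-zero rows.
#' @return symmetric matrix in `[0, 1]` with a zero diagonal.
#' @export
brayCurtis <- function(m) {
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero site rows: ", paste(rownames(m)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Hellinger transformation
#'
#' Square root of row-relative abundances; each transformed row's squared
#' values sum to 1, making Euclidean-based ordination (RDA, PCA)
#' appropriate for community data.
#'
#' @param m site-by-OTU count matrix with no all-zero rows.
#' @export
hellingerTransform <- function(m) {
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero site rows: ", paste(rownames(m)[zero], collapse = ", "))
  vegan::decostand(m, method = "hellinger")
}
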