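#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib metanull, .registration = TRUE
NULL

#' MetacommunitySeries: a time series of site-by-OTU count matrices
#'
#' The central container of the package. It holds one site-by-OTU count
#' matrix per sampling occasion over a shared OTU registry, a period label
#' (`"dry"` / `"wet"`) per occasion that partitions the series at a single
#' split index, and optionally a rooted phylogeny of the OTUs, per-occasion
#' environmental tables and planar site coordinates.
#'
#' @slot counts list of integer site-by-OTU matrices, one per time point,
#'   all with identical dimnames (sites as rows).
#' @slot timepoints character vector of time-point labels.
#' @slot period character vector, one of `"dry"`/`"wet"` per time point;
#'   all `"dry"` labels must precede all `"wet"` labels.
#' @slot tree a rooted `ape::phylo` whose tips cover the OTU registry, or
#'   `NULL`.
#' @slot env list of per-time-point environmental `data.frame`s (sites as
#'   rows), or an empty list.
#' @slot coords `data.frame` with numeric columns `x`, `y` and one row per
#'   site, or a 0-row `data.frame`.
#'
#' @seealso [metacommunitySeries()], [simulateMetacommunity()]
#' @export
setClass("MetacommunitySeries",
  representation(
    counts = "list",
    timepoints = "character",
    period = "character",
    tree = "ANY",
    env = "list",
    coords = "data.frame"
  ),
  prototype(
    counts = list(), timepoints = character(), period = character(),
    tree = NULL, env = list(), coords = data.frame()
  )
)

setValidity("MetacommunitySeries", function(object) {
  msg <- character()
  nt <- length(object@counts)
  if (length(object@timepoints) != nt)
    msg <- c(msg, "one time-point label per count matrix is required")
  if (length(object@period) != nt)
    msg <- c(msg, "one period label per time point is required")
  if (nt > 0) {
    ref <- dimnames(object@counts[[1]])
    for (k in seq_len(nt)) {
      m <- object@counts[[k]]
      if (!is.matrix(m) || !is.numeric(m))
        msg <- c(msg, sprintf("counts[[%d]] is not a numeric matrix", k))
      else {
        if (any(m < 0) || any(m != round(m)))
          msg <- c(msg, sprintf("counts[[%d]] has negative or non-integer cells", k))
        if (!identical(dimnames(m), ref))
          msg <- c(msg, sprintf("counts[[%d]] dimnames differ from time point 1", k))
      }
    }
    if (!all(object@period %in% c("dry", "wet")))
      msg <- c(msg, "period labels must be 'dry' or 'wet'")
    else if (is.unsorted(match(object@period, c("dry", "wet"))))
      msg <- c(msg, "all 'dry' time points must precede all 'wet' time points")
  }
  if (!is.null(object@tree)) {
    if (!inherits(object@tree, "phylo"))
      msg <- c(msg, "tree must be an ape 'phylo' object or NULL")
    else if (nt > 0 &&
             !all(colnames(object@counts[[1]]) %in% object@tree$tip.label))
      msg <- c(msg, "tree tips must cover the OTU registry")
  }
  if (length(object@env) > 0 && length(object@env) != nt)
    msg <- c(msg, "env must be empty or have one table per time point")
  if (nrow(object@coords) > 0 && nt > 0 &&
      nrow(object@coords) != nrow(object@counts[[1]]))
    msg <- c(msg, "coords must have one row per site")
  if (length(msg)) msg else TRUE
})

#' SimulatedMetacommunity: a MetacommunitySeries with known ground truth
#'
#' Extends [MetacommunitySeries-class] with the generating scenario: the
#' per-taxon environmental optima evolved on the emitted tree, the scenario
#' label, and the full configuration used.
#'
#' @slot optima numeric vector of per-OTU niche optima (environmental units).
#' @slot scenario character scalar naming the generating process.
#' @slot config the [scenarioConfig()] list used.
#' @export
setClass("SimulatedMetacommunity",
  contains = "MetacommunitySeries",
  representation(optima = "numeric", scenario = "character", config = "list")
)

#' EMSResult: elements-of-metacommunity-structure test results
#'
#' Holds the three hierarchical EMS tests for one ordinated incidence
#' matrix — coherence (embedded absences vs an r1 null), species turnover
#' (replacements vs a range-shift null), and boundary clumping (Morisita's
#' index) — together with the derived metacommunity type label.
#'
#' Sign conventions: coherence z = (null mean - observed)/null sd, so
#' fewer gaps than expected (coherent structure) is positive and
#' checkerboard-like excess gaps are negative; turnover
#' z = (observed - null mean)/null sd, so an excess of species
#' replacements is positive and nested species loss is negative.
#'
#' @slot coherence list with `observed`, `nullMean`, `nullSd`, `z`, `p`.
#' @slot turnover list with the same fields for species replacements.
#' @slot clumping list with Morisita index `index`, `chisq`, `df`, `p`.
#' @slot type character metacommunity type label (see
#'   [classifyMetacommunity()]).
#' @slot meta list of analysis metadata (reps, seed, null model, absence
#'   counting mode).
#' @export
setClass("EMSResult",
  representation(coherence = "list", turnover = "list", clumping = "list",
                 type = "character", meta = "list"),
  prototype(type = NA_character_, meta = list())
)

#' @describeIn MetacommunitySeries-class number of time points
#' @param x,object a `MetacommunitySeries`
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))
setMethod("nTimepoints", "MetacommunitySeries", function(x) length(x@counts))

#' Accessors for MetacommunitySeries
#'
#' `countsAt()` returns the site-by-OTU count matrix at time point `k`;
#' `periods()` the per-time-point period labels; `splitIndex()` the index
#' of the first wet time point; `seriesTree()` the phylogeny (or NULL);
#' `envAt()` the environmental table at time point `k`; `siteCoords()` the
#' coordinate table; `siteIds()`/`otuIds()` the axis labels.
#'
#' @param x a [MetacommunitySeries-class]
#' @param k time-point index
#' @return the requested component.
#' @export
setGeneric("countsAt", function(x, k) standardGeneric("countsAt"))
setMethod("countsAt", "MetacommunitySeries", function(x, k) x@counts[[k]])

#' @rdname countsAt
#' @export
setGeneric("periods", function(x) standardGeneric("periods"))
setMethod("periods", "MetacommunitySeries", function(x) x@period)

#' @rdname countsAt
#' @export
setGeneric("splitIndex", function(x) standardGeneric("splitIndex"))
setMethod("splitIndex", "MetacommunitySeries", function(x) {
  w <- which(x@period == "wet")
  if (length(w)) w[1] else length(x@period) + 1L
})

#' @rdname countsAt
#' @export
setGeneric("seriesTree", function(x) standardGeneric("seriesTree"))
setMethod("seriesTree", "MetacommunitySeries", function(x) x@tree)

#' @rdname countsAt
#' @export
setGeneric("envAt", function(x, k) standardGeneric("envAt"))
setMethod("envAt", "MetacommunitySeries", function(x, k) {
  if (length(x@env) == 0) NULL else x@env[[k]]
})

#' @rdname countsAt
#' @export
setGeneric("siteCoords", function(x) standardGeneric("siteCoords"))
setMethod("siteCoords", "MetacommunitySeries", function(x) x@coords)

#' @rdname countsAt
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))
setMethod("siteIds", "MetacommunitySeries", function(x)
  rownames(x@counts[[1]]))

#' @rdname countsAt
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))
setMethod("otuIds", "MetacommunitySeries", function(x)
  colnames(x@counts[[1]]))

setMethod("show", "MetacommunitySeries", function(object) {
  nt <- nTimepoints(object)
  cat(sprintf("%s with %d time points (%d dry, %d wet)\n",
              class(object), nt, sum(object@period == "dry"),
              sum(object@period == "wet")))
  if (nt > 0)
    cat(sprintf("  %d sites x %d OTUs\n", nrow(object@counts[[1]]),
                ncol(object@counts[[1]])))
  cat(sprintf("  tree: %s; env: %s; coords: %s\n",
              if (is.null(object@tree)) "absent" else
                sprintf("%d tips", length(object@tree$tip.label)),
              if (length(object@env)) "per time point" else "absent",
              if (nrow(object@coords)) "present" else "absent"))
  if (is(object, "SimulatedMetacommunity"))
    cat(sprintf("  scenario: %s\n", object@scenario))
  invisible(object)
})

setMethod("show", "EMSResult", function(object) {
  cat("EMSResult\n")
  cat(sprintf("  coherence: obs = %s, z = %.3f, p = %.4g\n",
              format(object@coherence$observed), object@coherence$z,
              object@coherence$p))
  cat(sprintf("  turnover:  obs = %s, z = %.3f, p = %.4g\n",
              format(object@turnover$observed), object@turnover$z,
              object@turnover$p))
  cat(sprintf("  clumping:  Morisita I = %.3f, p = %.4g\n",
              object@clumping$index, object@clumping$p))
  cat(sprintf("  type: %s\n", object@type))
  invisible(object)
})

#' Construct a MetacommunitySeries
#'
#' @param counts list of site-by-OTU count matrices (sites as rows), one
#'   per time point, sharing dimnames. A single matrix is accepted and
#'   wrapped as a one-point series.
#' @param timepoints optional time-point labels (default `t1`, `t2`, ...).
#' @param period per-time-point period labels in `{"dry","wet"}`, or a
#'   single integer `splitIndex` via `split`: time points `>= split` are wet.
#' @param split alternative to `period`: index of the first wet time point.
#' @param tree optional rooted `phylo` covering the OTUs.
#' @param env optional list of per-time-point environmental data.frames.
#' @param coords optional data.frame with columns `x`, `y` (one row per
#'   site).
#' @return a validated [MetacommunitySeries-class].
#' @examples
#' m <- matrix(rpois(12, 4), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("o", 1:4)))
#' metacommunitySeries(list(m, m), split = 2)
#' @export
metacommunitySeries <- function(counts, timepoints = NULL, period = NULL,
                                split = NULL, tree = NULL, env = list(),
                                coords = data.frame()) {
  if (is.matrix(counts)) counts <- list(counts)
  nt <- length(counts)
  if (is.null(timepoints)) timepoints <- paste0("t", seq_len(nt))
  if (is.null(period)) {
    if (is.null(split)) split <- nt + 1L
    period <- ifelse(seq_len(nt) >= split, "wet", "dry")
  }
  counts <- lapply(counts, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  new("MetacommunitySeries", counts = counts, timepoints = timepoints,
      period = period, tree = tree, env = env, coords = coords)
}
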