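#' Run configuration for the full analysis chain
#'
#' @param reps null-model / permutation replicates used by every stage
#'   (>= 99).
#' @param seed master seed; every stage derives its own sub-stream via
#'   [stageSeed()], so adding or removing a stage leaves the others'
#'   results unchanged.
#' @param alpha significance level used throughout.
#' @param stages character vector of stages to run, a subset of
#'   `c("multivariate", "ems", "raupcrick", "qpe", "attribution")`.
#' @param outDir optional output directory for [writeRunReport()].
#' @return a `runConfig` list.
#' @export
runConfig <- function(reps = 999, seed = 1L, alpha = 0.05,
                      stages = c("multivariate", "ems", "raupcrick",
                                 "qpe", "attribution"),
                      outDir = NULL) {
  if (reps < 99) stop("reps must be >= 99")
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(reps = reps, seed = as.integer(seed), alpha = alpha,
                 stages = stages, outDir = outDir),
            class = "runConfig")
}

#' Run the full assembly-inference chain on a metacommunity series
#'
#' Executes, per time point where applicable: (A) period-level
#' environment and community PERMANOVA/PERMDISP plus RDA forward
#' selection of environmental variables; (B) elements of metacommunity
#' structure; (C) incidence Raup-Crick beta-diversity; (D) quantitative
#' process estimates (betaNTI + beta_RCbray + process fractions); (E)
#' the attribution layer (per-time-point Mantel tests of beta_RCbray
#' against geographic and environmental distance, per-site temporal
#' shifts, verdict); and finally the dry-vs-wet comparison of every
#' per-time-point metric ([comparePeriodMetrics()]). A stage that fails
#' is recorded as failed and stages depending on it are skipped; the QPE
#' stage refuses to start without a tree.
#'
#' @param series a [MetacommunitySeries-class].
#' @param config a [runConfig()].
#' @return a `runReport` list with one element per stage plus
#'   `periodComparison`.
#' @export
runFull <- function(series, config = runConfig()) {
  stopifnot(is(series, "MetacommunitySeries"),
            inherits(config, "runConfig"))
  nt <- nTimepoints(series)
  per <- periods(series)
  report <- list(config = list(reps = config$reps, seed = config$seed,
                               alpha = config$alpha,
                               stages = config$stages),
                 stages = list())
  hasEnv <- length(series@env) > 0
  hasCoords <- nrow(siteCoords(series)) > 0
  if ("qpe" %in% config$stages && is.null(seriesTree(series)))
    stop("stage 'qpe' requires a phylogenetic tree on the series")
  runStage <- function(name, fn) {
    if (!(name %in% config$stages)) {
      report$stages[[name]] <<- list(status = "skipped",
                                     reason = "not requested")
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e)
      list(status = "failed", reason = conditionMessage(e)))
    if (is.null(res$status)) res <- c(list(status = "ok"), res)
    report$stages[[name]] <<- res
    invisible(NULL)
  }

  runStage("multivariate", function() {
    out <- list()
    if (hasEnv && length(unique(per)) == 2) {
      envAll <- do.call(rbind, lapply(seq_len(nt), function(k)
        envAt(series, k)))
      grp <- rep(per, times = vapply(seq_len(nt), function(k)
        nrow(envAt(series, k)), integer(1)))
      denv <- as.matrix(stats::dist(scale(envAll)))
      out$envPermanova <- unclass(permanova(
        denv, grp, reps = config$reps,
        seed = stageSeed(config$seed, "envPermanova")))
      out$envPermdisp <- unclass(permdisp(
        denv, grp, reps = config$reps,
        seed = stageSeed(config$seed, "envPermdisp")))
      commAll <- do.call(rbind, lapply(seq_len(nt), function(k) {
        m <- countsAt(series, k)
        rownames(m) <- paste0(rownames(m), "@t", k)
        m
      }))
      keep <- rowSums(commAll) > 0
      dcomm <- brayCurtis(commAll[keep, , drop = FALSE])
      grpC <- rep(per, each = nrow(countsAt(series, 1)))[keep]
      out$communityPermanova <- unclass(permanova(
        dcomm, grpC, reps = config$reps,
        seed = stageSeed(config$seed, "commPermanova")))
      out$communityPermdisp <- unclass(permdisp(
        dcomm, grpC, reps = config$reps,
        seed = stageSeed(config$seed, "commPermdisp")))
      Y <- hellingerTransform(commAll[keep, , drop = FALSE])
      out$forwardSelection <- rdaForwardSelect(
        Y, envAll[keep, , drop = FALSE], alpha = config$alpha,
        reps = config$reps,
        seed = stageSeed(config$seed, "forwardSelection"))
    } else {
      out$note <- "environment or two-period design absent; stage reduced"
    }
    out
  })

  runStage("ems", function() {
    res <- lapply(seq_len(nt), function(k) {
      emsAnalysis(countsAt(series, k), reps = config$reps,
                  seed = stageSeed(config$seed, paste0("ems", k)),
                  alpha = config$alpha)
    })
    list(perTimepoint = data.frame(
      timepoint = seq_len(nt), period = per,
      coherenceZ = vapply(res, function(r) r@coherence$z, numeric(1)),
      coherenceP = vapply(res, function(r) r@coherence$p, numeric(1)),
      turnoverZ = vapply(res, function(r) r@turnover$z, numeric(1)),
      morisita = vapply(res, function(r) r@clumping$index, numeric(1)),
      type = vapply(res, function(r) r@type, character(1))))
  })

  runStage("raupcrick", function() {
    mats <- lapply(seq_len(nt), function(k) {
      betaRCMatrix(countsAt(series, k), reps = config$reps,
                   seed = stageSeed(config$seed, paste0("rc", k)))
    })
    list(perTimepoint = data.frame(
      timepoint = seq_len(nt), period = per,
      meanBetaRC = vapply(mats, attr, numeric(1), "meanBetaRC")),
      matrices = mats)
  })

  runStage("qpe", function() {
    cls <- vector("list", nt)
    brc <- vector("list", nt)
    for (k in seq_len(nt)) {
      m <- countsAt(series, k)
      bnti <- betaNTI(m, seriesTree(series), reps = config$reps,
                      seed = stageSeed(config$seed, paste0("bnti", k)))
      brc[[k]] <- betaRCBray(m, reps = config$reps,
                             seed = stageSeed(config$seed,
                                              paste0("rcbray", k)))
      cls[[k]] <- classifyPairs(bnti, brc[[k]])
    }
    names(cls) <- paste0("t", seq_len(nt))
    fr <- processFractions(cls)
    fr$period <- per
    list(fractions = fr, classifications = cls, brcBray = brc)
  })

  runStage("attribution", function() {
    if (!("qpe" %in% config$stages) ||
        !identical(report$stages$qpe$status, "ok"))
      stop("attribution depends on the qpe stage")
    if (!hasCoords || !hasEnv)
      stop("attribution requires site coordinates and environment")
    mr <- attributeDispersalFraction(
      report$stages$qpe$brcBray, siteCoords(series), series@env,
      alpha = config$alpha, reps = config$reps,
      seed = stageSeed(config$seed, "attributionMantel"))
    ss <- perSiteTemporalShift(series, alpha = config$alpha,
                               reps = config$reps,
                               seed = stageSeed(config$seed, "siteShift"))
    c(list(mantel = mr, siteShift = ss),
      assemblyVerdict(mr, ss))
  })

  report$periodComparison <- comparePeriodMetrics(report, per)
  class(report) <- "runReport"
  report
}

#' Dry-vs-wet comparison of every per-time-point metric
#'
#' Kruskal-Wallis (and Levene) comparisons between the periods for the
#' EMS coherence z, the mean incidence Raup-Crick value, and each
#' assembly-process fraction. Metrics whose stage did not run, or with
#' fewer than two time points in a period, are skipped with a reason.
#'
#' @param report a `runReport` from [runFull()] (or a partial one).
#' @param period per-time-point period labels (taken from the report's
#'   tables when omitted).
#' @return data.frame with one row per metric: H, p, direction, status.
#' @export
comparePeriodMetrics <- function(report, period = NULL) {
  metrics <- list()
  st <- report$stages
  if (identical(st$ems$status, "ok")) {
    metrics[["coherence z"]] <- list(
      values = st$ems$perTimepoint$coherenceZ,
      period = st$ems$perTimepoint$period)
  }
  if (identical(st$raupcrick$status, "ok")) {
    metrics[["mean beta_RC"]] <- list(
      values = st$raupcrick$perTimepoint$meanBetaRC,
      period = st$raupcrick$perTimepoint$period)
  }
  if (identical(st$qpe$status, "ok")) {
    fr <- st$qpe$fractions
    for (lab in intersect(.processLabels, colnames(fr)))
      metrics[[paste0("fraction: ", lab)]] <-
        list(values = fr[[lab]], period = fr$period)
  }
  rows <- lapply(names(metrics), function(nm) {
    v <- metrics[[nm]]$values
    p <- metrics[[nm]]$period
    if (is.null(p) && !is.null(period)) p <- period
    if (is.null(p) || min(table(factor(p, c("dry", "wet")))) < 2)
      return(data.frame(metric = nm, H = NA_real_, p = NA_real_,
                        direction = NA_character_,
                        status = "skipped: need 2+ time points per period"))
    cp <- suppressWarnings(comparePeriods(v, p))
    data.frame(metric = nm, H = cp$kruskal$statistic,
               p = cp$kruskal$p,
               direction = cp$kruskal$direction, status = "ok")
  })
  if (length(rows) == 0)
    return(data.frame(metric = character(), H = numeric(),
                      p = numeric(), direction = character(),
                      status = character()))
  do.call(rbind, rows)
}

#' Write a run report to disk
#'
#' Layered TSV tables (one per stage result that is tabular) plus a
#' single machine-readable JSON summary with deterministic key order, so
#' two runs with the same configuration produce byte-identical
#' summaries.
#'
#' @param report a `runReport`.
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the JSON summary.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  st <- report$stages
  if (identical(st$ems$status, "ok")) wtsv(st$ems$perTimepoint, "ems")
  if (identical(st$raupcrick$status, "ok"))
    wtsv(st$raupcrick$perTimepoint, "raupcrick")
  if (identical(st$qpe$status, "ok")) wtsv(st$qpe$fractions, "qpe")
  if (identical(st$attribution$status, "ok")) {
    wtsv(st$attribution$mantel, "attribution_mantel")
    wtsv(st$attribution$siteShift$table, "attribution_site_shift")
  }
  if (!is.null(report$periodComparison))
    wtsv(report$periodComparison, "period_comparison")
  summary <- runReportSummary(report)
  path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Condense a run report into a plain summary list
#'
#' @param report a `runReport`.
#' @return a nested list with deterministic element order (stable across
#'   runs with the same configuration), suitable for JSON export.
#' @export
runReportSummary <- function(report) {
  st <- report$stages
  out <- list(config = report$config)
  out$stageStatus <- lapply(st, function(s)
    s$status %||% "missing")
  if (identical(st$ems$status, "ok"))
    out$ems <- list(
      coherenceZ = st$ems$perTimepoint$coherenceZ,
      types = st$ems$perTimepoint$type)
  if (identical(st$raupcrick$status, "ok"))
    out$raupcrick <- list(
      meanBetaRC = st$raupcrick$perTimepoint$meanBetaRC)
  if (identical(st$qpe$status, "ok")) {
    fr <- st$qpe$fractions
    out$qpe <- list(fractions = lapply(
      stats::setNames(nm = intersect(.processLabels, colnames(fr))),
      function(lab) fr[[lab]]))
  }
  if (identical(st$attribution$status, "ok"))
    out$attribution <- list(verdict = st$attribution$verdict,
                            evidence = as.list(st$attribution$evidence),
                            siteShifts = st$attribution$siteShift$summary)
  if (!is.null(report$periodComparison) &&
      nrow(report$periodComparison) > 0)
    out$periodComparison <- lapply(
      seq_len(nrow(report$periodComparison)), function(i)
        as.list(report$periodComparison[i, ]))
  out
}

#' @export
print.runReport <- function(x, ...) {
  cat("runReport (seed", x$config$seed, ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-13s %s\n", nm, x$stages[[nm]]$status %||% "?"))
  if (identical(x$stages$attribution$status, "ok"))
    cat("  verdict:", x$stages$attribution$verdict, "\n")
  invisible(x)
}
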