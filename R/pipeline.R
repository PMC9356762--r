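## End-to-end analysis: for every requested stratum, optional delay
## adjustment, per-week baseline fits over the evaluation window, excess
## quantification, and delimited-text outputs plus a JSON run manifest.

.defaultPipelineConfig <- function() {
  list(
    evaluation = list(from = NULL, to = NULL),
    farrington = list(b = 5, w = 3, n_season = 9, level = 0.95,
                      reweight_threshold = 2.58, max_reweight_iter = 1,
                      trend_mode = "ALWAYS", baseline_mode = "FULL_HISTORY"),
    cause_overrides = list(RESPIRATORY = list(b = 3)),
    delay = list(triangle = NULL, as_of = NULL),
    cumulation_rule = "all_weeks"
  )
}

.mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

.configFor <- function(config, cause) {
  f <- config$farrington
  ov <- config$cause_overrides[[cause]]
  if (!is.null(ov)) f <- .mergeConfig(f, ov)
  farringtonConfig(b = f$b, w = f$w, nSeason = f$n_season, level = f$level,
                   reweightThreshold = f$reweight_threshold,
                   maxReweightIter = f$max_reweight_iter,
                   trendMode = f$trend_mode, baselineMode = f$baseline_mode)
}

#' Read a pipeline or scenario configuration from YAML
#'
#' @param path YAML file.
#' @return named list.
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' Build a MortalityScenario from a configuration list or YAML file
#'
#' Recognized keys mirror [mortalityScenario()] arguments (snake_case:
#' `start_date`, `n_weeks`, `strata`, `beta`, `amplitude`, `phase`, `size`,
#' `episodes`, `delay_law`, `seed`); unspecified keys keep their defaults.
#'
#' @param x list or path to a YAML file.
#' @return a [MortalityScenario-class].
#' @export
loadScenario <- function(x) {
  if (is.character(x)) x <- readConfig(x)
  args <- list()
  if (!is.null(x$start_date)) args$startDate <- as.Date(x$start_date)
  if (!is.null(x$n_weeks)) args$nWeeks <- x$n_weeks
  if (!is.null(x$strata))
    args$strata <- do.call(rbind, lapply(x$strata, as.data.frame))
  for (k in c("beta", "amplitude", "phase", "size", "seed"))
    if (!is.null(x[[k]])) args[[k]] <- x[[k]]
  if (!is.null(x$episodes))
    args$episodes <- do.call(rbind, lapply(x$episodes, as.data.frame))
  if (!is.null(x$delay_law)) args$delayLaw <- as.numeric(x$delay_law)
  do.call(mortalityScenario, args)
}

.sanitize <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Run the full excess-mortality analysis
#'
#' For every stratum in `countsData` (or those selected by
#' `config$strata`): optional reporting-delay adjustment, a per-week
#' modified Farrington fit over the evaluation window (with per-cause
#' parameter overrides, e.g. b=3 for the respiratory category), and excess
#' quantification. Writes one weekly table per stratum
#' (`weekly_<cause>_<place>_<region>.csv`), a cumulative summary
#' (`summary.csv`), an excess-runs report (`runs.csv`), and a JSON run
#' manifest. A stratum failure is recorded in the manifest without aborting
#' the run.
#'
#' @param countsData named list of [WeeklyCounts-class] (e.g. from
#'   [readWeeklyCounts()] or [simulateSeries()]), or a path to a long-format
#'   counts file.
#' @param config list (see `.defaultPipelineConfig` keys) or YAML path; must
#'   set `evaluation$from` and `evaluation$to`.
#' @param outDir output directory (created if needed). `NULL` = no files,
#'   results returned only.
#' @param delayAdjust set `FALSE` to bypass the reporting-delay adjustment
#'   even when a triangle is configured.
#' @return (invisibly) list with `weekly` (per-stratum excess tables),
#'   `summary`, `runs`, `manifest`.
#' @export
runAnalysis <- function(countsData, config = list(), outDir = NULL,
                        delayAdjust = TRUE) {
  if (is.character(config)) config <- readConfig(config)
  config <- .mergeConfig(.defaultPipelineConfig(), config)
  if (is.character(countsData)) countsData <- readWeeklyCounts(countsData)
  if (methods::is(countsData, "WeeklyCounts"))
    countsData <- stats::setNames(list(countsData),
                                  stratumLabel(countsData))
  if (!is.null(config$strata))
    countsData <- countsData[intersect(names(countsData),
                                       unlist(config$strata))]
  if (is.null(config$evaluation$from) || is.null(config$evaluation$to))
    stop("config must set evaluation$from and evaluation$to")
  evalFrom <- as.Date(config$evaluation$from)
  evalTo <- as.Date(config$evaluation$to)
  tri <- NULL
  if (delayAdjust && !is.null(config$delay$triangle)) {
    tri <- if (is.character(config$delay$triangle))
      readReportingTriangle(config$delay$triangle) else config$delay$triangle
  }
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  weekly <- list(); summaries <- list(); runsOut <- list()
  manifest <- list(
    package_version = as.character(utils::packageVersion("exmort")),
    config = config[c("evaluation", "farrington", "cause_overrides",
                      "cumulation_rule")],
    delay_adjusted = !is.null(tri),
    strata = list()
  )
  for (key in names(countsData)) {
    s <- countsData[[key]]
    status <- list(stratum = key, b = NA, status = "ok",
                   warnings = character(), weeks_flagged = NA)
    res <- tryCatch({
      if (!is.null(tri)) {
        asOf <- if (!is.null(config$delay$as_of))
          as.Date(config$delay$as_of)
        else max(weekStarts(s))
        s <- adjustProvisional(s, tri, asOf)$series
      }
      cfg <- .configFor(config, s@cause)
      status$b <- cfg@b
      targets <- weekSeq(evalFrom, evalTo)
      warns <- character()
      est <- withCallingHandlers(
        farrington(s, targets, cfg),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      status$warnings <- unique(warns)
      tbl <- excessTable(s, est)
      status$weeks_flagged <- sum(tbl$flag != "NONE")
      tbl
    }, error = function(e) {
      status$status <<- paste("error:", conditionMessage(e))
      NULL
    })
    manifest$strata[[key]] <- status
    if (is.null(res)) next
    weekly[[key]] <- res
    cum <- cumulateExcess(res, evalFrom, evalTo,
                          rule = config$cumulation_rule)
    summaries[[key]] <- cbind(data.frame(stratum = key, cause = s@cause,
                                         place = s@place, region = s@region),
                              cum)
    rns <- excessRuns(res)
    if (nrow(rns))
      runsOut[[key]] <- cbind(data.frame(stratum = key), rns)
    if (!is.null(outDir)) {
      fn <- file.path(outDir, paste0("weekly_", .sanitize(key), ".csv"))
      out <- res
      out$week_start <- format(out$week_start)
      utils::write.csv(out, fn, row.names = FALSE, quote = FALSE)
    }
  }
  summary <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  runs <- if (length(runsOut))
    do.call(rbind, c(runsOut, list(make.row.names = FALSE)))
  else data.frame(stratum = character(), start = as.Date(character()),
                  end = as.Date(character()), n_weeks = integer())
  if (!is.null(outDir)) {
    utils::write.csv(summary, file.path(outDir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(runs, file.path(outDir, "runs.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         force = TRUE)
  }
  invisible(list(weekly = weekly, summary = summary, runs = runs,
                 manifest = manifest))
}

#' Cumulative summary over a period (Table-style)
#'
#' Per stratum: total observed deaths and cumulative excess and exiguous
#' ranges over `[from, to]`, computed from the weekly excess tables.
#'
#' @param results a [runAnalysis()] return value, or a results directory
#'   containing `weekly_*.csv` files.
#' @param from,to period bounds.
#' @param rule cumulation rule, see [cumulateExcess()].
#' @return data.frame, one row per stratum.
#' @export
summarizePeriod <- function(results, from, to,
                            rule = c("all_weeks", "flagged_only")) {
  rule <- match.arg(rule)
  if (is.character(results)) {
    files <- list.files(results, pattern = "^weekly_.*\\.csv$",
                        full.names = TRUE)
    weekly <- lapply(files, function(f) {
      d <- utils::read.csv(f, stringsAsFactors = FALSE)
      d$week_start <- as.Date(d$week_start)
      d
    })
    names(weekly) <- sub("^weekly_(.*)\\.csv$", "\\1", basename(files))
  } else weekly <- results$weekly
  rows <- lapply(names(weekly), function(key) {
    cbind(data.frame(stratum = key),
          cumulateExcess(weekly[[key]], from, to, rule = rule))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
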