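# End-to-end dark-vs-light comparison from a single run configuration.

.configSelection <- function(x) {
  atomSelection(chains = x$chains, residues = x$residues, atoms = x$atoms)
}

#' Read a run configuration
#'
#' A YAML file (or an equivalent list) describing a full dark-vs-light
#' analysis: the trajectory roster, region/helix definitions, interaction
#' specs, criteria overrides and output directory. Residue ranges are
#' inclusive, 1-based, written \code{"first-last"}.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return a validated configuration list of class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$trajectories) || length(cfg$trajectories) == 0L)
    stop("config must list at least one trajectory", call. = FALSE)
  labels <- vapply(cfg$trajectories, function(x) x$label %||% "",
                   character(1))
  if (any(!nzchar(labels)) || anyDuplicated(labels))
    stop("every trajectory needs a unique label", call. = FALSE)
  states <- vapply(cfg$trajectories, function(x) x$state %||% "",
                   character(1))
  if (any(!states %in% c("dark", "light")))
    stop("trajectory state must be 'dark' or 'light'", call. = FALSE)
  cfg$outputDir <- cfg$outputDir %||% "lovdyn-out"
  cfg$skipFrames <- cfg$skipFrames %||% 0L
  cfg$fitChain <- cfg$fitChain %||% "A"
  cfg$measureChain <- cfg$measureChain %||% "B"
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.configCriteria <- function(cfg) {
  cr <- cfg$criteria %||% list()
  geometricCriteria(
    maxDonorAcceptorDistance = cr$maxDonorAcceptorDistance %||% 3.2,
    angleRange = unlist(cr$angleRange %||% c(130, 180)),
    saltBridgeCutoff = cr$saltBridgeCutoff %||% 5.0,
    secondaryContactThreshold = cr$secondaryContactThreshold %||% 4.0)
}

.stageRecord <- function(report, stage, status, message = "") {
  report$stages <- rbind(report$stages, data.frame(
    stage = stage, status = status, message = message,
    stringsAsFactors = FALSE))
  report
}

.runStage <- function(report, stage, fun) {
  res <- tryCatch(
    withCallingHandlers(fun(), warning = function(w) {
      report$warnings <<- c(report$warnings,
                            paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }),
    error = function(e) e)
  if (inherits(res, "error")) {
    report <- .stageRecord(report, stage, "error", conditionMessage(res))
  } else if (is.character(res) && length(res) == 1L &&
             startsWith(res, "skipped")) {
    report <- .stageRecord(report, stage, "skipped", res)
    report$warnings <- c(report$warnings, paste0(stage, ": ", res))
  } else {
    report <- .stageRecord(report, stage, "ok")
    if (is.character(res)) report$files <- c(report$files, res)
  }
  report
}

#' Run the full dark-vs-light analysis
#'
#' Orchestrates every stage from one configuration: per-trajectory region
#' RMSDs, per-residue RMSD and RMSF profiles (fit on one chain, measure
#' the other), H-bond and salt-bridge occupancy tables, helix
#' crossing-angle series/histograms/summaries and DCCMs; per-state
#' averaged DCCMs; and across states a light-minus-dark difference DCCM,
#' a run-roster summary table with per-state "Average" rows, and a
#' light-minus-dark per-residue RMSD profile. All outputs are TSV files
#' in the configured output directory. Stages are independent: a failure
#' is recorded in the report and the run continues; stages whose inputs
#' are missing (e.g. difference maps without both states) are skipped
#' with an explicit warning. Identical configuration and inputs give
#' byte-identical outputs.
#'
#' @param config a [readRunConfig()] list or a YAML path.
#' @return a run report: list with \code{files} (produced outputs),
#'   \code{stages} (status table), \code{warnings}, and \code{failed}
#'   (TRUE if any stage errored).
#' @export
runAnalysis <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else readRunConfig(config)
  out <- cfg$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(files = character(), warnings = character(),
                 stages = data.frame(stage = character(),
                                     status = character(),
                                     message = character(),
                                     stringsAsFactors = FALSE))
  labels <- vapply(cfg$trajectories, `[[`, character(1), "label")
  states <- vapply(cfg$trajectories, `[[`, character(1), "state")
  criteria <- .configCriteria(cfg)

  trajs <- list()
  for (i in seq_along(cfg$trajectories)) {
    entry <- cfg$trajectories[[i]]
    report <- .runStage(report, paste0("load:", entry$label), function() {
      trajs[[entry$label]] <<- readTrajectory(entry$trajectory)
      character()
    })
  }
  loaded <- names(trajs)
  states <- states[labels %in% loaded]
  labels <- labels[labels %in% loaded]

  regions <- if (is.null(cfg$regions)) lovRegions()
             else lapply(cfg$regions, .configSelection)
  profiles <- list()   # per-label chain-B per-residue RMSD
  dccms <- list()

  for (lb in labels) {
    tr <- trajs[[lb]]
    fitSel <- atomSelection(chains = cfg$fitChain, atoms = "backbone")
    measSel <- atomSelection(chains = cfg$measureChain,
                             atoms = "backbone")

    report <- .runStage(report, paste0("profile:", lb), function() {
      prof <- perResidueRMSD(tr, measSel, fitSelection = fitSel)
      profiles[[lb]] <<- prof
      f1 <- file.path(out, paste0(lb, "_residue_rmsd.tsv"))
      writeTSV(prof, f1)
      fl <- rmsf(tr, atomSelection(atoms = "backbone"),
                 fitSelection = fitSel)
      f2 <- file.path(out, paste0(lb, "_rmsf.tsv"))
      writeTSV(fl, f2)
      c(f1, f2)
    })

    report <- .runStage(report, paste0("interactions:", lb), function() {
      files <- character()
      if (length(cfg$hbonds)) {
        specs <- lapply(cfg$hbonds, function(x)
          hbondSpec(x$label, x$donor, x$hydrogen, x$acceptor))
        tab <- hbondOccupancy(tr, specs, criteria,
                              skipFrames = cfg$skipFrames)
        f <- file.path(out, paste0(lb, "_hbonds.tsv"))
        writeTSV(tab, f); files <- c(files, f)
      }
      if (length(cfg$saltBridges)) {
        specs <- lapply(cfg$saltBridges, function(x)
          saltBridgeSpec(x$label, x$cation, x$anion))
        tab <- saltBridgeOccupancy(tr, specs, criteria,
                                   skipFrames = cfg$skipFrames)
        f <- file.path(out, paste0(lb, "_saltbridges.tsv"))
        writeTSV(tab, f); files <- c(files, f)
      }
      if (length(files) == 0L) "skipped: no interaction specs configured"
      else files
    })

    report <- .runStage(report, paste0("angles:", lb), function() {
      if (is.null(cfg$helices))
        return("skipped: no helices configured")
      hA <- helixDefinition(cfg$helices$a$chain, cfg$helices$a$residues)
      hB <- helixDefinition(cfg$helices$b$chain, cfg$helices$b$residues)
      dist <- crossingAngleDistribution(tr, hA, hB,
                                        binWidth = cfg$binWidth %||% 1)
      f1 <- file.path(out, paste0(lb, "_angles.tsv"))
      writeTSV(data.frame(frame = seq_along(dist@angles),
                          angle = dist@angles), f1)
      f2 <- file.path(out, paste0(lb, "_angle_histogram.tsv"))
      nb <- length(dist@breaks)
      writeTSV(data.frame(bin_low = dist@breaks[-nb],
                          bin_high = dist@breaks[-1L],
                          count = dist@counts), f2)
      f3 <- file.path(out, paste0(lb, "_angle_summary.tsv"))
      writeTSV(data.frame(mean = dist@mean, sd = dist@sd,
                          n = length(dist@angles)), f3)
      c(f1, f2, f3)
    })

    report <- .runStage(report, paste0("dccm:", lb), function() {
      m <- dccm(tr, fitSelection = atomSelection(atoms = "backbone"))
      dccms[[lb]] <<- m
      f <- file.path(out, paste0(lb, "_dccm.tsv"))
      writeMatrixTSV(m, f)
      f
    })
  }

  report <- .runStage(report, "summary", function() {
    if (length(trajs) == 0L) stop("no trajectories loaded")
    summary <- regionRMSDSummary(trajs, states[match(names(trajs), labels)],
                                 regions)
    f <- file.path(out, "region_rmsd_summary.tsv")
    writeTSV(summary, f)
    report$summary <<- summary
    f
  })

  avg <- list()
  for (st in c("dark", "light")) {
    report <- .runStage(report, paste0("dccm-average:", st), function() {
      ms <- dccms[labels[states == st]]
      ms <- ms[!vapply(ms, is.null, logical(1))]
      if (length(ms) == 0L)
        return(sprintf("skipped: no %s-state DCCMs available", st))
      avg[[st]] <<- averageDCCM(ms)
      f <- file.path(out, sprintf("dccm_average_%s.tsv", st))
      writeMatrixTSV(avg[[st]], f)
      f
    })
  }

  report <- .runStage(report, "dccm-difference", function() {
    if (is.null(avg$light) || is.null(avg$dark))
      return("skipped: need both dark- and light-state DCCMs")
    d <- differenceDCCM(avg$light, avg$dark)
    f <- file.path(out, "dccm_light_minus_dark.tsv")
    writeMatrixTSV(d, f)
    f
  })

  report <- .runStage(report, "profile-difference", function() {
    pl <- profiles[labels[states == "light"]]
    pd <- profiles[labels[states == "dark"]]
    pl <- pl[!vapply(pl, is.null, logical(1))]
    pd <- pd[!vapply(pd, is.null, logical(1))]
    if (length(pl) == 0L || length(pd) == 0L)
      return("skipped: need per-residue profiles for both states")
    mprof <- function(ps) {
      m <- ps[[1L]]
      m$value <- rowMeans(vapply(ps, `[[`, numeric(nrow(m)), "value"))
      m
    }
    d <- rmsdDifferenceProfile(mprof(pl), mprof(pd))
    f <- file.path(out, "residue_rmsd_light_minus_dark.tsv")
    writeTSV(d, f)
    f
  })

  report$failed <- any(report$stages$status == "error")
  report
}

#' Compare region summaries of two states
#'
#' Takes two region-RMSD summary tables (e.g. the dark-state and
#' light-state rows of [regionRMSDSummary()] outputs, from the same run
#' or two different runs) and reports, per region, the dark mean, the
#' light mean, their difference (dark minus light) and whether the dark
#' state is the more mobile one. The region sets must overlap.
#'
#' @param dark,light data.frames with columns \code{region} and
#'   \code{rmsd} (extra columns such as \code{label}/\code{state} are
#'   allowed; \code{"Average"} roster rows are excluded from the means).
#' @return a data.frame with columns \code{region}, \code{dark},
#'   \code{light}, \code{difference}, \code{darkGreater}.
#' @export
runCompare <- function(dark, light) {
  clean <- function(x) {
    stopifnot(all(c("region", "rmsd") %in% names(x)))
    if ("label" %in% names(x)) x <- x[x$label != "Average", , drop = FALSE]
    stats::aggregate(rmsd ~ region, data = x, FUN = mean)
  }
  d <- clean(dark); l <- clean(light)
  common <- intersect(d$region, l$region)
  if (length(common) == 0L)
    stop("no shared regions/metrics between the two summaries",
         call. = FALSE)
  dv <- d$rmsd[match(common, d$region)]
  lv <- l$rmsd[match(common, l$region)]
  data.frame(region = common, dark = dv, light = lv,
             difference = dv - lv, darkGreater = dv > lv,
             stringsAsFactors = FALSE)
}
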