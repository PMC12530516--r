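## Session configuration, input validation and the reproducible
## multi-stage pipeline runner. A session is described by one YAML file;
## all randomness flows from a single root seed via named substreams.

#' Read and validate a session configuration
#'
#' The YAML schema (all blocks optional unless a stage needs them):
#' \preformatted{
#' seed: 1
#' out: out/
#' fps: 30
#' arena: {width: 460, length: 300,
#'         shelter: [192.5, 267.5, 150, 300], px_per_mm: 1}
#' stimulus: {t0: 20}
#' windows: [15, 30]
#' photometry: {lam: 1.0e8, max_iter: 50, ratio_tol: 0.001,
#'              smooth_win: null, c_huber: 1.345}
#' inputs: {pose: pose.csv, photometry: photometry.csv,
#'          counts: counts.csv}
#' simulate: {duration: 60, ...}
#' }
#' Validation is fail-fast: a malformed field is reported by name
#' before any stage runs.
#'
#' @param path YAML file path.
#' @return validated config list (class `"loometrySession"`).
#' @export
readSessionConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateSessionConfig(cfg, dir = dirname(path))
}

#' @rdname readSessionConfig
#' @param cfg a config list (as from `yaml::read_yaml`).
#' @param dir directory against which relative input paths resolve.
#' @export
validateSessionConfig <- function(cfg, dir = ".") {
  fail <- function(field, why) stop(sprintf("config field '%s': %s",
                                            field, why), call. = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.numeric(cfg$seed)) fail("seed", "must be an integer")
  if (is.null(cfg$fps)) cfg$fps <- 30
  if (!isTRUE(cfg$fps > 0)) fail("fps", "must be > 0")
  if (is.null(cfg$windows)) cfg$windows <- c(15, 30)
  if (any(cfg$windows <= 0)) fail("windows", "must be positive")
  a <- cfg$arena
  cfg$arenaObj <- tryCatch({
    if (is.null(a)) ArenaGeometry()
    else ArenaGeometry(width = a$width %||% 460,
                       length = a$length %||% 300,
                       shelterBBox = a$shelter %||%
                         c((a$width %||% 460 - 75) / 2,
                           (a$width %||% 460 + 75) / 2,
                           (a$length %||% 300) - 150, a$length %||% 300),
                       pxPerMm = a$px_per_mm %||% 1)
  }, error = function(e) fail("arena", conditionMessage(e)))
  ph <- cfg$photometry
  cfg$airplsObj <- tryCatch(
    AirplsParams(lam = ph$lam %||% 1e8, maxIter = ph$max_iter %||% 50,
                 ratioTol = ph$ratio_tol %||% 0.001),
    error = function(e) fail("photometry", conditionMessage(e)))
  if (!is.null(cfg$inputs)) {
    for (nm in names(cfg$inputs)) {
      p <- cfg$inputs[[nm]]
      if (!file.exists(p) && file.exists(file.path(dir, p)))
        cfg$inputs[[nm]] <- file.path(dir, p)
      if (!file.exists(cfg$inputs[[nm]]))
        fail(paste0("inputs.", nm), sprintf("file '%s' not found", p))
    }
  }
  if (is.null(cfg$out)) cfg$out <- "out"
  structure(cfg, class = "loometrySession")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate input files against their expected schemas
#'
#' A reporting operation: each file is checked against the schema its
#' role implies (pose = three-row-header keypoint CSV; photometry =
#' `time_s, ch465, ch405, ttl` with monotone uniform time; counts =
#' region-counts schema). Returns one row per file with `pass` and the
#' first offending row/column in `detail`; never throws.
#'
#' @param paths named character vector or list; names from
#'   `c("pose", "photometry", "counts")`.
#' @return data.frame: `input`, `path`, `pass`, `detail`.
#' @export
validateInputs <- function(paths) {
  checkOne <- function(role, path) {
    detail <- ""
    pass <- TRUE
    res <- tryCatch({
      if (!file.exists(path)) stop("file not found")
      switch(role,
        pose = {
          hdr <- read.csv(path, header = FALSE, nrows = 3,
                          colClasses = "character")
          if (nrow(hdr) < 3 ||
              !identical(tolower(hdr[3, 2]), "x"))
            stop("not a three-row-header pose CSV")
          parts <- unique(as.character(unlist(hdr[2, -1])))
          cr <- as.character(unlist(hdr[3, -1]))
          per <- table(as.character(unlist(hdr[2, -1])))
          bad <- names(per)[per < 2]
          if (length(bad))
            stop(sprintf("body part '%s' lacks x/y columns", bad[1]))
        },
        photometry = {
          df <- read.csv(path, nrows = 100000)
          need <- c("time_s", "ch465", "ch405", "ttl")
          miss <- setdiff(need, names(df))
          if (length(miss))
            stop(sprintf("missing column '%s'", miss[1]))
          nm <- which(diff(df$time_s) <= 0)
          if (length(nm))
            stop(sprintf("non-monotone time_s at row %d", nm[1] + 1L))
        },
        counts = validateRegionCounts(read.csv(path)),
        stop(sprintf("unknown input role '%s'", role)))
      TRUE
    }, error = function(e) { detail <<- conditionMessage(e); FALSE })
    data.frame(input = role, path = path, pass = res, detail = detail)
  }
  out <- do.call(rbind, lapply(names(paths), function(nm)
    checkOne(nm, paths[[nm]])))
  rownames(out) <- NULL
  out
}

## deterministic per-stage substream seeds below 2^31
.substream <- function(seed, stage) {
  (as.integer(seed) +
     c(simulate = 101L, score = 211L, photometry = 307L,
       engram = 401L)[[stage]] * 7919L) %% .Machine$integer.max
}

.md5 <- function(path) unname(tools::md5sum(path))

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order against a validated
#' session config and writes a JSON run manifest (package version,
#' config hash, seed, input checksums, per-stage status and outputs).
#' Stages: `simulate` (write synthetic pose/photometry/counts CSVs into
#' the output directory and register them as inputs), `score`
#' (ethogram, speed, peri-stimulus summary), `photometry` (zdFF trace +
#' provenance), `engram` (reactivation table and region comparison).
#' Inputs are never mutated; reruns with the same config and seed
#' produce byte-identical outputs.
#'
#' @param config a config list from [readSessionConfig()] /
#'   [validateSessionConfig()].
#' @param stages subset of `c("simulate", "score", "photometry",
#'   "engram")`.
#' @return the manifest, invisibly (also written to
#'   `<out>/manifest.json`).
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "score", "photometry",
                                   "engram")) {
  if (!inherits(config, "loometrySession"))
    config <- validateSessionConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  order <- c("simulate", "score", "photometry", "engram")
  stages <- order[order %in% stages]
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ## config hash: canonical JSON of the plain fields
  plain <- config[setdiff(names(config), c("arenaObj", "airplsObj"))]
  cfgFile <- tempfile(fileext = ".json")
  jsonlite::write_json(plain, cfgFile, auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "loometry",
                   version = as.character(packageVersion("loometry")),
                   rversion = as.character(getRversion()),
                   seed = config$seed, configHash = .md5(cfgFile),
                   inputs = list(), stages = list())
  arena <- config$arenaObj
  t0 <- config$stimulus$t0 %||% 20
  timeline <- buildLoomTrain(LoomSpec(), t0 = t0)
  status <- function(name, outputs)
    manifest$stages[[name]] <<- list(status = "completed",
                                     outputs = outputs)
  for (st in stages) {
    res <- tryCatch({
      switch(st,
        simulate = {
          sim <- config$simulate %||% list()
          sc <- boutScript(
            states = sim$states %||% c("locomote", "freeze", "locomote",
                                       "flight", "shelter", "freeze"),
            durations = sim$durations %||% c(15, 5, 10, 2, 10, 18),
            jitterSd = sim$jitter_sd %||% 0.3, fps = config$fps)
          gp <- genPoseTrack(sc, arena, seed = .substream(config$seed,
                                                          "simulate"))
          posePath <- file.path(out, "pose.csv")
          writePoseTrack(gp$track, posePath, pxPerMm = arena@pxPerMm)
          spec <- photometrySimSpec(
            duration = sim$duration %||% 60,
            eventTimes = onsets(timeline, "loom"))
          ph <- genPhotometry(spec, seed = .substream(config$seed,
                                                      "simulate"))
          photPath <- file.path(out, "photometry.csv")
          writePhotometry(ph$recording, photPath)
          counts <- genRegionCounts(
            groups = list(reexposure = list(nMice = 6, trueReact = 0.35,
                                            trueCfos = 0.10,
                                            nEyfpMean = 150),
                          noreexposure = list(nMice = 6, trueReact = 0.10,
                                              trueCfos = 0.10,
                                              nEyfpMean = 150)),
            seed = .substream(config$seed, "simulate"))
          countsPath <- file.path(out, "counts.csv")
          write.csv(counts, countsPath, row.names = FALSE)
          config$inputs$pose <- posePath
          config$inputs$photometry <- photPath
          config$inputs$counts <- countsPath
          status(st, c(posePath, photPath, countsPath))
        },
        score = {
          if (is.null(config$inputs$pose)) stop("no pose input")
          track <- readPoseTrack(config$inputs$pose, fps = config$fps,
                                 arena = arena)
          etho <- scoreEthogram(track, arena)
          bedPath <- file.path(out, "ethogram.tsv")
          widePath <- file.path(out, "ethogram_frames.csv")
          writeEthogramBED(etho, bedPath)
          writeEthogramWide(etho, widePath)
          sp <- computeSpeed(track)
          spPath <- file.path(out, "speed.csv")
          write.csv(data.frame(t = sp@t, v = sp@v), spPath,
                    row.names = FALSE)
          sumPath <- file.path(out, "peri_stimulus.csv")
          nFrames <- length(etho@channels[[1]])
          win <- min(max(config$windows),
                     floor(min(t0, nFrames / etho@fps - t0)))
          summ <- suppressWarnings(periStimulusSummary(etho, timeline,
                                                       window = win))
          write.csv(summ, sumPath, row.names = FALSE)
          status(st, c(bedPath, widePath, spPath, sumPath))
        },
        photometry = {
          if (is.null(config$inputs$photometry))
            stop("no photometry input")
          rec <- readPhotometry(config$inputs$photometry)
          z <- computeZdff(rec, smoothWin = config$photometry$smooth_win,
                           airpls = config$airplsObj,
                           cHuber = config$photometry$c_huber %||% 1.345)
          zPath <- file.path(out, "zdff.csv")
          writeZdff(z, zPath)
          status(st, c(zPath, paste0(zPath, ".json")))
        },
        engram = {
          if (is.null(config$inputs$counts)) stop("no counts input")
          counts <- readRegionCounts(config$inputs$counts)
          tab <- reactivationTable(counts)
          tabPath <- file.path(out, "reactivation.csv")
          write.csv(tab, tabPath, row.names = FALSE)
          cmp <- compareRegions(tab)
          cmpPath <- file.path(out, "region_tests.tsv")
          write.table(cmp, cmpPath, sep = "\t", row.names = FALSE,
                      quote = FALSE)
          status(st, c(tabPath, cmpPath))
        })
      TRUE
    }, error = function(e) {
      manifest$stages[[st]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      FALSE
    })
    if (!res) break
  }
  for (nm in names(config$inputs))
    manifest$inputs[[nm]] <- list(path = config$inputs[[nm]],
                                  md5 = .md5(config$inputs[[nm]]))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
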