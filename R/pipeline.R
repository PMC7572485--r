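## Pipeline orchestration: configuration with stable hashing, model
## serialization, and the end-to-end run over a cohort manifest.

## FNV-1a 32-bit over the JSON serialization; stable across sessions.
.fnv1a <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    # xor only touches the low byte (bytes are < 256); keep h as a double
    # since it exceeds the 32-bit signed range bitwXor supports
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b %% 256L)
    # 32-bit modular multiply by the FNV prime 16777619
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  h
}

#' Stable hash of a configuration object
#'
#' @param cfg any JSON-serializable list.
#' @return 8-hex-digit string identifying the configuration.
#' @export
configHash <- function(cfg) {
  j <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12)
  h <- .fnv1a(utf8ToInt(as.character(j)))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end analysis with their defaults: 1-30 Hz
#' zero-phase band-pass over a 20 s epoch, clustering of GFP-peak
#' topographies with 20 restarts over k = 2..8, run-collapsed unnormalized
#' microstate LZC, 4-8 Hz theta over a 1-30 Hz total band, and an RBF SVM
#' with 10 stratified folds. Any element can be overridden via `...` (named
#' sub-lists are merged) or loaded from YAML with [readPipelineConfig()].
#'
#' @param ... named overrides, e.g. `clustering = list(k = 4)`.
#' @return A list of class `"PipelineConfig"` with attribute `"hash"`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    preprocessing = list(
      band = c(1, 30), epochLength = 20, targetFs = NULL, filterOrder = 4
    ),
    clustering = list(
      kRange = 2:8, k = NULL, nInit = 20, gfpPeaks = TRUE, seed = 1,
      minDurationMs = 0
    ),
    complexity = list(collapseRuns = TRUE, normalize = FALSE),
    spectral = list(theta = c(4, 8), total = c(1, 30)),
    classifier = list(kernel = "radial", folds = 10, cost = 1, seed = 1),
    tanova = list(nPerm = 999, seed = 1)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "PipelineConfig", hash = configHash(unclass(cfg)))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [pipelineConfig()].
#'
#' @param path YAML file.
#' @return A `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

#' Serialize a microstate model to JSON
#'
#' @param model a [MicrostateModel-class].
#' @param path output file.
#' @param config optional configuration to embed (hashed).
#' @return `path`, invisibly.
#' @export
writeModelJSON <- function(model, path, config = NULL) {
  obj <- list(
    k = nStates(model),
    level = model@level,
    gev = gev(model),
    channelNames = channelNames(model),
    classNames = model@classNames,
    maps = apply(microstateMaps(model), 1, identity, simplify = FALSE)
  )
  if (!is.null(config)) obj$configHash <- configHash(unclass(config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}

#' Read a microstate model from JSON
#' @param path JSON file written by [writeModelJSON()].
#' @return A [MicrostateModel-class].
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  maps <- if (is.list(obj$maps)) do.call(rbind, obj$maps) else as.matrix(obj$maps)
  MicrostateModel(maps,
    gev = obj$gev, level = obj$level,
    channelNames = obj$channelNames %||% character(),
    classNames = obj$classNames %||% character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a label sequence as single-column CSV
#'
#' The header cell carries the sampling rate (`fs=<Hz>`).
#' @param seq a [LabelSequence-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLabelSequenceCSV <- function(seq, path) {
  writeLines(
    c(sprintf("fs=%g", samplingRate(seq)), as.character(stateLabels(seq))),
    path
  )
  invisible(path)
}

#' Read a label sequence CSV written by [writeLabelSequenceCSV()]
#' @param path input file.
#' @return A [LabelSequence-class].
#' @export
readLabelSequenceCSV <- function(path) {
  lines <- readLines(path)
  fs <- as.numeric(sub("^fs=", "", lines[1]))
  LabelSequence(as.integer(lines[-1]), fs = fs)
}

.loadSubject <- function(path, fs = NULL, labels = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    readEDF(path)
  } else {
    if (is.null(fs)) stop("fs required for text input", call. = FALSE)
    readMatrixText(path, fs = fs, labels = labels)
  }
}

#' Run the full microstate pipeline over a cohort
#'
#' Orchestrates every stage: per-subject preprocessing, GFP-peak clustering
#' with Krzanowski-Lai selection of k (unless `clustering$k` is fixed),
#' cohort-level clustering per group, alignment of cohort maps across
#' groups, backfitting, sequence statistics, complexity and spectral
#' features, group statistics (two-way ANOVA on durations, Mann-Whitney on
#' duration and C, TANOVA per class), and cross-validated classification.
#' Subject-level failures are recorded and skipped; the run continues.
#'
#' @param subjects either a named list of [EEGRecording-class] objects, or a
#'   manifest data.frame with columns `subject_id`, `path`, `group` (and
#'   optionally `fs` for text inputs, with channel `labels` supplied via the
#'   `labels` argument).
#' @param config a [pipelineConfig()].
#' @param labels channel labels for text-matrix manifest entries.
#' @param outputDir optional directory; when given, models, label sequences,
#'   features and test reports are written there.
#' @param verbose log progress to stderr.
#' @return A list with `config`, `configHash`, `subjects` (per-subject
#'   results), `k`, `cohortModels`, `alignment`, `features`, `groupStats`,
#'   `classifier` and `failures`.
#' @export
runPipeline <- function(subjects, config = pipelineConfig(), labels = NULL,
                        outputDir = NULL, verbose = FALSE) {
  log <- function(...) if (verbose) message(sprintf(...))
  hash <- attr(config, "hash") %||% configHash(unclass(config))

  if (is.data.frame(subjects)) {
    manifest <- subjects
    subjects <- list()
    groups <- character()
    for (i in seq_len(nrow(manifest))) {
      sid <- manifest$subject_id[i]
      rec <- tryCatch(
        .loadSubject(manifest$path[i], fs = manifest$fs[i], labels = labels),
        error = function(e) e
      )
      if (inherits(rec, "error")) {
        subjects[[sid]] <- rec
      } else {
        rec@subjectId <- as.character(sid)
        rec@group <- as.character(manifest$group[i])
        subjects[[sid]] <- rec
      }
    }
  }

  failures <- list()
  prep <- list()
  for (sid in names(subjects)) {
    res <- tryCatch(
      {
        rec <- subjects[[sid]]
        if (inherits(rec, "error")) stop(conditionMessage(rec))
        pp <- config$preprocessing
        preprocessEEG(rec,
          band = pp$band, targetFs = pp$targetFs,
          epochLength = pp$epochLength, filterOrder = pp$filterOrder
        )
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[sid]] <- conditionMessage(res)
      log("subject %s failed: %s", sid, conditionMessage(res))
    } else {
      prep[[sid]] <- res
    }
  }
  if (length(prep) == 0) stop("no subject survived preprocessing", call. = FALSE)

  cl <- config$clustering
  obsOf <- function(rec) {
    X <- t(eegData(rec))
    if (isTRUE(cl$gfpPeaks)) {
      pk <- gfpCurve(rec)$peaks
      if (length(pk) >= max(cl$kRange, cl$k)) X <- X[pk, , drop = FALSE]
    }
    X
  }

  # per-subject optimal k, then the cohort-wide median (unless fixed)
  k <- cl$k
  klCurves <- NULL
  if (is.null(k)) {
    set.seed(cl$seed)
    klCurves <- lapply(prep, function(rec) {
      selectKKL(obsOf(rec), kRange = cl$kRange, nInit = cl$nInit)
    })
    k <- as.integer(round(stats::median(vapply(klCurves, optimalK, 0L))))
    log("selected k = %d (median Krzanowski-Lai optimum)", k)
  }

  set.seed(cl$seed)
  subjectModels <- lapply(prep, function(rec) {
    modifiedKMeans(obsOf(rec), k, nInit = cl$nInit,
                   channelNames = channelNames(rec))
  })

  groupsOf <- vapply(prep, groupLabel, "")
  cohortModels <- list()
  for (g in unique(groupsOf)) {
    cohortModels[[g]] <- fitCohort(subjectModels[groupsOf == g], k,
                                   nInit = cl$nInit)
  }

  alignment <- NULL
  gNames <- names(cohortModels)
  if (length(gNames) >= 2) {
    alignment <- alignModels(cohortModels[[gNames[1]]], cohortModels[[gNames[2]]])
  }

  perSubject <- list()
  feat <- NULL
  for (sid in names(prep)) {
    res <- tryCatch(
      {
        rec <- prep[[sid]]
        g <- groupsOf[[sid]]
        seq <- backfit(rec, cohortModels[[g]],
                       minDurationMs = cl$minDurationMs)
        st <- sequenceStats(seq)
        cx <- complexityProfile(rec, seq,
          collapseRuns = config$complexity$collapseRuns,
          normalize = config$complexity$normalize
        )
        sp <- thetaRelativePower(rec,
          theta = config$spectral$theta, total = config$spectral$total
        )
        list(
          sequence = seq, stats = st, complexity = cx, spectral = sp,
          group = g
        )
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[sid]] <- conditionMessage(res)
      log("subject %s failed: %s", sid, conditionMessage(res))
      next
    }
    perSubject[[sid]] <- res
    feat <- rbind(feat, data.frame(
      subject = sid, group = res$group,
      thetaRP = res$spectral$thetaRP, C = res$complexity$C,
      meanDurationMs = res$stats$grandMeanDurationMs,
      stringsAsFactors = FALSE
    ))
  }

  # group statistics over the first two groups
  groupStats <- list()
  gs <- unique(feat$group)
  if (length(gs) >= 2) {
    durTab <- do.call(rbind, lapply(names(perSubject), function(sid) {
      st <- perSubject[[sid]]$stats
      data.frame(
        subject = sid, group = perSubject[[sid]]$group,
        class = seq_len(k), value = st$meanDurationMs,
        stringsAsFactors = FALSE
      )
    }))
    durTab <- durTab[is.finite(durTab$value) &
                       durTab$group %in% gs[1:2], , drop = FALSE]
    groupStats$durationAnova <- tryCatch(twoWayAnova(durTab),
      error = function(e) conditionMessage(e)
    )
    x <- feat$meanDurationMs[feat$group == gs[1]]
    y <- feat$meanDurationMs[feat$group == gs[2]]
    groupStats$durationU <- mannWhitneyZ(x, y)
    groupStats$complexityU <- mannWhitneyZ(
      feat$C[feat$group == gs[1]], feat$C[feat$group == gs[2]]
    )
    ia <- which(groupsOf == gs[1])
    ib <- which(groupsOf == gs[2])
    if (length(ia) >= 2 && length(ib) >= 2 && !is.null(alignment)) {
      groupStats$tanova <- lapply(seq_len(k), function(cls) {
        mA <- do.call(rbind, lapply(subjectModels[ia], function(m) {
          alignModels(cohortModels[[gs[1]]], m)$permutation[cls] |>
            (\(j) microstateMaps(m)[j, ])()
        }))
        mB <- do.call(rbind, lapply(subjectModels[ib], function(m) {
          alignModels(cohortModels[[gs[1]]], m)$permutation[cls] |>
            (\(j) microstateMaps(m)[j, ])()
        }))
        tanova(mA, mB, nPerm = config$tanova$nPerm, seed = config$tanova$seed)
      })
    }
  }

  classifier <- NULL
  if (length(gs) >= 2) {
    cf <- feat[feat$group %in% gs[1:2], , drop = FALSE]
    cf$label <- cf$group
    pos <- if ("AD" %in% gs) "AD" else gs[2]
    classifier <- tryCatch(
      crossvalSVM(cf,
        folds = config$classifier$folds, kernel = config$classifier$kernel,
        cost = config$classifier$cost, positive = pos,
        seed = config$classifier$seed
      ),
      error = function(e) conditionMessage(e)
    )
  }

  out <- list(
    config = config, configHash = hash, k = k, klCurves = klCurves,
    subjectModels = subjectModels, cohortModels = cohortModels,
    alignment = alignment, subjects = perSubject, features = feat,
    groupStats = groupStats, classifier = classifier, failures = failures
  )

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    for (g in names(cohortModels)) {
      writeModelJSON(cohortModels[[g]],
        file.path(outputDir, paste0("cohort_", g, ".json")),
        config = config
      )
    }
    for (sid in names(perSubject)) {
      writeLabelSequenceCSV(
        perSubject[[sid]]$sequence,
        file.path(outputDir, paste0("labels_", sid, ".csv"))
      )
    }
    utils::write.csv(feat, file.path(outputDir, "features.csv"),
                     row.names = FALSE)
    report <- list(
      configHash = hash, k = k,
      groupStats = lapply(groupStats, function(x) {
        if (is.data.frame(x)) x else unclass(x)
      }),
      classifier = if (!is.null(classifier) && is.list(classifier)) {
        unclass(classifier$metrics)
      }
    )
    jsonlite::write_json(report, file.path(outputDir, "report.json"),
      auto_unbox = TRUE, digits = 12, force = TRUE
    )
  }
  out
}
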