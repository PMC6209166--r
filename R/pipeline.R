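#' Pipeline configuration
#'
#' Bundles every tunable of the full workflow with its default.  Defaults
#' follow the method's standard settings: 20\% holdout, automatic bin
#' number from the training-set size, 100 relabeling iterations against an
#' FPR threshold of 0.05, linear SVM cost 10, and Bonferroni-adjusted
#' significance at 0.001.
#'
#' @param manifest path to a manifest CSV with columns \code{sample_id},
#'   \code{group}, \code{path} (tab-delimited cell-by-marker text files, or
#'   FCS files when \code{format = "fcs"}); ignored when a cohort is passed
#'   to [runPipeline()] directly.
#' @param format "matrix" or "fcs".
#' @param blocklist channels excluded from pair enumeration.
#' @param holdoutFraction holdout fraction in (0, 1).
#' @param bins "auto" or a fixed integer.
#' @param calibrate logical: estimate the FPR curve before selection.
#' @param fprIterations relabeling iterations per bin number.
#' @param fprThreshold FPR threshold for the recommended bin number.
#' @param bList candidate bin numbers for calibration.
#' @param svmCost soft-margin cost C.
#' @param alpha adjusted-p significance level.
#' @param balanceMode "strict" or "proportional" (see [balancedSplit()]).
#' @param masterSeed integer seed fanned out to the pipeline stages.
#' @param outDir output directory (created if needed); NULL disables file
#'   output.
#' @return named list of class \code{"cytobinConfig"}.
#' @export
pipelineConfig <- function(manifest = NULL, format = c("matrix", "fcs"),
                           blocklist = character(0),
                           holdoutFraction = 0.2, bins = "auto",
                           calibrate = FALSE, fprIterations = 100L,
                           fprThreshold = 0.05, bList = 2:8,
                           svmCost = 10, alpha = 0.001,
                           balanceMode = c("strict", "proportional"),
                           masterSeed = 1L, outDir = NULL) {
    format <- match.arg(format)
    balanceMode <- match.arg(balanceMode)
    stopifnot(holdoutFraction > 0, holdoutFraction < 1,
              alpha > 0, alpha <= 1, svmCost > 0)
    structure(list(
        manifest = manifest, format = format, blocklist = blocklist,
        holdoutFraction = holdoutFraction, bins = bins,
        calibrate = calibrate, fprIterations = as.integer(fprIterations),
        fprThreshold = fprThreshold, bList = as.integer(bList),
        svmCost = svmCost, alpha = alpha, balanceMode = balanceMode,
        masterSeed = as.integer(masterSeed), outDir = outDir
    ), class = "cytobinConfig")
}

#' Load a cohort from a manifest CSV
#'
#' @param manifest path to a CSV with columns \code{sample_id},
#'   \code{group}, \code{path}; relative paths resolve against the
#'   manifest's directory.
#' @param format "matrix" (tab-delimited text) or "fcs".
#' @return list of labeled [CellSample-class] objects.
#' @export
readManifest <- function(manifest, format = c("matrix", "fcs")) {
    format <- match.arg(format)
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "path")
    if (!all(need %in% names(tab))) {
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    }
    base <- dirname(manifest)
    lapply(seq_len(nrow(tab)), function(i) {
        p <- tab$path[i]
        if (!file.exists(p)) p <- file.path(base, tab$path[i])
        smp <- if (format == "fcs") readFCS(p) else readCellMatrix(p)
        smp@sampleId <- as.character(tab$sample_id[i])
        smp@groupLabel <- as.character(tab$group[i])
        validObject(smp)
        smp
    })
}

#' Write a cohort to text matrices plus a manifest
#'
#' @param cohort list of [CellSample-class] objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(cohort, function(s) {
        p <- file.path(dir, paste0(sampleId(s), ".tsv"))
        writeCellMatrix(s, p)
        basename(p)
    }, character(1))
    manifest <- file.path(dir, "manifest.csv")
    utils::write.csv(data.frame(
        sample_id = vapply(cohort, sampleId, character(1)),
        group = cohortGroups(cohort),
        path = paths
    ), manifest, row.names = FALSE, quote = FALSE)
    invisible(manifest)
}

stageSeed <- function(masterSeed, stage) {
    offsets <- c(calibration = 101L, split = 211L, selection = 307L)
    childSeed(masterSeed, match(stage, names(offsets)), offsets[[stage]])
}

#' Run the full discovery pipeline
#'
#' Ingest, optionally calibrate the bin number, screen all marker pairs for
#' perfect discrimination, test every box of the selected pairs, and write
#' the results.  Stages draw from seeds derived deterministically from the
#' master seed, so reruns with the same configuration are reproducible and
#' stages can be rerun independently.
#'
#' @param config a [pipelineConfig()] list.
#' @param cohort optional pre-loaded labeled cohort; when NULL the
#'   manifest in \code{config} is read.
#' @return list with elements \code{calibration}
#'   ([CalibrationResult-class] or NULL), \code{b} (bin number used),
#'   \code{pairs} (pair screening table), \code{boxes} (box test table or
#'   NULL when no pair was selected), \code{config}.  When
#'   \code{config$outDir} is set, calibration.csv, pairs.csv, boxes.csv and
#'   summary.txt are written there.
#' @export
runPipeline <- function(config = pipelineConfig(), cohort = NULL) {
    stopifnot(inherits(config, "cytobinConfig"))
    if (is.null(cohort)) {
        if (is.null(config$manifest)) {
            stop("stage ingest: no cohort given and no manifest configured; ",
                 "set config$manifest or pass cohort=")
        }
        cohort <- readManifest(config$manifest, config$format)
    }
    groups <- cohortGroups(cohort)
    if (length(unique(groups)) != 2L || min(table(groups)) < 2L) {
        stop("stage ingest: the cohort must contain two groups with at ",
             "least two samples each; found ",
             paste(names(table(groups)), table(groups), sep = "=",
                   collapse = ", "))
    }

    calib <- NULL
    if (isTRUE(config$calibrate)) {
        set.seed(stageSeed(config$masterSeed, "calibration"))
        calib <- tryCatch(
            fprCurve(cohort, bList = config$bList,
                     iterations = config$fprIterations,
                     threshold = config$fprThreshold,
                     blocklist = config$blocklist, C = config$svmCost),
            error = function(e) stop("stage calibrate: ",
                                     conditionMessage(e)))
    }

    set.seed(stageSeed(config$masterSeed, "selection"))
    pairs <- tryCatch(
        selectPairs(cohort, b = config$bins,
                    fraction = config$holdoutFraction,
                    mode = config$balanceMode,
                    blocklist = config$blocklist, C = config$svmCost),
        error = function(e) stop("stage select: ", conditionMessage(e)))
    b <- attr(pairs, "b")

    boxes <- NULL
    sel <- pairs[pairs$selected, , drop = FALSE]
    if (nrow(sel) > 0L) {
        boxes <- tryCatch(
            importantBoxes(cohort, sel, b, alpha = config$alpha),
            error = function(e) stop("stage boxes: ", conditionMessage(e)))
    }

    result <- list(calibration = calib, b = b, pairs = pairs,
                   boxes = boxes, config = config)
    if (!is.null(config$outDir)) writePipelineOutputs(result)
    result
}

writePipelineOutputs <- function(result) {
    dir <- result$config$outDir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("# master_seed: %d", result$config$masterSeed)
    writeTable <- function(df, file) {
        con <- file(file.path(dir, file), "wt")
        on.exit(close(con))
        writeLines(stamp, con)
        utils::write.csv(df, con, row.names = FALSE)
    }
    if (!is.null(result$calibration)) {
        e <- calibrationEntries(result$calibration)
        e$recommended <- e$b == recommendedBins(result$calibration)
        writeTable(e, "calibration.csv")
    }
    writeTable(result$pairs, "pairs.csv")
    if (!is.null(result$boxes)) writeTable(result$boxes, "boxes.csv")
    nSel <- sum(result$pairs$selected)
    summary <- c(
        stamp,
        sprintf("samples: %d", length(attr(result$pairs, "split")$train) +
                    length(attr(result$pairs, "split")$holdout)),
        sprintf("bins: %d", result$b),
        sprintf("selected pairs: %d", nSel),
        if (!is.null(result$boxes)) {
            sprintf("significant boxes: %d", sum(result$boxes$significant))
        },
        if (!is.null(result$calibration)) {
            sprintf("recommended bins (FPR < %g): %d",
                    result$calibration@threshold,
                    recommendedBins(result$calibration))
        }
    )
    writeLines(summary, file.path(dir, "summary.txt"))
    invisible(NULL)
}
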