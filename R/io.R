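# Delimited-text readers and writers for spectra and manifests, and the
# run configuration serialization.

#' Write an acquisition to delimited text
#'
#' Tab-delimited layout: first column the wavenumber axis, then one column
#' per accumulation (`acq_1`, `acq_2`, ...), then the dark frames
#' (`dark_1`, ...).
#'
#' @param acq A [RawAcquisition-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeSpectra <- function(acq, path) {
    stopifnot(is(acq, "RawAcquisition"))
    df <- data.frame(wavenumber = acq@wavenumber, acq@repeats, acq@darks)
    colnames(df) <- c("wavenumber",
                      sprintf("acq_%d", seq_len(ncol(acq@repeats))),
                      sprintf("dark_%d", seq_len(ncol(acq@darks))))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Read an acquisition from delimited text
#'
#' Expects the layout written by [writeSpectra()]: a `wavenumber` column,
#' accumulation columns, and dark columns identified by a `dark` name
#' prefix. The wavenumber axis is validated to be strictly increasing;
#' offending lines are named in the error.
#'
#' @param path Input file path.
#' @param exposure,laserPower Acquisition settings to attach.
#' @return A [RawAcquisition-class].
#' @export
readSpectra <- function(path, exposure = 1, laserPower = 100) {
    df <- read.delim(path, check.names = FALSE)
    if (nrow(df) == 0)
        stop("spectrum file '", path, "' contains no data rows")
    if (!"wavenumber" %in% colnames(df))
        stop("spectrum file '", path, "' lacks a 'wavenumber' column")
    wn <- df$wavenumber
    bad <- which(diff(wn) <= 0)
    if (length(bad))
        stop("non-monotone wavenumber axis in '", path, "' at line ",
             bad[1] + 2L, " (data row ", bad[1] + 1L, ")")
    darkCols <- grep("^dark", colnames(df))
    acqCols <- setdiff(seq_along(df)[-1], darkCols)
    if (length(acqCols) == 0)
        stop("spectrum file '", path, "' has no accumulation columns")
    if (length(darkCols) == 0)
        stop("spectrum file '", path, "' has no dark columns")
    RawAcquisition(wn, as.matrix(df[, acqCols, drop = FALSE]),
                   as.matrix(df[, darkCols, drop = FALSE]),
                   exposure = exposure, laserPower = laserPower,
                   metadata = list(source = path))
}

#' Write / read a measurement manifest
#'
#' @param manifest Manifest data frame.
#' @param path CSV file path.
#' @return `writeManifest`: invisibly `path`; `readManifest`: data frame.
#' @export
writeManifest <- function(manifest, path) {
    write.csv(manifest, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("measurement_id", "patient_id", "pct_cancer", "pct_normal",
              "pct_fat")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop("manifest '", path, "' lacks required columns: ",
             paste(missing, collapse = ", "))
    df
}

.RUNCONFIG_KEYS <- c("cohort", "pipeline", "models", "seed", "outputDir")

#' Run configuration
#'
#' Bundles every knob of an end-to-end run: the cohort generator settings,
#' the preprocessing parameters, the model list and the seed.
#'
#' @param cohort A [cohortSpec()] (or a plain list of its arguments).
#' @param pipeline A [pipelineConfig()].
#' @param models Character vector of model ids to train.
#' @param seed Integer master seed.
#' @param outputDir Where [runAll()] writes its reports.
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(cohort = cohortSpec(), pipeline = pipelineConfig(),
                      models = c("A", "B", "C", "FAT"), seed = 1,
                      outputDir = "raman-run") {
    structure(list(cohort = cohort, pipeline = pipeline, models = models,
                   seed = seed, outputDir = outputDir),
              class = "RunConfig")
}

#' Serialize / restore a run configuration (YAML)
#'
#' Configurations round-trip unchanged; unknown keys in a file are
#' rejected.
#'
#' @param config A [runConfig()].
#' @param path YAML file path.
#' @return `writeRunConfig`: invisibly `path`; `readRunConfig`: a
#'   `"RunConfig"`.
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(inherits(config, "RunConfig"))
    x <- unclass(config)
    x$cohort <- unclass(x$cohort)
    x$cohort$classMixture <- as.list(x$cohort$classMixture)
    x$cohort$axis <- list(from = x$cohort$axis[1],
                          to = x$cohort$axis[length(x$cohort$axis)],
                          by = mean(diff(x$cohort$axis)))
    x$pipeline <- unclass(x$pipeline)
    yaml::write_yaml(x, path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    x <- yaml::read_yaml(path)
    unknown <- setdiff(names(x), .RUNCONFIG_KEYS)
    if (length(unknown))
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    missing <- setdiff(.RUNCONFIG_KEYS, names(x))
    if (length(missing))
        stop("missing configuration keys: ", paste(missing, collapse = ", "))
    ax <- x$cohort$axis
    x$cohort$axis <- defaultAxis(ax$from, ax$to, ax$by)
    x$cohort$classMixture <- unlist(x$cohort$classMixture)
    cohort <- do.call(cohortSpec, x$cohort)
    pipeline <- do.call(pipelineConfig, x$pipeline)
    runConfig(cohort = cohort, pipeline = pipeline,
              models = unlist(x$models), seed = x$seed,
              outputDir = x$outputDir)
}
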