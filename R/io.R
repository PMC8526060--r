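## Plain-text I/O: TSV matrices with JSON metadata side-files, GMT gene
## sets, and YAML a-priori group configurations.

#' Write a MeasureMatrix as TSV with a JSON metadata side-file
#'
#' Values go to a TSV (individuals as rows, measure keys as columns,
#' missing cells empty); batch labels and per-measure metadata go to a
#' JSON side-file.
#'
#' @param m a \linkS4class{MeasureMatrix}.
#' @param file TSV path.
#' @param metaFile JSON side-file path (default: `file` with a
#'   `.meta.json` suffix).
#' @return `file`, invisibly.
#' @export
writeMeasureMatrix <- function(m, file,
                               metaFile = paste0(file, ".meta.json")) {
    stopifnot(is(m, "MeasureMatrix"))
    df <- as.data.frame(m@values)
    write.table(df, file, sep = "\t", quote = FALSE, na = "",
                row.names = TRUE, col.names = NA)
    info <- as.data.frame(m@measureInfo)
    jsonlite::write_json(
        list(individuals = rownames(m@values), batch = m@batch,
             measures = info),
        metaFile, auto_unbox = TRUE, na = "null", pretty = TRUE)
    invisible(file)
}

#' Read a MeasureMatrix written by [writeMeasureMatrix()]
#'
#' @param file TSV path.
#' @param metaFile JSON side-file path.
#' @return A \linkS4class{MeasureMatrix}.
#' @export
readMeasureMatrix <- function(file,
                              metaFile = paste0(file, ".meta.json")) {
    v <- as.matrix(read.table(file, sep = "\t", header = TRUE,
                              row.names = 1L, check.names = FALSE,
                              na.strings = ""))
    meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
    info <- meta$measures
    MeasureMatrix(v, batch = meta$batch, assay = info$assay,
                  measure = info$measure,
                  day = ifelse(is.na(info$day), NA_integer_,
                               as.integer(info$day)),
                  group = info$group)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited format: set name, description, then member gene
#' ids, one set per line.
#'
#' @param file GMT path.
#' @return Named list of character vectors; descriptions in
#'   `attr(., "description")`.
#' @export
readGmt <- function(file) {
    lines <- readLines(file)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(x) x[-(1:2)])
    names(sets) <- vapply(parts, `[`, character(1), 1L)
    attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
    sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param file output path.
#' @param description per-set description column (recycled).
#' @return `file`, invisibly.
#' @export
writeGmt <- function(sets, file, description = "na") {
    description <- rep_len(description, length(sets))
    lines <- vapply(seq_along(sets), function(k) {
        paste(c(names(sets)[k], description[k], sets[[k]]),
              collapse = "\t")
    }, character(1))
    writeLines(lines, file)
    invisible(file)
}

#' Read an a-priori group configuration from YAML
#'
#' The config maps each group name to a list of selectors with fields
#' `assay` (exact match), `measure` (regular expression) and optional
#' `day` (`"*"` or an integer vector; default any).
#'
#' @param file YAML path.
#' @return The parsed configuration (named list of selector lists).
#' @export
readGroupConfig <- function(file) {
    cfg <- yaml::read_yaml(file)
    if (!length(cfg)) stop("empty group configuration")
    cfg
}

#' Apply an a-priori group configuration to a MeasureMatrix
#'
#' Sets the `group` column of `measureInfo(m)` according to the selectors
#' of `config` (see [readGroupConfig()]). Each measure may match at most
#' one group; overlapping selectors are an error.
#'
#' @param m a \linkS4class{MeasureMatrix}.
#' @param config a configuration list (group name -> list of selectors).
#' @return `m` with updated group labels.
#' @export
applyGroupConfig <- function(m, config) {
    stopifnot(is(m, "MeasureMatrix"))
    info <- m@measureInfo
    assigned <- rep(NA_character_, nrow(info))
    for (g in names(config)) {
        sels <- config[[g]]
        if (!is.null(sels$assay) || !is.null(sels$measure))
            sels <- list(sels)      # single selector shorthand
        hit <- rep(FALSE, nrow(info))
        for (sel in sels) {
            h <- rep(TRUE, nrow(info))
            if (!is.null(sel$assay))
                h <- h & info$assay == sel$assay
            if (!is.null(sel$measure))
                h <- h & grepl(sel$measure, info$measure)
            if (!is.null(sel$day) && !identical(sel$day, "*"))
                h <- h & info$day %in% as.integer(sel$day)
            hit <- hit | (h & !is.na(h))
        }
        clash <- hit & !is.na(assigned)
        if (any(clash))
            stop("measure(s) match more than one group: ",
                 paste(head(rownames(info)[clash], 5), collapse = ", "))
        assigned[hit] <- g
    }
    groupLabels(m) <- assigned
    m
}

#' Write a CorrelationResult as TSV files
#'
#' @param x a \linkS4class{CorrelationResult}.
#' @param rFile,pFile output paths for the r and p matrices (either may
#'   be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
writeCorrelationResult <- function(x, rFile = NULL, pFile = NULL) {
    stopifnot(is(x, "CorrelationResult"))
    if (!is.null(rFile))
        write.table(x@r, rFile, sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(pFile))
        write.table(x@p, pFile, sep = "\t", quote = FALSE, col.names = NA)
    invisible(c(rFile, pFile))
}

#' Write a ComponentSpectrum as CSV
#'
#' Emits a `(threshold, n_components)` block followed by a
#' `(k, fraction)` histogram block, separated by a comment line.
#'
#' @param x a \linkS4class{ComponentSpectrum}.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSpectrum <- function(x, file) {
    stopifnot(is(x, "ComponentSpectrum"))
    con <- file(file, "w")
    on.exit(close(con))
    writeLines("threshold,n_components", con)
    writeLines(sprintf("%.10g,%d", x@thresholds, x@nComponents), con)
    writeLines("# histogram", con)
    writeLines("k,fraction", con)
    writeLines(sprintf("%s,%.10g", names(x@histogram), x@histogram), con)
    invisible(file)
}

#' Write turn events as CSV
#'
#' @param x a \linkS4class{TurnSequence}.
#' @param file output path; columns `time`, `direction` and, when
#'   present, `condition`.
#' @return `file`, invisibly.
#' @export
writeTurnSequence <- function(x, file) {
    stopifnot(is(x, "TurnSequence"))
    df <- data.frame(time = x@times, direction = x@directions)
    if (length(x@condition)) df$condition <- x@condition
    write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read turn events from CSV
#'
#' @param file CSV with columns `time`, `direction`, optional
#'   `condition`.
#' @return A \linkS4class{TurnSequence}.
#' @export
readTurnSequence <- function(file) {
    df <- read.table(file, sep = ",", header = TRUE,
                     stringsAsFactors = FALSE)
    TurnSequence(df$time, df$direction,
                 condition = if ("condition" %in% names(df))
                     df$condition else character())
}
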