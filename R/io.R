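## Plate / metadata / trajectory readers and writers. Wide plate CSV: first
## column time_h, one column per well. Writers are atomic (temp file +
## rename) and can embed "# key: value" provenance comments that the
## readers skip.

.atomicWrite <- function(writeFun, path) {
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writeFun(tmp)
    if (!file.rename(tmp, path))
        stop("could not move temporary file onto ", path)
    invisible(path)
}

.writeCsvWithHeader <- function(df, path, comments = NULL, digits = 12) {
    .atomicWrite(function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        for (nm in names(comments))
            writeLines(sprintf("# %s: %s", nm, comments[[nm]]), con)
        isNum <- vapply(df, is.numeric, logical(1))
        df[isNum] <- lapply(df[isNum], function(x)
            trimws(formatC(x, digits = digits, format = "g")))
        write.csv(df, con, row.names = FALSE, quote = FALSE)
    }, path)
}

#' Read a wide plate CSV
#'
#' Strictly validated: the first column must be \code{time_h} and strictly
#' increasing, remaining columns are wells (unique names), all cells
#' numeric, table rectangular. Lines starting with \code{#} are provenance
#' comments and skipped.
#'
#' @param path CSV path.
#' @return a \linkS4class{PlateExperiment} with empty metadata (join with
#'   \code{\link{readWellMetadata}}).
#' @export
readPlate <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    hdr <- strsplit(grep("^#", readLines(path, warn = FALSE),
                         value = TRUE, invert = TRUE)[1], ",")[[1]]
    if (anyDuplicated(hdr))
        stop("duplicate well headers: ",
             paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
    df <- read.csv(path, check.names = FALSE, comment.char = "#")
    if (ncol(df) < 2) stop("plate file needs a time column and >= 1 well")
    if (colnames(df)[1] != "time_h")
        stop("first column must be 'time_h'")
    if (!all(vapply(df, is.numeric, logical(1))))
        stop("non-numeric cells in plate file")
    if (anyNA(df)) stop("ragged or missing cells in plate file")
    tt <- df[[1]]
    if (any(diff(tt) <= 0)) stop("non-monotone time column")
    od <- as.matrix(df[, -1, drop = FALSE])
    PlateExperiment(tt, od)
}

#' Write a plate (and optionally its metadata) to CSV
#'
#' @param plate a \linkS4class{PlateExperiment}.
#' @param path output CSV path for the wide OD table.
#' @param metadataPath optional path for the well-metadata CSV.
#' @param comments named list/vector embedded as \code{# key: value} header
#'   lines (e.g. seed, config hash).
#' @param digits significant digits for numeric payload (default 12).
#' @return the plate path, invisibly.
#' @export
writePlate <- function(plate, path, metadataPath = NULL, comments = NULL,
                       digits = 12) {
    df <- data.frame(time_h = plateTime(plate), check.names = FALSE)
    od <- odMatrix(plate)
    for (w in colnames(od)) df[[w]] <- od[, w]
    .writeCsvWithHeader(df, path, comments, digits)
    if (!is.null(metadataPath)) {
        md <- wellMetadata(plate)
        .writeCsvWithHeader(md, metadataPath, comments, digits)
    }
    invisible(path)
}

#' Join a well-metadata table onto a plate
#'
#' @param plate a \linkS4class{PlateExperiment}.
#' @param metadata data.frame with columns \code{well}, \code{role},
#'   \code{dilution_factor}, \code{true_T0_cfu}, \code{condition},
#'   \code{replicate}. Roles must be adapted/de_novo/blank; every listed
#'   well must exist on the plate; de novo rows must carry a true T0.
#' @return the plate with populated \code{colData}.
#' @export
joinWellMetadata <- function(plate, metadata) {
    req <- c("well", "role", "dilution_factor", "true_T0_cfu",
             "condition", "replicate")
    miss <- setdiff(req, colnames(metadata))
    if (length(miss))
        stop("metadata missing mandatory column(s): ",
             paste(miss, collapse = ", "))
    bad <- setdiff(unique(metadata$role[!is.na(metadata$role)]),
                   .VALID_ROLES)
    if (length(bad))
        stop("invalid role(s): ", paste(bad, collapse = ", "),
             " (expected adapted/de_novo/blank)")
    unknown <- setdiff(metadata$well, colnames(plate))
    if (length(unknown))
        stop("metadata refers to well(s) absent from the plate: ",
             paste(unknown, collapse = ", "))
    dn <- metadata$role == "de_novo" & !is.na(metadata$role)
    if (any(dn & !is.finite(metadata$true_T0_cfu)))
        stop("de_novo wells require a true_T0_cfu value")
    cd <- SummarizedExperiment::colData(plate)
    idx <- match(metadata$well, rownames(cd))
    cd$role[idx] <- as.character(metadata$role)
    cd$dilution_factor[idx] <- as.numeric(metadata$dilution_factor)
    cd$true_T0_cfu[idx] <- as.numeric(metadata$true_T0_cfu)
    cd$condition[idx] <- as.character(metadata$condition)
    cd$replicate[idx] <- as.integer(metadata$replicate)
    SummarizedExperiment::colData(plate) <- cd
    validObject(plate)
    plate
}

#' Read a well-metadata CSV and join it onto a plate
#'
#' @param path metadata CSV path.
#' @param plate the \linkS4class{PlateExperiment} the wells belong to.
#' @return the plate with populated metadata.
#' @export
readWellMetadata <- function(path, plate) {
    if (!file.exists(path)) stop("file not found: ", path)
    md <- read.csv(path, comment.char = "#")
    joinWellMetadata(plate, md)
}

#' Write / read a model trajectory as tidy CSV
#'
#' Columns: time, s0, sd, sa, s1, mu_obs.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path CSV path.
#' @param comments optional provenance comments (see
#'   \code{\link{writePlate}}).
#' @return \code{writeTrajectory}: the path, invisibly;
#'   \code{readTrajectory}: a data.frame.
#' @export
writeTrajectory <- function(traj, path, comments = NULL) {
    .writeCsvWithHeader(as.data.frame(traj), path, comments, digits = 15)
    invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.csv(path, comment.char = "#")
}
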