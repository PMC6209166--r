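# Minimal list-mode FCS reader.  Supports FCS 2.0/3.0/3.1 files with
# $MODE L and $DATATYPE F (float32), D (float64) or I (unsigned integers of
# 8/16/32/64 bits per $PnB), in either byte order.  This covers the files
# standard acquisition software exports; anything more exotic should go
# through the delimited-text fallback (readCellMatrix).

parseFcsText <- function(raw, begin, end) {
    if (end <= begin || end > length(raw)) {
        stop("FCS format error: TEXT segment offsets [", begin, ", ", end,
             "] are out of range")
    }
    txt <- raw[(begin + 1L):(end + 1L)]
    delim <- rawToChar(txt[1])
    body <- rawToChar(txt[-1])
    Encoding(body) <- "latin1"
    # keywords and values alternate, separated by the delimiter; escaped
    # (doubled) delimiters inside values are rare and not supported here
    parts <- strsplit(body, delim, fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
        stop("FCS format error: TEXT segment contains no keyword/value pairs")
    }
    if (length(parts) %% 2L == 1L) parts <- c(parts, "")
    kw <- parts[seq(1, length(parts), by = 2)]
    vals <- parts[seq(2, length(parts), by = 2)]
    names(vals) <- trimws(kw)
    vals
}

fcsKeyword <- function(kw, name, default = NULL) {
    v <- if (name %in% names(kw)) kw[[name]] else NULL
    if (is.null(v) || is.na(v)) {
        if (is.null(default)) {
            stop("FCS format error: required keyword ", name, " is missing")
        }
        return(default)
    }
    v
}

#' Read an FCS list-mode file
#'
#' Parses the header and TEXT segment of an FCS 2.0/3.0/3.1 file and decodes
#' the list-mode DATA segment into a [CellSample-class].  Marker names use
#' the stain name ($PnS) when present and the detector short name ($PnN)
#' otherwise, since analyses are phrased in terms of markers (CD8, CCR7),
#' not detectors.  A spillover matrix stored under $SPILLOVER, SPILL or
#' COMP is attached as attribute \code{"spill"} for use with
#' [applyCompensation()]; compensation is never applied implicitly.
#'
#' @param path path to the FCS file.
#' @param markerSubset optional character vector restricting the channels
#'   kept (matched against the resolved marker names).
#' @param sampleId sample identifier; defaults to the file name.
#' @param groupLabel optional group label.
#' @return A [CellSample-class]; attribute \code{"spill"} holds the
#'   spillover matrix when the file carries one, and attribute
#'   \code{"keywords"} the raw TEXT-segment keywords.
#' @export
readFCS <- function(path, markerSubset = NULL,
                    sampleId = basename(path), groupLabel = "") {
    raw <- readBin(path, what = "raw", n = file.size(path))
    if (length(raw) < 58L) {
        stop("FCS format error: file too short to hold an FCS header")
    }
    version <- rawToChar(raw[1:6])
    if (!grepl("^FCS[23]\\.[01]$", version)) {
        stop("FCS format error: unrecognized version string '", version, "'")
    }
    offs <- suppressWarnings(as.integer(vapply(0:3, function(i) {
        trimws(rawToChar(raw[(11 + i * 8):(18 + i * 8)]))
    }, character(1))))
    if (anyNA(offs[1:2])) {
        stop("FCS format error: unreadable TEXT segment offsets in header")
    }
    kw <- parseFcsText(raw, offs[1], offs[2])

    nPar <- as.integer(fcsKeyword(kw, "$PAR"))
    nTot <- as.integer(fcsKeyword(kw, "$TOT"))
    mode <- fcsKeyword(kw, "$MODE", "L")
    if (!identical(toupper(mode), "L")) {
        stop("FCS format error: only list mode ($MODE L) is supported, got '",
             mode, "'")
    }
    dtype <- toupper(fcsKeyword(kw, "$DATATYPE"))
    byteord <- fcsKeyword(kw, "$BYTEORD", "1,2,3,4")
    endian <- if (startsWith(byteord, "1")) "little" else "big"
    bits <- as.integer(vapply(seq_len(nPar), function(i) {
        fcsKeyword(kw, sprintf("$P%dB", i))
    }, character(1)))

    dataBegin <- as.integer(fcsKeyword(kw, "$BEGINDATA", offs[3]))
    dataEnd <- as.integer(fcsKeyword(kw, "$ENDDATA", offs[4]))
    if (is.na(dataBegin) || dataBegin <= 0L) {
        stop("FCS format error: DATA segment offset missing ",
             "($BEGINDATA and header both absent)")
    }
    expected <- nTot * sum(bits) / 8
    avail <- length(raw) - dataBegin
    if (avail < expected) {
        stop("FCS format error: DATA segment truncated (need ", expected,
             " bytes, found ", avail, ")")
    }
    dataRaw <- raw[(dataBegin + 1L):(dataBegin + expected)]

    if (dtype %in% c("F", "D")) {
        size <- if (dtype == "F") 4L else 8L
        if (any(bits != size * 8L)) {
            stop("FCS format error: $PnB inconsistent with $DATATYPE ", dtype)
        }
        vals <- readBin(dataRaw, what = "double", n = nPar * nTot,
                        size = size, endian = endian)
    } else if (dtype == "I") {
        if (length(unique(bits)) != 1L) {
            stop("FCS format error: mixed $PnB widths for integer data ",
                 "are not supported")
        }
        size <- bits[1] %/% 8L
        if (!size %in% c(1L, 2L, 4L, 8L)) {
            stop("FCS format error: unsupported integer width ", bits[1])
        }
        vals <- readBin(dataRaw, what = "integer", n = nPar * nTot,
                        size = min(size, 4L), endian = endian,
                        signed = size >= 4L)
        vals <- as.numeric(vals)
        # 32-bit values read as signed; fold negatives back to unsigned
        if (size == 4L) vals[vals < 0] <- vals[vals < 0] + 2^32
    } else {
        stop("FCS format error: unsupported $DATATYPE '", dtype, "'")
    }
    mat <- matrix(vals, nrow = nTot, ncol = nPar, byrow = TRUE)

    shortNames <- vapply(seq_len(nPar), function(i) {
        fcsKeyword(kw, sprintf("$P%dN", i), sprintf("P%d", i))
    }, character(1))
    stainNames <- vapply(seq_len(nPar), function(i) {
        fcsKeyword(kw, sprintf("$P%dS", i), "")
    }, character(1))
    markers <- ifelse(nzchar(stainNames), stainNames, shortNames)
    if (anyDuplicated(markers)) {
        stop("FCS format error: resolved marker names are not unique: ",
             paste(unique(markers[duplicated(markers)]), collapse = ", "))
    }
    colnames(mat) <- markers

    if (!is.null(markerSubset)) {
        missing <- setdiff(markerSubset, markers)
        if (length(missing)) {
            stop("marker(s) not found: ", paste(missing, collapse = ", "),
                 "; available channels: ", paste(markers, collapse = ", "))
        }
        mat <- mat[, markerSubset, drop = FALSE]
    }
    out <- cellSample(mat, sampleId = sampleId, groupLabel = groupLabel)
    spillKw <- intersect(c("$SPILLOVER", "SPILL", "COMP", "$COMP"), names(kw))
    if (length(spillKw)) {
        attr(out, "spill") <- parseSpillKeyword(kw[[spillKw[1]]])
    }
    attr(out, "keywords") <- kw
    out
}

# "$SPILLOVER" value format: n,name1,...,namen,s11,s12,...,snn (row-major)
parseSpillKeyword <- function(value) {
    parts <- strsplit(value, ",", fixed = TRUE)[[1]]
    n <- as.integer(parts[1])
    if (is.na(n) || length(parts) != 1L + n + n * n) {
        stop("FCS format error: malformed spillover keyword")
    }
    nm <- parts[2:(n + 1)]
    m <- matrix(as.numeric(parts[-(1:(n + 1))]), nrow = n, byrow = TRUE,
                dimnames = list(nm, nm))
    m
}

#' Apply spillover compensation
#'
#' Replaces the intensities of the markers named by the spill matrix with
#' \code{intensities \%*\% solve(spill)}, the standard unmixing of
#' fluorescence spillover.  Markers not named by the matrix pass through
#' unchanged.
#'
#' @param sample a [CellSample-class].
#' @param spill square numeric matrix with identical row/column names that
#'   are a subset of the sample's markers; if missing, the matrix attached
#'   by [readFCS()] (attribute \code{"spill"}) is used.
#' @return The compensated [CellSample-class].
#' @export
applyCompensation <- function(sample, spill = attr(sample, "spill")) {
    stopifnot(is(sample, "CellSample"))
    if (is.null(spill)) {
        stop("no spill matrix supplied and none attached to the sample")
    }
    spill <- as.matrix(spill)
    if (nrow(spill) != ncol(spill)) stop("spill matrix must be square")
    nm <- colnames(spill)
    if (is.null(nm) || !identical(nm, rownames(spill))) {
        stop("spill matrix must carry identical row and column names")
    }
    missing <- setdiff(nm, markerNames(sample))
    if (length(missing)) {
        stop("spill matrix names not present in sample: ",
             paste(missing, collapse = ", "))
    }
    inv <- tryCatch(solve(spill), error = function(e) {
        stop("spill matrix is singular or ill-conditioned: ",
             conditionMessage(e))
    })
    x <- intensities(sample)
    x[, nm] <- x[, nm, drop = FALSE] %*% inv
    cellSample(x, sampleId = sampleId(sample),
               groupLabel = groupLabel(sample))
}

#' Read / write a cell-by-marker matrix as delimited text
#'
#' The format-agnostic fallback for cytometry data that did not come from an
#' FCS file, and the package's own interchange format: a tab-delimited table
#' whose header row holds the marker names, preceded by comment lines
#' \code{# sample_id: ...} and \code{# group_label: ...}.  Values are
#' printed at 9 significant digits, enough for a bitwise round trip of
#' float32-precision cytometry data.
#'
#' @param path file path.
#' @param sample a [CellSample-class] (for writing).
#' @return \code{readCellMatrix()} returns a [CellSample-class];
#'   \code{writeCellMatrix()} returns \code{path} invisibly.
#' @export
readCellMatrix <- function(path) {
    lines <- readLines(path)
    if (length(lines) < 2L) {
        stop("format error in '", path, "': need a header row and at ",
             "least one data row")
    }
    sid <- basename(path)
    grp <- ""
    meta <- grep("^#", lines)
    for (i in meta) {
        if (grepl("^#\\s*sample_id:", lines[i])) {
            sid <- trimws(sub("^#\\s*sample_id:", "", lines[i]))
        } else if (grepl("^#\\s*group_label:", lines[i])) {
            grp <- trimws(sub("^#\\s*group_label:", "", lines[i]))
        }
    }
    bodyIdx <- if (length(meta)) setdiff(seq_along(lines), meta) else
        seq_along(lines)
    body <- lines[bodyIdx]
    if (length(body) < 2L) {
        stop("format error in '", path, "': no data rows")
    }
    header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    rows <- strsplit(body[-1], "\t", fixed = TRUE)
    widths <- lengths(rows)
    bad <- which(widths != length(header))
    if (length(bad)) {
        stop("format error in '", path, "': line ", bodyIdx[bad[1] + 1L],
             " has ", widths[bad[1]], " fields, expected ", length(header))
    }
    mat <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                  ncol = length(header), byrow = TRUE)
    if (anyNA(mat)) {
        stop("format error in '", path, "': non-numeric intensity values")
    }
    colnames(mat) <- header
    cellSample(mat, sampleId = sid, groupLabel = grp)
}

#' @rdname readCellMatrix
#' @export
writeCellMatrix <- function(sample, path) {
    stopifnot(is(sample, "CellSample"))
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c(
        paste0("# sample_id: ", sampleId(sample)),
        paste0("# group_label: ", groupLabel(sample)),
        paste(markerNames(sample), collapse = "\t")
    ), con)
    x <- format(intensities(sample), digits = 9, trim = TRUE,
                scientific = FALSE)
    writeLines(apply(x, 1, paste, collapse = "\t"), con)
    invisible(path)
}
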