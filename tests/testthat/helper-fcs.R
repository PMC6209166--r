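# Minimal FCS 3.1 list-mode writer used to build synthetic fixtures at test
# time (the package itself never writes FCS).  Supports float32/float64/
# uint16 data, little or big endian, optional $PnS stain names and an
# optional $SPILLOVER keyword.
writeSyntheticFCS <- function(path, mat, stainNames = NULL,
                              datatype = c("F", "D", "I"),
                              endian = c("little", "big"),
                              spill = NULL, dropTot = FALSE) {
    datatype <- match.arg(datatype)
    endian <- match.arg(endian)
    nPar <- ncol(mat)
    nTot <- nrow(mat)
    bits <- switch(datatype, F = 32L, D = 64L, I = 16L)
    size <- bits %/% 8L

    kv <- c(
        "$DATATYPE", datatype,
        "$MODE", "L",
        "$BYTEORD", if (endian == "little") "1,2,3,4" else "4,3,2,1",
        "$PAR", as.character(nPar),
        if (!dropTot) c("$TOT", as.character(nTot)),
        "$NEXTDATA", "0"
    )
    for (i in seq_len(nPar)) {
        kv <- c(kv, sprintf("$P%dB", i), as.character(bits),
                sprintf("$P%dN", i), colnames(mat)[i],
                sprintf("$P%dR", i), "262144",
                sprintf("$P%dE", i), "0,0")
        if (!is.null(stainNames) && nzchar(stainNames[i])) {
            kv <- c(kv, sprintf("$P%dS", i), stainNames[i])
        }
    }
    if (!is.null(spill)) {
        kv <- c(kv, "$SPILLOVER", paste(
            c(nrow(spill), colnames(spill), t(spill)), collapse = ","))
    }

    # two-pass: sizes of BEGINDATA/ENDDATA values can change the TEXT length
    buildText <- function(dataBegin, dataEnd) {
        paste0("/", paste(c(kv, "$BEGINDATA", dataBegin,
                            "$ENDDATA", dataEnd), collapse = "/"), "/")
    }
    headerLen <- 58L
    txt <- buildText(0, 0)
    for (rep in 1:3) {
        dataBegin <- headerLen + nchar(txt)
        dataEnd <- dataBegin + nTot * nPar * size - 1L
        txt2 <- buildText(dataBegin, dataEnd)
        if (nchar(txt2) == nchar(txt)) break
        txt <- txt2
    }
    txt <- txt2

    textBegin <- headerLen
    textEnd <- textBegin + nchar(txt) - 1L
    header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                      textBegin, textEnd, dataBegin, dataEnd, 0L, 0L)
    stopifnot(nchar(header) == headerLen)

    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    writeChar(txt, con, eos = NULL)
    vals <- as.vector(t(mat))   # event-major (row-major) order
    if (datatype == "I") {
        writeBin(as.integer(vals), con, size = size, endian = endian)
    } else {
        writeBin(as.double(vals), con, size = size, endian = endian)
    }
    invisible(path)
}

randomEventMatrix <- function(nCells = 100, markers = c("FSC", "SSC", "FL1"),
                              seed = 1) {
    set.seed(seed)
    mat <- matrix(round(runif(nCells * length(markers), 0, 1000), 2),
                  nrow = nCells, dimnames = list(NULL, markers))
    mat
}
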