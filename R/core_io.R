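#' Experimental sampling grid and succession phase windows
#'
#' The particle-colonization experiments sample each flask at eleven fixed
#' times over 204 hours. Succession phases are defined on that clock:
#' attachment (0-12 h), selection (12-60 h), a transition window (60-108 h)
#' in which community membership mixes, and facilitation (108-204 h).
#'
#' @return `samplingGrid()` returns the eleven sampling times in hours.
#'   `phaseWindows()` returns a data.frame with one row per phase and its
#'   closed/open window bounds. `phaseForTime()` maps times (hours) to phase
#'   labels.
#' @examples
#' samplingGrid()
#' phaseForTime(c(0, 36, 72, 156))
#' @export
samplingGrid <- function() c(0, 12, 24, 36, 48, 60, 72, 108, 132, 156, 204)

#' @rdname samplingGrid
#' @export
phaseWindows <- function() {
    data.frame(
        phase = c("attachment", "selection", "transition", "facilitation"),
        lower = c(0, 12, 60, 108),
        upper = c(12, 60, 108, 204),
        # closed on the left except selection; transition open both sides
        lower_closed = c(TRUE, FALSE, FALSE, TRUE),
        upper_closed = c(TRUE, TRUE, FALSE, TRUE))
}

#' @rdname samplingGrid
#' @param time_h numeric vector of times in hours.
#' @export
phaseForTime <- function(time_h) {
    w <- phaseWindows()
    out <- rep("unlabeled", length(time_h))
    for (r in seq_len(nrow(w))) {
        lo <- if (w$lower_closed[r]) time_h >= w$lower[r] else time_h > w$lower[r]
        hi <- if (w$upper_closed[r]) time_h <= w$upper[r] else time_h < w$upper[r]
        out[lo & hi] <- w$phase[r]
    }
    out
}

#' Minimum temporal separation between two phases on the sampling grid
#'
#' Smallest time difference between a grid sample falling in `phase_a` and
#' one falling in `phase_b`; e.g. the selection and facilitation phases are
#' separated by at least 48 h (last selection sample 60 h, first
#' facilitation sample 108 h), the width of the transition window.
#'
#' @param phase_a,phase_b phase labels from [phaseWindows()].
#' @param grid sampling times in hours; defaults to [samplingGrid()].
#' @return minimum separation in hours.
#' @examples
#' phaseSeparation("selection", "facilitation")  # 48
#' @export
phaseSeparation <- function(phase_a, phase_b, grid = samplingGrid()) {
    ph <- phaseForTime(grid)
    ta <- grid[ph == phase_a]
    tb <- grid[ph == phase_b]
    if (!length(ta) || !length(tb))
        stop("phase not represented on the grid")
    min(abs(outer(ta, tb, "-")))
}

#' Read a samples-by-taxa count table
#'
#' Supports a tab-separated dialect (first column `sample_id`, header row of
#' taxon identifiers, UTF-8) and BIOM (JSON, format 1.0) tables. BIOM stores
#' observations (taxa) in rows; the result is always oriented samples in
#' rows.
#'
#' @param path path to the table.
#' @param format `"tsv"` or `"biom"`.
#' @return A [CountTable-class].
#' @seealso [writeCountTable()]
#' @export
readCountTable <- function(path, format = c("tsv", "biom")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "biom") {
        b <- biomformat::read_biom(path)
        m <- t(as(biomformat::biom_data(b), "matrix"))
        return(CountTable(m))
    }
    df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (ncol(df) < 2)
        stop("malformed header: need a sample_id column plus taxon columns")
    if (nrow(df) == 0) stop("validation error: empty data section")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    for (j in seq_len(ncol(m))) {
        col <- suppressWarnings(as.numeric(m[, j]))
        bad <- which(is.na(col) | col < 0 | col != round(col))
        if (length(bad))
            stop(sprintf(
                "validation error: cell at sample '%s', taxon '%s' is not a non-negative integer",
                ids[bad[1]], colnames(m)[j]))
    }
    storage.mode(m) <- "double"
    CountTable(m, sample_ids = ids)
}

#' Write a count table in the package TSV dialect
#'
#' @param table a [CountTable-class].
#' @param path output path.
#' @return `path`, invisibly. Round trips through [readCountTable()] are
#'   bit-exact for integer tables.
#' @export
writeCountTable <- function(table, path) {
    stopifnot(is(table, "CountTable"))
    df <- data.frame(sample_id = sampleIDs(table), counts(table),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Read and validate sample metadata
#'
#' Metadata carry one row per sample with columns `sample_id`, `substrate`,
#' `replicate`, `time_h` and `phase`. Phases must agree with the default
#' phase map ([phaseForTime()]) unless labeled `"unlabeled"`.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readSampleInfo <- function(path) {
    df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    validateSampleInfo(df)
}

#' @rdname readSampleInfo
#' @param info a data.frame to validate in place.
#' @export
validateSampleInfo <- function(info) {
    need <- c("sample_id", "substrate", "replicate", "time_h", "phase")
    miss <- setdiff(need, names(info))
    if (length(miss)) stop("missing metadata columns: ",
                           paste(miss, collapse = ", "))
    if (anyDuplicated(info$sample_id)) stop("duplicated sample_id")
    if (any(!is.finite(info$time_h)) || any(info$time_h < 0))
        stop("time_h must be non-negative")
    expected <- phaseForTime(info$time_h)
    lab <- info$phase != "unlabeled"
    if (any(info$phase[lab] != expected[lab]))
        stop("phase labels inconsistent with the default phase map for: ",
             paste(info$sample_id[lab][info$phase[lab] != expected[lab]],
                   collapse = ", "))
    info
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples whose total is below
#' `depth` are dropped and reported. The default depth of 1000 reads matches
#' the convention of rarefying to the smallest library.
#'
#' @param table a [CountTable-class].
#' @param depth target reads per sample (positive integer).
#' @param seed integer seed for the subsampling.
#' @return A rarefied [CountTable-class]; dropped sample identifiers are in
#'   `attr(, "dropped")`.
#' @examples
#' ct <- CountTable(matrix(c(800, 1500, 400, 600), 2, 2))
#' rarefy(ct, depth = 1000, seed = 1)
#' @export
rarefy <- function(table, depth = 1000, seed = 1) {
    stopifnot(is(table, "CountTable"))
    if (length(depth) != 1 || depth < 1 || depth != round(depth))
        stop("depth must be a positive integer")
    x <- counts(table)
    tot <- rowSums(x)
    keep <- tot >= depth
    if (!any(keep))
        stop("all samples fall below the rarefaction depth")
    dropped <- rownames(x)[!keep]
    if (length(dropped))
        message("dropping ", length(dropped),
                " sample(s) below depth ", depth, ": ",
                paste(dropped, collapse = ", "))
    x <- x[keep, , drop = FALSE]
    set.seed(seed)
    out <- x
    for (i in seq_len(nrow(x))) {
        n <- sum(x[i, ])
        if (n == depth) next                      # already at depth
        reads <- rep.int(seq_len(ncol(x)), x[i, ])
        pick <- sample(reads, depth, replace = FALSE)
        out[i, ] <- tabulate(pick, nbins = ncol(x))
    }
    res <- CountTable(out)
    attr(res, "dropped") <- dropped
    res
}

.is_pure_dna <- function(s) !grepl("[^ACGT]", s)

#' Match isolate 16S sequences to exact sequence variants
#'
#' An ESV matches an isolate when the ESV sequence is an exact substring of
#' the isolate's 16S sequence, in forward or reverse-complement orientation
#' (the deterministic equivalent of a 100% identity, 100% query-coverage
#' hit). Positions carrying IUPAC ambiguity codes never count as identical,
#' so ESVs containing ambiguity codes cannot match. Isolates without any
#' match are flagged as discarded from downstream propensity analysis.
#'
#' @param esv_seqs named character vector or [Biostrings::DNAStringSet] of
#'   ESV sequences (queries).
#' @param isolate_seqs named character vector or DNAStringSet of isolate 16S
#'   sequences (subjects).
#' @return named list, one element per isolate, each a character vector of
#'   matching ESV identifiers (possibly empty); discarded isolates in
#'   `attr(, "discarded")`.
#' @export
matchIsolates <- function(esv_seqs, isolate_seqs) {
    esv <- .as_seq_chr(esv_seqs, "esv")
    iso <- .as_seq_chr(isolate_seqs, "isolate")
    if (any(nchar(esv) == 0) || any(nchar(iso) == 0))
        stop("validation error: empty sequence")
    rc <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
    esv_rc <- rc(esv)
    usable <- .is_pure_dna(esv)                   # ambiguity codes never match
    res <- lapply(iso, function(subject) {
        hit <- usable &
            (vapply(esv, grepl, logical(1), x = subject, fixed = TRUE) |
             vapply(esv_rc, grepl, logical(1), x = subject, fixed = TRUE))
        names(esv)[hit]
    })
    attr(res, "discarded") <- names(iso)[vapply(res, length, 1L) == 0]
    res
}

.as_seq_chr <- function(x, what) {
    if (methods::is(x, "XStringSet")) x <- as.character(x)
    if (!is.character(x)) stop(what, " sequences must be character or DNAStringSet")
    if (is.null(names(x))) names(x) <- paste0(what, seq_along(x))
    toupper(x)
}

#' Read FASTA sequences as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
readFasta <- function(path) {
    s <- Biostrings::readDNAStringSet(path)
    setNames(toupper(as.character(s)), names(s))
}
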