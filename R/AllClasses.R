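#' @useDynLib particleSuccession, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats aov coef dnbinom median optim optimHess p.adjust
#'   pgamma pnorm pchisq pt ptukey qnorm qt quantile rbeta rbinom rexp
#'   rgamma rmultinom rnbinom rnorm runif sd setNames t.test var TukeyHSD
#' @importFrom utils read.delim write.table head
#' @importFrom grDevices nclass.Sturges
NULL

#' Samples-by-taxa count table
#'
#' Container for an amplicon (ESV) count matrix with samples in rows and taxa
#' in columns. Entries are non-negative integers; row names are sample
#' identifiers and column names are taxon identifiers, both unique.
#'
#' @slot counts integer-valued matrix, M samples x S taxa, with complete
#'   unique dimnames.
#'
#' @seealso [readCountTable()], [rarefy()], [CountTable()]
#' @exportClass CountTable
setClass("CountTable", representation(counts = "matrix"))

setValidity("CountTable", function(object) {
    x <- object@counts
    msg <- character()
    if (is.null(rownames(x)) || is.null(colnames(x)))
        msg <- c(msg, "counts must have sample (row) and taxon (column) names")
    else {
        if (anyDuplicated(rownames(x)))
            msg <- c(msg, "duplicated sample identifiers")
        if (anyDuplicated(colnames(x)))
            msg <- c(msg, "duplicated taxon identifiers")
    }
    if (!is.numeric(x))
        msg <- c(msg, "counts must be numeric")
    else {
        if (any(!is.finite(x)))
            msg <- c(msg, "counts must be finite")
        else {
            if (any(x < 0)) msg <- c(msg, "counts must be non-negative")
            if (any(x != round(x))) msg <- c(msg, "counts must be integers")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CountTable
#'
#' @param counts numeric matrix of non-negative integers (samples x taxa).
#' @param sample_ids,taxon_ids optional identifier vectors; defaults to the
#'   matrix dimnames, or `sample1..M` / `taxon1..S` when absent.
#' @return A [CountTable-class] object.
#' @examples
#' ct <- CountTable(matrix(c(3, 1, 0, 2), 2, 2))
#' rowSums(counts(ct))
#' @export
CountTable <- function(counts, sample_ids = NULL, taxon_ids = NULL) {
    counts <- as.matrix(counts)
    if (!is.null(sample_ids)) rownames(counts) <- sample_ids
    if (!is.null(taxon_ids)) colnames(counts) <- taxon_ids
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
    storage.mode(counts) <- "double"
    new("CountTable", counts = counts)
}

#' Dirichlet-multinomial mixture fit
#'
#' Result of [fitDMM()]: K Dirichlet components over taxa, mixture weights,
#' per-sample posterior membership (responsibilities), and the Laplace
#' approximation of the negative log model evidence used for selecting K.
#'
#' @slot K integer number of mixture components.
#' @slot alpha K x S matrix of positive Dirichlet parameters, one row per
#'   component.
#' @slot weights numeric simplex of length K.
#' @slot responsibilities M x K matrix; rows sum to 1.
#' @slot negLogEvidence Laplace-approximated negative log evidence (nats).
#' @slot logLik maximized observed-data log-likelihood.
#' @slot converged logical; EM convergence status.
#' @slot iterations integer EM iterations used.
#' @exportClass DMMFit
setClass("DMMFit", representation(
    K = "integer", alpha = "matrix", weights = "numeric",
    responsibilities = "matrix", negLogEvidence = "numeric",
    logLik = "numeric", converged = "logical", iterations = "integer"))

setValidity("DMMFit", function(object) {
    msg <- character()
    if (any(object@alpha <= 0)) msg <- c(msg, "alpha entries must be > 0")
    rs <- rowSums(object@responsibilities)
    if (any(abs(rs - 1) > 1e-9))
        msg <- c(msg, "responsibility rows must sum to 1")
    if (!is.finite(object@negLogEvidence))
        msg <- c(msg, "negLogEvidence must be finite")
    if (length(msg)) msg else TRUE
})

#' Posterior of the Hierarchical Dirichlet Process neutral model
#'
#' Retained MCMC draws from [fitHDP()]: the metacommunity distribution over
#' observed taxa plus an explicit "unobserved" mass component, the
#' biodiversity (speciation) parameter theta, per-sample immigration rates,
#' and the Dirichlet-multinomial log-likelihood of the data at each draw.
#'
#' @slot beta draws x (S+1) matrix; each row a simplex, last column the
#'   unobserved-taxa mass.
#' @slot theta numeric vector of draws.
#' @slot immigration draws x M matrix of immigration rates.
#' @slot logLik numeric vector, observed-data log-likelihood per draw.
#' @slot settings list(sweeps, burn_in, thinning, seed).
#' @slot sampleIDs,taxonIDs identifiers of the fitted table.
#' @slot gewekeZ Geweke z statistic of the log-likelihood trace.
#' @exportClass HDPPosterior
setClass("HDPPosterior", representation(
    beta = "matrix", theta = "numeric", immigration = "matrix",
    logLik = "numeric", settings = "list",
    sampleIDs = "character", taxonIDs = "character", gewekeZ = "numeric"))

setValidity("HDPPosterior", function(object) {
    msg <- character()
    if (any(abs(rowSums(object@beta) - 1) > 1e-9))
        msg <- c(msg, "beta draws must sum to 1")
    if (any(object@theta <= 0)) msg <- c(msg, "theta draws must be positive")
    if (any(object@immigration <= 0))
        msg <- c(msg, "immigration draws must be positive")
    if (length(msg)) msg else TRUE
})

#' Result of the neutrality pseudo-p test
#'
#' @slot variant "complete" (neutral metacommunity and local communities) or
#'   "local" (only local communities neutral).
#' @slot pseudoP empirical pseudo p-value: fraction of retained posterior
#'   draws in which the observed log-likelihood exceeds that of the matched
#'   synthetic neutral data set.
#' @slot nDraws number of retained draws (resolution of the pseudo p).
#' @slot reject decision at the stated threshold.
#' @slot threshold rejection threshold (default 0.001).
#' @slot logLikObs,logLikSyn per-draw observed and synthetic log-likelihoods.
#' @exportClass NeutralityResult
setClass("NeutralityResult", representation(
    variant = "character", pseudoP = "numeric", nDraws = "integer",
    reject = "logical", threshold = "numeric",
    logLikObs = "numeric", logLikSyn = "numeric"))

#' Pairwise beta-nearest-taxon index matrices
#'
#' @slot bmntd observed pairwise abundance-weighted beta mean nearest taxon
#'   distances.
#' @slot nullMean,nullSD moments of the tip-shuffle null per pair.
#' @slot bnti z-scores (betaNTI); `NA` where the null SD is zero.
#' @slot significant logical mask, `abs(bnti) > 2`.
#' @slot classification character matrix: "homogeneous_selection",
#'   "variable_selection", "indeterminate", or "undefined".
#' @slot nNull number of null realizations.
#' @exportClass BNTIMatrix
setClass("BNTIMatrix", representation(
    bmntd = "matrix", nullMean = "matrix", nullSD = "matrix",
    bnti = "matrix", significant = "matrix", classification = "matrix",
    nNull = "integer"))

#' Zero-inflated negative binomial fit for one taxon
#'
#' @slot countCoefs coefficient table (estimate, se, z, p) of the count part
#'   (log link, intercept = attachment reference).
#' @slot zeroCoefs coefficient table of the zero-inflation part (logit link).
#' @slot dispersion negative binomial size parameter (>0).
#' @slot logLik maximized log-likelihood.
#' @slot vcov joint covariance matrix of all free parameters.
#' @slot converged logical.
#' @slot zeroInflated FALSE when the fit fell back to a plain negative
#'   binomial because the zero part was unidentifiable.
#' @exportClass ZINBFit
setClass("ZINBFit", representation(
    countCoefs = "matrix", zeroCoefs = "matrix", dispersion = "numeric",
    logLik = "numeric", vcov = "matrix", converged = "logical",
    zeroInflated = "logical"))

#' Gene or pathway proportion table
#'
#' Features (pathways, gene families) in rows, samples in columns; each
#' column is a composition summing to 1. A group label per sample drives the
#' differential-proportion tests.
#'
#' @slot proportions features x samples matrix, columns on the simplex.
#' @slot groups character vector of per-sample group labels.
#' @exportClass GeneProfileTable
setClass("GeneProfileTable",
         representation(proportions = "matrix", groups = "character"))

setValidity("GeneProfileTable", function(object) {
    msg <- character()
    x <- object@proportions
    if (is.null(rownames(x))) msg <- c(msg, "features must be named")
    else if (anyDuplicated(rownames(x))) msg <- c(msg, "duplicated features")
    if (any(x < 0)) msg <- c(msg, "proportions must be non-negative")
    if (any(abs(colSums(x) - 1) > 1e-9))
        msg <- c(msg, "columns must sum to 1")
    if (length(object@groups) != ncol(x))
        msg <- c(msg, "one group label per sample required")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneProfileTable, normalizing columns to proportions
#'
#' @param x features x samples matrix of non-negative counts or proportions;
#'   columns are renormalized to sum to 1.
#' @param groups per-sample group labels.
#' @return A [GeneProfileTable-class] object.
#' @export
GeneProfileTable <- function(x, groups) {
    x <- as.matrix(x)
    if (is.null(rownames(x)))
        rownames(x) <- paste0("feature", seq_len(nrow(x)))
    cs <- colSums(x)
    if (any(cs <= 0)) stop("every sample needs a positive total")
    x <- sweep(x, 2, cs, "/")
    new("GeneProfileTable", proportions = x, groups = as.character(groups))
}
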