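## Hierarchical Dirichlet Process neutral-model fitting and the empirical
## pseudo-p neutrality test.

.geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
    n <- length(x)
    a <- x[seq_len(max(2, floor(frac1 * n)))]
    b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

#' Fit the Hierarchical Dirichlet Process neutral model
#'
#' Collapsed Gibbs sampling over latent ancestral ("table") counts in the
#' Chinese-restaurant-franchise representation: the metacommunity
#' distribution (over observed taxa plus an explicit unobserved-taxa mass)
#' is redrawn from its Dirichlet conditional, while the speciation
#' parameter theta and the per-sample immigration rates are updated by
#' slice sampling under weakly informative log-normal priors (median 1,
#' sigma 2 on the log scale). The default schedule keeps
#' `(sweeps - burn_in) / thinning = 2500` draws; a reduced schedule such as
#' `sweeps = 5000, burn_in = 2500` is appropriate for desk-scale work.
#'
#' @param table a [CountTable-class]; samples with zero total are excluded
#'   with a warning.
#' @param sweeps,burn_in,thinning MCMC schedule; `sweeps > burn_in` and
#'   `(sweeps - burn_in)` divisible by `thinning`.
#' @param seed integer seed.
#' @param prior_mu,prior_sd log-normal prior on theta and the immigration
#'   rates (log scale).
#' @return An [HDPPosterior-class]; a Geweke |z| > 3 on the log-likelihood
#'   trace raises a non-fatal warning and is stored in the object.
#' @export
fitHDP <- function(table, sweeps = 50000, burn_in = 25000, thinning = 10,
                   seed = 1, prior_mu = 0, prior_sd = 2) {
    stopifnot(is(table, "CountTable"))
    if (sweeps <= burn_in) stop("sweeps must exceed burn_in")
    if ((sweeps - burn_in) %% thinning != 0)
        stop("(sweeps - burn_in) must be divisible by thinning")
    X <- counts(table)
    tot <- rowSums(X)
    if (any(tot == 0)) {
        warning("excluding ", sum(tot == 0), " sample(s) with zero total")
        X <- X[tot > 0, , drop = FALSE]
    }
    if (nrow(X) == 0) stop("no non-empty samples")
    storage.mode(X) <- "integer"
    set.seed(seed)
    fit <- cpp_hdp_gibbs(X, as.integer(sweeps), as.integer(burn_in),
                         as.integer(thinning), prior_mu, prior_sd)
    gz <- .geweke_z(fit$loglik)
    if (is.finite(gz) && abs(gz) > 3)
        warning("log-likelihood trace may not have converged (Geweke |z| = ",
                round(abs(gz), 2), ")")
    new("HDPPosterior",
        beta = fit$beta, theta = as.numeric(fit$theta),
        immigration = fit$immigration, logLik = as.numeric(fit$loglik),
        settings = list(sweeps = as.integer(sweeps),
                        burn_in = as.integer(burn_in),
                        thinning = as.integer(thinning), seed = seed),
        sampleIDs = rownames(X), taxonIDs = colnames(X),
        gewekeZ = as.numeric(gz))
}

#' Empirical pseudo-p test of neutral community assembly
#'
#' For each retained posterior draw, a synthetic count matrix with the same
#' samples and per-sample depths is generated from the neutral model --
#' under the `complete` variant the metacommunity itself is redrawn from
#' the neutral (stick-breaking) prior at that draw's theta; under the
#' `local` variant the fitted metacommunity distribution is kept -- the
#' metacommunity distribution is refit on the synthetic matrix, and the
#' observed log-likelihood is compared with the synthetic one. The pseudo
#' p-value is the fraction of draws in which the observed data are the
#' more likely; neutrality is rejected when it falls below `threshold`
#' (default 0.001). A pseudo p of exactly 0 is printed as `< 1/n_draws`.
#'
#' @param table the [CountTable-class] the posterior was fitted on.
#' @param variant `"complete"` or `"local"`.
#' @param posterior an [HDPPosterior-class] from [fitHDP()] on `table`.
#' @param seed integer seed for the synthetic draws.
#' @param threshold rejection threshold on the pseudo p.
#' @param refit_iters fixed-point iterations for the synthetic-matrix
#'   metacommunity refit.
#' @return A [NeutralityResult-class].
#' @export
neutralityTest <- function(table, variant = c("complete", "local"),
                           posterior, seed = 1, threshold = 0.001,
                           refit_iters = 25) {
    variant <- match.arg(variant)
    stopifnot(is(table, "CountTable"), is(posterior, "HDPPosterior"))
    X <- counts(table)
    X <- X[rowSums(X) > 0, , drop = FALSE]
    if (!identical(rownames(X), posterior@sampleIDs) ||
        !identical(colnames(X), posterior@taxonIDs))
        stop("posterior was not fitted on this table")
    storage.mode(X) <- "integer"
    set.seed(seed)
    r <- cpp_neutrality(X, posterior@beta, posterior@theta,
                        posterior@immigration,
                        complete = (variant == "complete"),
                        refit_iters = as.integer(refit_iters))
    nd <- length(r$loglik_obs)
    p <- sum(r$loglik_obs > r$loglik_syn) / nd
    new("NeutralityResult", variant = variant, pseudoP = p,
        nDraws = as.integer(nd), reject = p < threshold,
        threshold = threshold,
        logLikObs = as.numeric(r$loglik_obs),
        logLikSyn = as.numeric(r$loglik_syn))
}

#' Run the neutrality test battery over community classes
#'
#' Fits the HDP and runs the pseudo-p test, for both variants if asked,
#' on each class's sub-table (one class = one putative metacommunity).
#' Classes with fewer than 3 samples are skipped with a warning; an empty
#' input yields an empty report.
#'
#' @param tables named list of [CountTable-class] objects, one per
#'   community class (e.g. split by [assignClasses()] labels).
#' @param variants subset of `c("complete", "local")`.
#' @param sweeps,burn_in,thinning schedule passed to [fitHDP()].
#' @param seed integer seed (incremented per class).
#' @param threshold rejection threshold.
#' @return data.frame: class, variant, pseudo_p, n_draws, reject; a
#'   summary count of rejections in `attr(, "n_reject")`.
#' @export
runClassBattery <- function(tables, variants = c("complete", "local"),
                            sweeps = 50000, burn_in = 25000, thinning = 10,
                            seed = 1, threshold = 0.001) {
    variants <- match.arg(variants, several.ok = TRUE)
    rows <- list()
    for (ci in seq_along(tables)) {
        cls <- names(tables)[ci]
        if (is.null(cls) || !nzchar(cls)) cls <- paste0("class", ci)
        tab <- tables[[ci]]
        if (nSamples(tab) < 3) {
            warning("class ", cls, " has fewer than 3 samples; skipped")
            next
        }
        post <- fitHDP(tab, sweeps = sweeps, burn_in = burn_in,
                       thinning = thinning, seed = seed + ci)
        for (v in variants) {
            res <- neutralityTest(tab, v, post, seed = seed + ci,
                                  threshold = threshold)
            rows[[length(rows) + 1]] <- data.frame(
                class = cls, variant = v, pseudo_p = pseudoP(res),
                n_draws = res@nDraws, reject = res@reject)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(class = character(), variant = character(),
                   pseudo_p = numeric(), n_draws = integer(),
                   reject = logical())
    attr(out, "n_reject") <- sum(out$reject)
    out
}
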