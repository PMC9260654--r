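## Per-taxon zero-inflated negative binomial models of phase preference and
## life-strategy classification.

.PHASES <- c("attachment", "selection", "facilitation")

.zinb_design <- function(design, totals) {
    keep <- design$phase %in% .PHASES
    X <- cbind(intercept = 1,
               selection = as.numeric(design$phase[keep] == "selection"),
               facilitation = as.numeric(design$phase[keep] == "facilitation"))
    list(X = X, keep = keep, offset = log(rep_len(totals, nrow(design))[keep]))
}

## negative log-likelihood and analytic gradient of the ZINB model
## par = (beta[3], gamma[3], log size); gamma absent when zi = FALSE
.zinb_nll <- function(par, y, X, off, zi) {
    p <- ncol(X)
    beta <- par[1:p]
    mu <- exp(drop(X %*% beta) + off)
    a <- exp(par[length(par)])
    pi0 <- if (zi) stats::plogis(drop(X %*% par[(p + 1):(2 * p)])) else
        rep(0, length(y))
    f0 <- (a / (a + mu))^a
    z <- y == 0
    ll <- numeric(length(y))
    ll[z] <- log(pi0[z] + (1 - pi0[z]) * f0[z])
    ll[!z] <- log1p(-pi0[!z]) +
        dnbinom(y[!z], size = a, mu = mu[!z], log = TRUE)
    -sum(ll)
}

.zinb_grad <- function(par, y, X, off, zi) {
    p <- ncol(X)
    beta <- par[1:p]
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    a <- exp(par[length(par)])
    pi0 <- if (zi) stats::plogis(drop(X %*% par[(p + 1):(2 * p)])) else
        rep(0, length(y))
    f0 <- exp(a * (log(a) - log(a + mu)))
    z <- y == 0
    deta <- dzeta <- da <- numeric(length(y))
    # positive counts
    yp <- y[!z]; mup <- mu[!z]
    deta[!z] <- a * (yp - mup) / (a + mup)
    dzeta[!z] <- -pi0[!z]
    da[!z] <- digamma(yp + a) - digamma(a) + log(a / (a + mup)) + 1 -
        (yp + a) / (a + mup)
    # zeros
    s <- pi0[z] + (1 - pi0[z]) * f0[z]
    deta[z] <- -(1 - pi0[z]) * f0[z] * a * mu[z] / ((a + mu[z]) * s)
    dzeta[z] <- (1 - f0[z]) * pi0[z] * (1 - pi0[z]) / s
    da[z] <- (1 - pi0[z]) * f0[z] *
        (log(a / (a + mu[z])) + mu[z] / (a + mu[z])) / s
    g_beta <- drop(crossprod(X, deta))
    g_phi <- sum(da) * a
    if (zi) -c(g_beta, drop(crossprod(X, dzeta)), g_phi)
    else -c(g_beta, g_phi)
}

#' Fit a zero-inflated negative binomial phase model for one taxon
#'
#' Maximum likelihood fit of
#' `y ~ pi * delta_0 + (1 - pi) * NegBin(mu, size)` with
#' `log mu = phase effects + log(sample total)` (offset in the count part
#' only) and `logit pi` linear in the same phase design; the attachment
#' phase is the reference level. Standard errors come from the observed
#' information at the optimum. When the zero part is unidentifiable (no
#' excess zeros beyond the negative binomial, or a degenerate zero
#' pattern), the fit falls back to a plain negative binomial with a flag.
#' Samples outside the three phases (transition, unlabeled) are excluded.
#'
#' @param y per-sample counts for one taxon (same order as `design`).
#' @param design sample metadata (see [readSampleInfo()]); all three phases
#'   must be represented.
#' @param totals per-sample library totals for the offset (recycled).
#' @return A [ZINBFit-class].
#' @export
fitZINB <- function(y, design, totals = 1000) {
    if (length(y) != nrow(design))
        stop("y and design must align")
    d <- .zinb_design(design, totals)
    y <- y[d$keep]
    if (!all(.PHASES %in% design$phase[d$keep]))
        stop("all three phases must be represented in the design")
    if (all(y == 0)) stop("structural error: all-zero taxon cannot be fitted")
    X <- d$X; off <- d$offset
    p <- ncol(X)
    # plain NB fit first (also the fallback)
    beta0 <- c(log((mean(y) + 0.5) / mean(exp(off))), 0, 0)
    nb <- optim(c(beta0, 0), .zinb_nll, .zinb_grad, y = y, X = X, off = off,
                zi = FALSE, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-14))
    # ZINB start: NB count part, mild zero inflation
    start <- c(nb$par[1:p], -1, 0, 0, nb$par[p + 1])
    zb <- tryCatch(
        optim(start, .zinb_nll, .zinb_grad, y = y, X = X, off = off,
              zi = TRUE, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14)),
        error = function(e) NULL)
    separated <- !is.null(zb) && is.finite(zb$value) &&
        (zb$convergence != 0 || max(abs(zb$par[(p + 1):(2 * p)])) >= 8)
    use_zi <- !is.null(zb) && is.finite(zb$value) &&
        zb$value < nb$value - 1e-6 && !separated
    if (separated)
        warning("degenerate zero part (separation); falling back to ",
                "a plain negative binomial")
    fit <- if (use_zi) zb else nb
    zi <- use_zi
    npar <- length(fit$par)
    H <- optimHess(fit$par, .zinb_nll, .zinb_grad, y = y, X = X, off = off,
                   zi = zi)
    vc <- tryCatch(solve(H), error = function(e)
        matrix(NA_real_, npar, npar))
    se <- sqrt(pmax(diag(vc), 0))
    cf <- function(idx) {
        est <- fit$par[idx]; s <- se[idx]
        cbind(estimate = est, se = s, z = est / s,
              p = 2 * pnorm(-abs(est / s)))
    }
    count <- cf(1:p); rownames(count) <- colnames(X)
    zero <- if (zi) {
        zc <- cf((p + 1):(2 * p)); rownames(zc) <- colnames(X); zc
    } else matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("estimate", "se", "z", "p")))
    g <- .zinb_grad(fit$par, y, X, off, zi)
    new("ZINBFit", countCoefs = count, zeroCoefs = zero,
        dispersion = exp(fit$par[npar]), logLik = -fit$value, vcov = vc,
        converged = fit$convergence == 0 && all(is.finite(se)) &&
            max(abs(g)) < 1e-3,
        zeroInflated = zi)
}

.wald_greater <- function(fit, ph_a, ph_b, alpha) {
    # one-sided Wald test that count-part score of ph_a exceeds ph_b
    idx <- c(attachment = NA, selection = 2, facilitation = 3)
    est <- function(ph) if (ph == "attachment") 0 else
        fit@countCoefs[idx[ph], "estimate"]
    v <- fit@vcov
    var_of <- function(ph) if (ph == "attachment") 0 else v[idx[ph], idx[ph]]
    cov_ab <- if (ph_a == "attachment" || ph_b == "attachment") 0 else
        v[idx[ph_a], idx[ph_b]]
    d <- est(ph_a) - est(ph_b)
    s <- sqrt(var_of(ph_a) + var_of(ph_b) - 2 * cov_ab)
    if (!is.finite(s) || s == 0) return(FALSE)
    pnorm(d / s, lower.tail = FALSE) < alpha
}

#' Assign a life strategy from a fitted phase model
#'
#' Ranks the three phases by their count-part coefficient (attachment
#' fixed at 0) and finds the smallest top set whose members all
#' significantly exceed (one-sided Wald at level `alpha`) every phase
#' outside the set. A singleton gives that phase's strategy, a pair gives
#' "generalist" (elevated preference for at least two phases), and no
#' valid set gives "unassigned". The significance code records, for
#' selection and facilitation, the sign and significance of the contrast
#' against the attachment reference (`+`/`-` significant at `alpha`, `0`
#' otherwise).
#'
#' @param fit a [ZINBFit-class].
#' @param alpha per-contrast significance level (default 0.05).
#' @param taxon optional taxon identifier carried into the output.
#' @return one-row data.frame: `taxon`, `code`, `strategy`, `reason`.
#' @export
assignStrategy <- function(fit, alpha = 0.05, taxon = NA_character_) {
    stopifnot(is(fit, "ZINBFit"))
    code <- paste0(vapply(c("selection", "facilitation"), function(ph) {
        i <- c(selection = 2, facilitation = 3)[ph]
        est <- fit@countCoefs[i, "estimate"]
        p <- fit@countCoefs[i, "p"]
        if (is.finite(p) && p < alpha) if (est > 0) "+" else "-" else "0"
    }, character(1)), collapse = "")
    code <- paste0("s", substr(code, 1, 1), "f", substr(code, 2, 2))
    if (!fit@converged)
        return(data.frame(taxon = taxon, code = code,
                          strategy = "unassigned",
                          reason = "model did not converge"))
    score <- c(attachment = 0,
               selection = fit@countCoefs["selection", "estimate"],
               facilitation = fit@countCoefs["facilitation", "estimate"])
    ord <- names(sort(score, decreasing = TRUE))
    for (k in 1:2) {
        top <- ord[seq_len(k)]; rest <- ord[-seq_len(k)]
        ok <- all(vapply(top, function(a)
            all(vapply(rest, function(b)
                .wald_greater(fit, a, b, alpha), logical(1))), logical(1)))
        if (ok)
            return(data.frame(
                taxon = taxon, code = code,
                strategy = if (k == 1) top else "generalist",
                reason = if (k == 1) "single preferred phase" else
                    paste("preference for", paste(sort(top), collapse = "+"))))
    }
    data.frame(taxon = taxon, code = code, strategy = "unassigned",
               reason = "no significant phase contrast")
}

#' Fit phase models and strategies for every taxon in a table
#'
#' Convenience wrapper: fits [fitZINB()] per taxon (pooling samples across
#' substrates and replicates, as the response includes every sample in the
#' design) and classifies each with [assignStrategy()]. All-zero or
#' failing taxa are reported as unassigned with the error message.
#'
#' @param table a [CountTable-class] (samples aligned with `info`).
#' @param info sample metadata.
#' @param alpha per-contrast significance level.
#' @param totals per-sample totals for the offset; default the observed
#'   row sums.
#' @return data.frame with one row per taxon: `taxon`, `code`, `strategy`,
#'   `reason`.
#' @export
assignStrategies <- function(table, info, alpha = 0.05, totals = NULL) {
    stopifnot(is(table, "CountTable"))
    X <- counts(table)
    if (is.null(totals)) totals <- rowSums(X)
    out <- lapply(colnames(X), function(tx) {
        res <- tryCatch({
            fit <- fitZINB(X[, tx], info, totals = totals)
            assignStrategy(fit, alpha = alpha, taxon = tx)
        }, error = function(e)
            data.frame(taxon = tx, code = "s0f0", strategy = "unassigned",
                       reason = conditionMessage(e)))
        res
    })
    do.call(rbind, out)
}

#' Propagate ESV strategies to matched isolates
#'
#' Each isolate inherits the strategy of its 100%-matched ESV(s); isolates
#' without a match are excluded with a reason, and isolates matching
#' several ESVs with conflicting strategies are flagged unresolved.
#'
#' @param assignments data.frame from [assignStrategies()] (or
#'   [assignStrategy()] rows).
#' @param isolate_map named list from [matchIsolates()].
#' @return data.frame: `isolate`, `esvs`, `strategy`, `note`.
#' @export
classifyIsolates <- function(assignments, isolate_map) {
    rows <- lapply(names(isolate_map), function(iso) {
        esvs <- isolate_map[[iso]]
        if (!length(esvs))
            return(data.frame(isolate = iso, esvs = "",
                              strategy = "excluded",
                              note = "no 100% ESV match; discarded"))
        st <- unique(assignments$strategy[assignments$taxon %in% esvs])
        if (length(st) == 1)
            data.frame(isolate = iso, esvs = paste(esvs, collapse = ";"),
                       strategy = st, note = "")
        else
            data.frame(isolate = iso, esvs = paste(esvs, collapse = ";"),
                       strategy = "unresolved",
                       note = paste("conflicting strategies:",
                                    paste(st, collapse = ", ")))
    })
    do.call(rbind, rows)
}
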