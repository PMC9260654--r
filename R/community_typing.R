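## Dirichlet-multinomial mixture (DMM) community typing.
##
## Each sample's composition is modelled as drawn from one of K Dirichlet
## "metacommunities"; the number of classes is selected at the minimum of
## the Laplace-approximated negative log model evidence.

.ldm <- function(x, alpha) {
    # log Dirichlet-multinomial mass incl. the multinomial coefficient
    A <- sum(alpha); n <- sum(x)
    lgamma(n + 1) - sum(lgamma(x + 1)) + lgamma(A) - lgamma(A + n) +
        sum(lgamma(alpha + x) - lgamma(alpha))
}

## per-component log DM for all samples: X (M x S), alpha vector -> M vector
.ldm_rows <- function(X, alpha, lmc) {
    A <- sum(alpha)
    n <- rowSums(X)
    lmc + lgamma(A) - lgamma(A + n) +
        rowSums(lgamma(sweep(X, 2, alpha, "+"))) - sum(lgamma(alpha))
}

.ALPHA_FLOOR <- 1e-6
.DMM_PRIOR_SD <- 3   # log-normal prior SD on each alpha (log scale)

.dmm_loglik_parts <- function(X, alpha, w, lmc) {
    L <- vapply(seq_len(nrow(alpha)),
                function(k) .ldm_rows(X, alpha[k, ], lmc), numeric(nrow(X)))
    L <- matrix(L, nrow(X), nrow(alpha))
    Lw <- sweep(L, 2, log(w), "+")
    m <- apply(Lw, 1, max)
    ll_i <- m + log(rowSums(exp(Lw - m)))
    r <- exp(Lw - ll_i)
    list(loglik = sum(ll_i), resp = r, comp = L)
}

#' Fit a Dirichlet-multinomial mixture to a count table
#'
#' EM over component memberships with digamma fixed-point updates of each
#' component's Dirichlet parameters; the observed-data log-likelihood is
#' non-decreasing across iterations. The negative log model evidence is a
#' Laplace approximation around the posterior mode in an unconstrained
#' reparameterization (log alpha; multinomial-logit weights), under weak
#' log-normal priors on alpha and a flat Dirichlet prior on the weights.
#'
#' @param table a [CountTable-class].
#' @param K number of mixture components (`1 <= K <=` number of samples).
#' @param seed integer seed for the responsibility initialization.
#' @param max_iter,tol EM stopping rule: relative objective change `< tol`
#'   or `max_iter` reached (status in the `converged` slot).
#' @return A [DMMFit-class]; the EM objective trace is in
#'   `attr(, "trace")`.
#' @seealso [selectK()], [assignClasses()]
#' @export
fitDMM <- function(table, K, seed = 1, max_iter = 250, tol = 1e-8) {
    stopifnot(is(table, "CountTable"))
    X <- counts(table)
    M <- nrow(X); S <- ncol(X)
    K <- as.integer(K)
    if (K < 1) stop("K must be >= 1")
    if (K > M) stop("K must not exceed the number of samples")
    lmc <- lgamma(rowSums(X) + 1) - rowSums(lgamma(X + 1))
    set.seed(seed)
    props <- sweep(X + 0.5, 1, rowSums(X + 0.5), "/")
    centers <- sample(M, K)
    alpha <- props[centers, , drop = FALSE] * 20 + 0.1
    w <- rep(1 / K, K)
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    it <- 0L
    r <- matrix(1, M, K)
    while (it < max_iter) {
        it <- it + 1L
        parts <- .dmm_loglik_parts(X, alpha, w, lmc)
        r <- parts$resp
        trace <- c(trace, parts$loglik)
        if (is.finite(prev) &&
            abs(parts$loglik - prev) < tol * (abs(prev) + 1)) {
            converged <- TRUE
            break
        }
        prev <- parts$loglik
        w <- pmax(colMeans(r), 1e-12); w <- w / sum(w)
        # Minka fixed-point update per component (monotone lower bound)
        n <- rowSums(X)
        for (k in seq_len(K)) {
            a <- alpha[k, ]; A <- sum(a)
            num <- colSums(r[, k] * (digamma(sweep(X, 2, a, "+")) -
                                     rep(digamma(a), each = M)))
            den <- sum(r[, k] * (digamma(A + n) - digamma(A)))
            if (den > 0) a <- a * num / den
            alpha[k, ] <- pmax(a, .ALPHA_FLOOR)
        }
    }
    small <- w < 1 / M^2
    if (any(small))
        warning(sum(small), " degenerate component(s) with weight < 1/M^2")
    rownames(r) <- rownames(X)
    colnames(alpha) <- colnames(X)
    nle <- .dmm_neg_log_evidence(X, alpha, w, lmc)
    fit <- new("DMMFit", K = K, alpha = alpha, weights = w,
               responsibilities = r, negLogEvidence = nle,
               logLik = trace[length(trace)], converged = converged,
               iterations = it)
    attr(fit, "trace") <- trace
    fit
}

## gradient of the log posterior h(theta) in the unconstrained
## parameterization theta = (log alpha_11.., u_1..u_{K-1})
.dmm_pack <- function(alpha, w) {
    K <- nrow(alpha)
    u <- if (K > 1) log(w[-K] / w[K]) else numeric(0)
    c(log(t(alpha)), u)
}

.dmm_unpack <- function(theta, K, S) {
    alpha <- t(matrix(exp(theta[seq_len(K * S)]), S, K))
    if (K > 1) {
        u <- c(theta[(K * S + 1):(K * S + K - 1)], 0)
        w <- exp(u - max(u)); w <- w / sum(w)
    } else w <- 1
    list(alpha = alpha, w = w)
}

.dmm_logpost <- function(theta, X, K, S, lmc) {
    p <- .dmm_unpack(theta, K, S)
    ll <- .dmm_loglik_parts(X, p$alpha, p$w, lmc)$loglik
    lam <- theta[seq_len(K * S)]
    lp <- sum(stats::dnorm(lam, 0, .DMM_PRIOR_SD, log = TRUE))
    if (K > 1) lp <- lp + lgamma(K) + sum(log(p$w))
    ll + lp
}

.dmm_grad <- function(theta, X, K, S, lmc) {
    p <- .dmm_unpack(theta, K, S)
    parts <- .dmm_loglik_parts(X, p$alpha, p$w, lmc)
    r <- parts$resp
    M <- nrow(X); n <- rowSums(X)
    g_lam <- matrix(0, K, S)
    for (k in seq_len(K)) {
        a <- p$alpha[k, ]; A <- sum(a)
        dA <- digamma(A) - digamma(A + n)                     # per sample
        dmat <- digamma(sweep(X, 2, a, "+")) - rep(digamma(a), each = M)
        g_a <- colSums(r[, k] * (dmat + dA))
        g_lam[k, ] <- g_a * a
    }
    lam <- theta[seq_len(K * S)]
    g_lam <- as.numeric(t(g_lam)) - lam / .DMM_PRIOR_SD^2
    if (K > 1) {
        g_u <- colSums(r) - M * p$w + (1 - K * p$w)           # lik + prior
        c(g_lam, g_u[-K])
    } else g_lam
}

## Laplace approximation of the log evidence at the EM solution, with a
## block-diagonal Hessian (per-component curvature at fixed
## responsibilities, plus a mixing-weight block); exact at K = 1.
.dmm_neg_log_evidence <- function(X, alpha, w, lmc, resp = NULL) {
    K <- nrow(alpha); S <- ncol(alpha); M <- nrow(X)
    theta <- .dmm_pack(alpha, w)
    h <- .dmm_logpost(theta, X, K, S, lmc)
    # refine the EM solution toward the posterior mode; keep only a
    # well-behaved improvement (BFGS can stall on saddle ridges at K > 2)
    opt <- tryCatch(
        optim(theta, .dmm_logpost, .dmm_grad, X = X, K = K, S = S,
              lmc = lmc, method = "BFGS",
              control = list(fnscale = -1, maxit = 500, reltol = 1e-12)),
        error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value > h &&
        max(abs(.dmm_grad(opt$par, X, K, S, lmc))) < 1e-2) {
        p <- .dmm_unpack(opt$par, K, S)
        alpha <- p$alpha; w <- p$w
        theta <- opt$par
        h <- opt$value
        resp <- NULL
    }
    if (is.null(resp))
        resp <- .dmm_loglik_parts(X, alpha, w, lmc)$resp
    n <- rowSums(X)
    logdet <- 0
    for (k in seq_len(K)) {
        a <- alpha[k, ]; A <- sum(a); r <- resp[, k]
        cfac <- sum(r * (trigamma(A) - trigamma(A + n)))
        dj <- colSums(r * (trigamma(sweep(X, 2, a, "+")) -
                           rep(trigamma(a), each = M)))
        gj <- colSums(r * (digamma(sweep(X, 2, a, "+")) -
                           rep(digamma(a), each = M))) +
            sum(r * (digamma(A) - digamma(A + n)))
        # Hessian of the weighted log-lik + prior in lambda = log alpha
        Hk <- -(outer(a, a) * cfac)
        diag(Hk) <- diag(Hk) - a^2 * dj - a * gj + 1 / .DMM_PRIOR_SD^2
        ev <- eigen(Hk, symmetric = TRUE, only.values = TRUE)$values
        logdet <- logdet + sum(log(pmax(ev, 1e-6)))
    }
    if (K > 1) {
        # observed information of the mixing weights in multinomial-logit
        # coordinates (flat Dirichlet prior adds no curvature at the mode)
        Hu <- M * (diag(w[-K], K - 1) - outer(w[-K], w[-K]))
        ev <- eigen(Hu, symmetric = TRUE, only.values = TRUE)$values
        logdet <- logdet + sum(log(pmax(ev, 1e-6)))
    }
    d <- K * S + (K - 1)
    -(h + 0.5 * d * log(2 * pi) - 0.5 * logdet + lgamma(K + 1))
}

#' Select the number of community classes by minimum negative log evidence
#'
#' Fits the mixture for each K on a grid with several seeded restarts,
#' keeps each K's best fit, and returns the K minimizing the
#' Laplace-approximated negative log evidence, together with the full
#' evidence curve.
#'
#' @param table a [CountTable-class].
#' @param k_grid sorted integer grid of candidate K.
#' @param seeds number of EM restarts per K.
#' @param ... passed to [fitDMM()].
#' @return list with `best_k`, `curve` (data.frame K / neg_log_evidence /
#'   converged), and `fits` (best [DMMFit-class] per K). A message flags a
#'   minimum on the grid boundary.
#' @export
selectK <- function(table, k_grid = 1:5, seeds = 5, ...) {
    if (!length(k_grid)) stop("k_grid must be non-empty")
    k_grid <- sort(unique(as.integer(k_grid)))
    fits <- vector("list", length(k_grid))
    nle <- rep(NA_real_, length(k_grid))
    for (i in seq_along(k_grid)) {
        best <- NULL
        for (s in seq_len(seeds)) {
            f <- tryCatch(
                suppressWarnings(fitDMM(table, k_grid[i], seed = s, ...)),
                error = function(e) NULL)
            if (!is.null(f) &&
                (is.null(best) || f@negLogEvidence < best@negLogEvidence))
                best <- f
        }
        if (is.null(best)) {
            warning("all fits failed at K = ", k_grid[i])
        } else {
            fits[[i]] <- best
            nle[i] <- best@negLogEvidence
        }
    }
    if (all(is.na(nle))) stop("no K could be fitted")
    best_i <- which.min(nle)
    if (best_i %in% c(1L, length(k_grid)) && length(k_grid) > 1)
        message("evidence minimum lies on the K-grid boundary (K = ",
                k_grid[best_i], ")")
    list(best_k = k_grid[best_i],
         curve = data.frame(K = k_grid, neg_log_evidence = nle,
                            converged = vapply(fits, function(f)
                                if (is.null(f)) NA else f@converged, NA)),
         fits = setNames(fits, paste0("K", k_grid)))
}

#' Assign each sample to its community class
#'
#' Labels each sample with the argmax-responsibility component; exact ties
#' break toward the lower component index. The maximum responsibility is
#' reported so ambiguous samples stay visible.
#'
#' @param fit a [DMMFit-class].
#' @return data.frame with columns `sample_id`, `class`, `confidence`.
#' @export
assignClasses <- function(fit) {
    stopifnot(is(fit, "DMMFit"))
    r <- fit@responsibilities
    cls <- max.col(r, ties.method = "first")
    data.frame(sample_id = rownames(r), class = cls,
               confidence = r[cbind(seq_len(nrow(r)), cls)],
               row.names = NULL)
}
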