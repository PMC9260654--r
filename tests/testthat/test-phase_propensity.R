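test_that("pure negative binomial data fall back to the plain NB fit and
           match the independent oracle", {
    skip_if_not_installed("glmmTMB")
    des <- full_design()
    des <- des[des$phase %in% c("attachment", "selection", "facilitation"), ]
    par <- zinbParams(intercept = -5, selection = 0.7, facilitation = 1.1,
                      zero_intercept = -Inf, dispersion = 1.5)
    y <- simulateZINBCounts(par, des, totals = 1000, seed = 1)
    fit <- suppressWarnings(fitZINB(y, des, totals = 1000))
    expect_false(fit@zeroInflated)
    dat <- cbind(des, y = y)
    dat$phase_f <- factor(dat$phase, levels = c("attachment", "selection",
                                                "facilitation"))
    ref <- glmmTMB::glmmTMB(y ~ phase_f,
        offset = rep(log(1000), nrow(des)),
        family = glmmTMB::nbinom2, data = dat)
    expect_equal(unname(fit@countCoefs[, "estimate"]),
                 unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
    expect_equal(fit@dispersion, glmmTMB::sigma(ref), tolerance = 1e-2)
})

test_that("zero-inflated fits agree with glmmTMB and beat the nested NB", {
    skip_if_not_installed("glmmTMB")
    des <- full_design()
    des <- des[des$phase %in% c("attachment", "selection", "facilitation"), ]
    par <- zinbParams(intercept = -5, facilitation = log(3),
                      zero_intercept = -0.5, zero_facilitation = 1,
                      dispersion = 2)
    y <- simulateZINBCounts(par, des, totals = 1000, seed = 2)
    fit <- fitZINB(y, des, totals = 1000)
    expect_true(fit@zeroInflated)
    expect_true(fit@converged)
    dat <- cbind(des, y = y)
    dat$phase_f <- factor(dat$phase, levels = c("attachment", "selection",
                                                "facilitation"))
    ref <- glmmTMB::glmmTMB(y ~ phase_f, ziformula = ~ phase_f,
        offset = rep(log(1000), nrow(des)),
        family = glmmTMB::nbinom2, data = dat)
    expect_equal(unname(fit@countCoefs[, "estimate"]),
                 unname(glmmTMB::fixef(ref)$cond), tolerance = 5e-3)
    expect_equal(unname(fit@zeroCoefs[, "estimate"]),
                 unname(glmmTMB::fixef(ref)$zi), tolerance = 0.05)
    expect_equal(fit@logLik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-5)
    # nesting: ZINB optimum at least as good as the plain NB optimum
    nll_nb <- particleSuccession:::.zinb_nll
    d <- particleSuccession:::.zinb_design(des, 1000)
    nb <- optim(c(fit@countCoefs[, "estimate"], log(fit@dispersion)),
                nll_nb, particleSuccession:::.zinb_grad,
                y = y[d$keep], X = d$X, off = d$offset, zi = FALSE,
                method = "BFGS")
    expect_gte(fit@logLik, -nb$value - 1e-6)
})

test_that("the reported optimum is a stationary point of the ZINB
           likelihood", {
    des <- full_design(n_substrates = 4)
    des <- des[des$phase %in% c("attachment", "selection", "facilitation"), ]
    par <- zinbParams(intercept = -5, selection = 0.5,
                      zero_intercept = -1, dispersion = 1)
    y <- simulateZINBCounts(par, des, totals = 800, seed = 3)
    fit <- fitZINB(y, des, totals = 800)
    pars <- c(fit@countCoefs[, "estimate"],
              if (fit@zeroInflated) fit@zeroCoefs[, "estimate"],
              log(fit@dispersion))
    d <- particleSuccession:::.zinb_design(des, 800)
    g <- particleSuccession:::.zinb_grad(pars, y[d$keep], d$X, d$offset,
                                         fit@zeroInflated)
    expect_lt(max(abs(g)), 1e-5 * (abs(fit@logLik) + 1))
})

test_that("fit contracts: all-zero taxa, missing phases, sample order", {
    des <- full_design(n_substrates = 2)
    des3 <- des[des$phase %in% c("attachment", "selection", "facilitation"), ]
    expect_error(fitZINB(rep(0, nrow(des3)), des3), "all-zero")
    only2 <- des3[des3$phase != "selection", ]
    expect_error(fitZINB(rpois(nrow(only2), 3), only2),
                 "all three phases")
    par <- zinbParams(intercept = -5, facilitation = 0.8,
                      zero_intercept = -1, dispersion = 1)
    y <- simulateZINBCounts(par, des3, totals = 600, seed = 4)
    f1 <- fitZINB(y, des3, totals = 600)
    set.seed(5); perm <- sample(nrow(des3))
    f2 <- fitZINB(y[perm], des3[perm, ], totals = 600)
    expect_equal(f1@countCoefs[, "estimate"], f2@countCoefs[, "estimate"],
                 tolerance = 1e-6)
})

test_that("strategy rules follow the significantly-maximal-phase
           definition", {
    mk_fit <- function(sel, fac, se = 0.1) {
        cc <- cbind(estimate = c(0, sel, fac), se = se,
                    z = c(0, sel, fac) / se,
                    p = 2 * pnorm(-abs(c(0, sel, fac) / se)))
        rownames(cc) <- c("intercept", "selection", "facilitation")
        v <- diag(se^2, 7); v[2, 3] <- v[3, 2] <- 0
        new("ZINBFit", countCoefs = cc,
            zeroCoefs = cc, dispersion = 1, logLik = 0, vcov = v,
            converged = TRUE, zeroInflated = TRUE)
    }
    # both later phases significantly depleted -> attachment specialist
    a <- assignStrategy(mk_fit(-2, -2))
    expect_equal(a$strategy, "attachment")
    expect_equal(a$code, "s-f-")
    # facilitation clearly elevated, selection close behind and both above
    # the reference -> generalist over selection + facilitation
    g <- assignStrategy(mk_fit(1.9, 2))
    expect_equal(g$strategy, "generalist")
    # nothing significant -> unassigned
    u <- assignStrategy(mk_fit(0.05, -0.05))
    expect_equal(u$strategy, "unassigned")
    expect_equal(u$code, "s0f0")
    # single elevated phase -> that phase
    s <- assignStrategy(mk_fit(2, 0.1))
    expect_equal(s$strategy, "selection")
    # non-converged fits are never assigned
    nc <- mk_fit(2, 0.1); nc@converged <- FALSE
    expect_equal(assignStrategy(nc)$strategy, "unassigned")
})

test_that("known phase effects are recovered within Wald CIs", {
    des <- full_design()    # 8 substrates x 11 times x 3 replicates = 264
    expect_equal(nrow(des), 264)
    des3 <- des[des$phase %in% c("attachment", "selection", "facilitation"), ]
    par <- zinbParams(intercept = -6, facilitation = log(3),
                      zero_intercept = -1, dispersion = 1.5)
    cover <- vapply(1:15, function(s) {
        y <- simulateZINBCounts(par, des3, totals = 1000, seed = s)
        fit <- tryCatch(fitZINB(y, des3, totals = 1000),
                        error = function(e) NULL)
        if (is.null(fit)) return(NA)
        est <- fit@countCoefs["facilitation", "estimate"]
        se <- fit@countCoefs["facilitation", "se"]
        abs(est - log(3)) <= qnorm(0.975) * se
    }, logical(1))
    expect_gte(mean(cover, na.rm = TRUE), 0.8)
})

test_that("isolate classification propagates, flags conflicts, and
           excludes unmatched isolates", {
    asg <- data.frame(taxon = c("e1", "e2", "e3"),
                      code = c("s+f0", "s0f+", "s0f+"),
                      strategy = c("selection", "facilitation",
                                   "facilitation"))
    map <- list(isoA = "e1", isoB = c("e2", "e3"), isoC = character(0),
                isoD = c("e1", "e2"))
    out <- classifyIsolates(asg, map)
    expect_equal(out$strategy[out$isolate == "isoA"], "selection")
    expect_equal(out$strategy[out$isolate == "isoB"], "facilitation")
    expect_equal(out$strategy[out$isolate == "isoC"], "excluded")
    expect_equal(out$strategy[out$isolate == "isoD"], "unresolved")
    expect_match(out$note[out$isolate == "isoD"], "conflicting")
})
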