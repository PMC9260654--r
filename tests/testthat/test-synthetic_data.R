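test_that("stick-breaking metacommunities are simplexes with theta-driven
           evenness and richness", {
    b <- sampleMetacommunity(20, 50, seed = 1)
    expect_equal(sum(b), 1, tolerance = 1e-12)
    expect_true(all(b >= 0))
    expect_error(sampleMetacommunity(-1, 10), "positive")

    shannon_even <- function(w) {
        w <- w[w > 0]
        -sum(w * log(w)) / log(length(w))
    }
    stats <- vapply(1:200, function(s) {
        c(ev_lo = shannon_even(sampleMetacommunity(0.5, 50, seed = s)),
          ev_hi = shannon_even(sampleMetacommunity(50, 50, seed = s)),
          r1 = sum(sampleMetacommunity(0.5, 50, seed = s) > 1e-3),
          r2 = sum(sampleMetacommunity(5, 50, seed = s) > 1e-3),
          r3 = sum(sampleMetacommunity(50, 50, seed = s) > 1e-3))
    }, numeric(5))
    expect_gt(mean(stats["ev_hi", ]), mean(stats["ev_lo", ]))
    # expected richness grows monotonically with theta
    expect_lt(mean(stats["r1", ]), mean(stats["r2", ]))
    expect_lt(mean(stats["r2", ]), mean(stats["r3", ]))
})

test_that("local communities have fixed depth and mean beta", {
    beta <- sampleMetacommunity(20, 30, seed = 3)
    p <- neutralParams(theta = 20, immigration = 10, depth = 500,
                       n_taxa_cap = 30)
    ct <- sampleLocalCommunities(beta, p, 500, seed = 4)
    expect_equal(unname(rowSums(counts(ct))), rep(500, 500))
    rel <- sweep(counts(ct), 1, 500, "/")
    # per-taxon SE of the mean under the Dirichlet-multinomial
    vif <- (10 + 500) / (10 + 1)
    se <- sqrt(beta * (1 - beta) / 500 * vif / 500)
    expect_true(all(abs(colMeans(rel) - beta) <= 3 * se + 1e-12))
    expect_error(sampleLocalCommunities(beta, neutralParams(n_taxa_cap = 10),
                                        5), "dimension mismatch")
})

test_that("huge immigration makes local communities track the
           metacommunity", {
    beta <- sampleMetacommunity(10, 20, seed = 5)
    p <- neutralParams(theta = 10, immigration = 1e9, depth = 2000,
                       n_taxa_cap = 20)
    ct <- sampleLocalCommunities(beta, p, 20, seed = 6)
    rel <- sweep(counts(ct), 1, rowSums(counts(ct)), "/")
    mad <- mean(abs(t(rel) - beta))
    # multinomial-only sampling error scale
    expect_lt(mad, 2 * mean(sqrt(beta * (1 - beta) / 2000)))
})

test_that("Dirichlet-multinomial variance inflation matches (I+n)/(I+1)", {
    beta <- c(0.5, 0.3, 0.2)
    p <- neutralParams(theta = 1, immigration = 5, depth = 50, n_taxa_cap = 3)
    ct <- sampleLocalCommunities(beta, p, 4000, seed = 7)
    vif <- (5 + 50) / (5 + 1)
    v_exp <- 50 * beta * (1 - beta) * vif
    v_obs <- apply(counts(ct), 2, var)
    expect_equal(unname(v_obs), unname(v_exp), tolerance = 0.12)
})

test_that("generators are seed-reproducible", {
    expect_identical(sampleMetacommunity(5, 20, seed = 9),
                     sampleMetacommunity(5, 20, seed = 9))
    b <- sampleMetacommunity(5, 20, seed = 9)
    p <- neutralParams(n_taxa_cap = 20)
    expect_identical(counts(sampleLocalCommunities(b, p, 5, seed = 2)),
                     counts(sampleLocalCommunities(b, p, 5, seed = 2)))
    s1 <- simulateSuccession(seed = 11)
    s2 <- simulateSuccession(seed = 11)
    expect_identical(counts(s1$table), counts(s2$table))
    expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("succession simulator reproduces the design grid, phase map and
           tree structure", {
    p <- successionParams(replicates = 3)
    sim <- simulateSuccession(p, seed = 1)
    expect_setequal(unique(sim$info$time_h), samplingGrid())
    expect_equal(nrow(sim$info), 33)
    expect_identical(sim$info$phase, phaseForTime(sim$info$time_h))
    expect_s3_class(sim$tree, "phylo")
    expect_setequal(sim$tree$tip.label, taxonIDs(sim$table))
    # phase blocks are clades: within-block cophenetic distances smaller
    D <- ape::cophenetic.phylo(sim$tree)
    npp <- p$n_taxa_per_phase
    blk <- rep(1:3, each = npp)
    names(blk) <- paste0("taxon", seq_len(3 * npp))
    within <- D[outer(blk[rownames(D)], blk[colnames(D)], "==") &
                upper.tri(D)]
    between <- D[outer(blk[rownames(D)], blk[colnames(D)], "!=") &
                 upper.tri(D)]
    expect_lt(max(within), min(between))
    expect_error(simulateSuccession(successionParams(n_taxa_per_phase = 1)),
                 "at least 2")
})

test_that("zero-inflation degenerate cases reduce to the negative
           binomial and the offset is a pure log-link offset", {
    des <- full_design(n_substrates = 8)
    des <- des[des$phase %in% c("attachment", "selection", "facilitation"), ]
    par <- zinbParams(intercept = -5, facilitation = log(3),
                      zero_intercept = -Inf, dispersion = 2)
    y <- simulateZINBCounts(par, des, totals = 1000, seed = 1)
    # pi = 0: observed zero fraction matches the NB prediction
    mu <- exp(-5 + log(3) * (des$phase == "facilitation") + log(1000))
    p0 <- mean(dnbinom(0, size = 2, mu = mu))
    many <- unlist(lapply(1:40, function(s)
        simulateZINBCounts(par, des, totals = 1000, seed = s) == 0))
    se <- sqrt(p0 * (1 - p0) / length(many))
    expect_lt(abs(mean(many) - p0), 3 * se)
    # doubling the totals doubles expected counts
    y2 <- vapply(1:300, function(s)
        mean(simulateZINBCounts(par, des, totals = 2000, seed = 1000 + s)),
        numeric(1))
    y1 <- vapply(1:300, function(s)
        mean(simulateZINBCounts(par, des, totals = 1000, seed = 4000 + s)),
        numeric(1))
    expect_equal(mean(y2) / mean(y1), 2, tolerance = 0.1)
    expect_error(simulateZINBCounts(par, des[0, ]), "non-empty")
})
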