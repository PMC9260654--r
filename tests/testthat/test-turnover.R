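test_that("phylogenetic balances match the hand example and the ILR
           contract", {
    tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
    ct <- CountTable(matrix(c(25, 25, 50), 1, 3,
                            dimnames = list("s1", c("A", "B", "C"))))
    b <- philrTransform(ct, tree, pseudocount = 0)
    # root balance sqrt(2*1/3)*ln(gm(A,B)/gm(C)); (A|B) balance 0
    expect_equal(sort(unname(b[1, ])), sort(c(0, sqrt(2 / 3) * log(0.5))),
                 tolerance = 1e-9)
    expect_equal(round(min(b), 3), -0.566)
    # all-equal composition -> all balances zero
    cte <- CountTable(matrix(c(10, 10, 10), 1, 3,
                             dimnames = list("s1", c("A", "B", "C"))))
    expect_equal(unname(philrTransform(cte, tree, pseudocount = 0)[1, ]),
                 c(0, 0), tolerance = 1e-12)
    # scale invariance after closure
    ct10 <- CountTable(10 * counts(ct))
    expect_equal(philrTransform(ct10, tree, pseudocount = 0), b,
                 tolerance = 1e-10)
    # errors: zeros without pseudocount; tip mismatch
    ctz <- CountTable(matrix(c(0, 2, 3), 1, 3,
                             dimnames = list("s1", c("A", "B", "C"))))
    expect_error(philrTransform(ctz, tree, pseudocount = 0), "pseudocount")
    bad <- CountTable(matrix(1, 1, 2, dimnames = list("s1", c("A", "Z"))))
    expect_error(philrTransform(bad, tree), "absent from the tree")
})

test_that("balance dimensionality equals the internal node count and
           multichotomies resolve deterministically", {
    set.seed(2)
    tr <- ape::rtree(12)
    ct <- dm_table(rep(1, 12), 6, depth = 400, seed = 3)
    ct <- CountTable(counts(ct), taxon_ids = tr$tip.label)
    b <- philrTransform(ct, tr)
    expect_equal(ncol(b), 11)           # binary: S - 1 internal nodes
    star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
    ct4 <- CountTable(matrix(c(1, 2, 3, 4), 1, 4,
                             dimnames = list("s", c("A", "B", "C", "D"))))
    b1 <- philrTransform(ct4, star)
    expect_equal(ncol(b1), 3)
    expect_identical(b1, philrTransform(ct4, star))
    # abundance weighting changes values but not dimensionality
    ba <- philrTransform(ct, tr, weighting = "abundance")
    expect_equal(dim(ba), dim(b))
})

test_that("Mantel r and p follow the permutation-test conventions", {
    set.seed(4)
    m <- matrix(runif(36), 6, 6); m <- m + t(m); diag(m) <- 0
    res <- mantelTest(m, 2 * m, permutations = 99, seed = 1)
    expect_equal(res$r, 1)
    expect_gte(res$p, 1 / 100)
    expect_error(mantelTest(m, matrix(1, 6, 6) - diag(6) * 0), "constant")
})

test_that("4-sample Mantel p equals the exhaustive enumeration oracle", {
    set.seed(5)
    d1 <- matrix(runif(16), 4, 4); d1 <- d1 + t(d1); diag(d1) <- 0
    d2 <- matrix(runif(16), 4, 4); d2 <- d2 + t(d2); diag(d2) <- 0
    res <- mantelTest(d1, d2, permutations = 999, seed = 1)
    expect_true(res$exact)
    # independent brute force over all 4! relabelings
    lt <- lower.tri(d1)
    r_obs <- cor(d1[lt], d2[lt])
    perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
    rs <- apply(perms, 1, function(p) {
        pm <- d2[unlist(p), unlist(p)]
        cor(d1[lt], pm[lt])
    })
    expect_equal(res$p, mean(rs >= r_obs - 1e-12))
})

test_that("betaMNTD matches the hand example and a double-loop oracle", {
    D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    expect_identical(betaMNTD(c(A = 1), c(B = 0.5, C = 0.5), D), 2.5)
    expect_equal(betaMNTD(c(A = .3, B = .7), c(A = .3, B = .7), D), 0)
    expect_equal(betaMNTD(c(A = 1), c(B = .5, C = .5), D),
                 betaMNTD(c(B = .5, C = .5), c(A = 1), D))
    expect_error(betaMNTD(c(A = 0), c(B = 1), D), "empty community")

    # random 10-taxon instances against a naive O(S^2) oracle
    naive <- function(fk, fl, D) {
        ik <- which(fk > 0); il <- which(fl > 0)
        fk <- fk / sum(fk); fl <- fl / sum(fl)
        s1 <- 0; s2 <- 0
        for (i in ik) s1 <- s1 + fk[i] * min(D[i, il])
        for (j in il) s2 <- s2 + fl[j] * min(D[j, ik])
        unname(0.5 * (s1 + s2))
    }
    set.seed(6)
    tr <- ape::rtree(10)
    D10 <- ape::cophenetic.phylo(tr)
    for (rep in 1:20) {
        fk <- rbinom(10, 1, 0.6) * runif(10); fl <- rbinom(10, 1, 0.6) * runif(10)
        if (sum(fk) == 0 || sum(fl) == 0) next
        names(fk) <- names(fl) <- rownames(D10)
        expect_equal(betaMNTD(fk, fl, D10), naive(fk, fl, D10),
                     tolerance = 1e-12)
    }
})

test_that("betaMNTD agrees with the picante oracle on community matrices", {
    skip_if_not_installed("picante")
    set.seed(7)
    tr <- ape::rtree(15)
    X <- matrix(rpois(5 * 15, 2), 5, 15,
                dimnames = list(paste0("s", 1:5), tr$tip.label))
    X[X < 1] <- 0
    keep <- rowSums(X) > 0
    X <- X[keep, , drop = FALSE]
    ref <- as.matrix(picante::comdistnt(X, ape::cophenetic.phylo(tr),
                                        abundance.weighted = TRUE))
    for (i in 1:(nrow(X) - 1)) for (j in (i + 1):nrow(X)) {
        expect_equal(betaMNTD(X[i, ], X[j, ], ape::cophenetic.phylo(tr)),
                     ref[i, j], tolerance = 1e-10)
    }
})

test_that("betaNTI flags degenerate pairs, defaults to 999 nulls, and is
           invariant to re-rooting", {
    expect_equal(formals(betaNTI)$n_null, 999)
    set.seed(8)
    tr <- ape::rtree(12)
    X <- matrix(rpois(4 * 12, 3), 4, 12,
                dimnames = list(paste0("s", 1:4), tr$tip.label))
    X[1, ] <- X[2, ]          # identical communities -> undefined pair
    ct <- CountTable(X)
    bn <- betaNTI(ct, tr, n_null = 99, seed = 1)
    expect_true(is.na(bnti(bn)["s1", "s2"]))
    expect_identical(bn@classification["s1", "s2"], "undefined")
    expect_true(all(abs(bn@bnti - t(bn@bnti)) < 1e-12, na.rm = TRUE))
    # patristic distances are root-free, so re-rooting changes nothing
    tr2 <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[5],
                     resolve.root = TRUE)
    bn2 <- betaNTI(ct, tr2, n_null = 99, seed = 1)
    expect_equal(bnti(bn), bnti(bn2), tolerance = 1e-9)
    expect_error(betaNTI(ct, tr, n_null = 9), ">= 99")
})

test_that("phase-structured succession shows homogeneous selection within
           phases and a decaying correlogram", {
    sim <- simulateSuccession(seed = 33)
    keep <- sim$info$phase %in% c("selection", "facilitation")
    ct <- CountTable(counts(sim$table)[keep, ])
    bn <- betaNTI(ct, sim$tree, n_null = 999, seed = 2)
    ph <- sim$info$phase[keep]
    same <- outer(ph, ph, "==") & upper.tri(bn@bnti)
    frac_sel <- mean(bn@bnti[same] < -2, na.rm = TRUE)
    expect_gte(frac_sel, 0.8)

    # correlogram: phylogenetically similar at short lags, signal decayed
    # at the 48 h phase separation
    bal <- philrTransform(sim$table, sim$tree)
    pd <- as.matrix(dist(bal))
    td <- as.matrix(dist(sim$info$time_h))
    cg <- suppressWarnings(
        mantelCorrelogram(pd, td, permutations = 999, seed = 3))
    expect_true(cg$significant[1] && cg$r[1] > 0)
    late <- cg[cg$midpoint >= 48, ]
    expect_false(any(late$significant & late$r > 0))

    # no temporal structure -> near-zero statistic everywhere
    sim0 <- simulateSuccession(seed = 32, equal_phases = TRUE)
    bal0 <- philrTransform(sim0$table, sim0$tree)
    cg0 <- suppressWarnings(mantelCorrelogram(
        as.matrix(dist(bal0)), as.matrix(dist(sim0$info$time_h)),
        permutations = 199, seed = 4))
    expect_lt(max(abs(cg0$r)), 0.2)
})
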