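## Phylogenetic turnover statistics: phylogenetic ILR balances, Mantel
## tests and correlograms over temporal distance classes, and
## abundance-weighted betaMNTD / betaNTI with a tip-shuffle null.

.resolve_binary <- function(tree) {
    # deterministic left-first bifurcation of multichotomies, zero-length
    if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
    stats::reorder(tree, "cladewise")
}

#' Phylogenetic isometric log-ratio (balance) transform
#'
#' Maps each sample composition to one log-ratio balance per internal node
#' of the (binary, rooted) tree:
#' `b = w_node * sqrt(r*s/(r+s)) * ln(g(x_R)/g(x_S))`, where `R`/`S` are
#' the two child clades, `g` the (part-weighted) geometric mean of the
#' clade's composition and `r`,`s` the (weighted) clade sizes.
#' `weighting = "uniform"` sets all part and node weights to 1;
#' `"abundance"` uses Euclidean-norm x geometric-mean part weights and
#' square-root branch-length node weights (the convention of the
#' phylogenetic ILR literature for abundance-weighted balances).
#'
#' @param table a [CountTable-class]; taxa must all be tree tips.
#' @param tree rooted `ape::phylo`; multichotomies are resolved
#'   deterministically with zero-length edges.
#' @param pseudocount added to every count before closure (default 1); zero
#'   counts with `pseudocount = 0` raise an error.
#' @param weighting `"uniform"` or `"abundance"`.
#' @return samples x balances matrix (one column per internal node). The
#'   transform is scale-invariant: multiplying a sample's counts by a
#'   constant leaves its balances unchanged.
#' @export
philrTransform <- function(table, tree, pseudocount = 1,
                           weighting = c("uniform", "abundance")) {
    stopifnot(is(table, "CountTable"))
    weighting <- match.arg(weighting)
    X <- counts(table)
    if (!all(colnames(X) %in% tree$tip.label))
        stop("validation error: taxa absent from the tree: ",
             paste(head(setdiff(colnames(X), tree$tip.label), 5),
                   collapse = ", "))
    tree <- ape::keep.tip(tree, colnames(X))
    tree <- .resolve_binary(tree)
    X <- X[, tree$tip.label, drop = FALSE]
    if (pseudocount == 0 && any(X == 0))
        stop("zero counts present: supply a positive pseudocount")
    Xs <- X + pseudocount
    rel <- sweep(Xs, 1, rowSums(Xs), "/")

    S <- length(tree$tip.label)
    if (weighting == "uniform") {
        pw <- rep(1, S)
    } else {
        enorm <- sqrt(colSums(rel^2))
        gmc <- exp(colMeans(log(Xs)))
        pw <- enorm * gmc
    }
    names(pw) <- tree$tip.label

    nodes <- sort(unique(tree$edge[, 1]))        # internal nodes
    tipsets <- .clade_tipsets(tree)
    logrel <- log(rel)
    out <- matrix(0, nrow(X), length(nodes),
                  dimnames = list(rownames(X), paste0("n", nodes)))
    for (q in seq_along(nodes)) {
        nd <- nodes[q]
        ch <- tree$edge[tree$edge[, 1] == nd, 2]  # cladewise: left first
        Rt <- tipsets[[ch[1]]]; St <- tipsets[[ch[2]]]
        PR <- sum(pw[Rt]); PS <- sum(pw[St])
        gR <- logrel[, Rt, drop = FALSE] %*% (pw[Rt] / PR)
        gS <- logrel[, St, drop = FALSE] %*% (pw[St] / PS)
        wn <- if (weighting == "abundance") {
            bl <- tree$edge.length[match(ch, tree$edge[, 2])]
            sqrt(sum(bl))
        } else 1
        out[, q] <- wn * sqrt(PR * PS / (PR + PS)) * (gR - gS)
    }
    out
}

.clade_tipsets <- function(tree) {
    S <- length(tree$tip.label)
    nmax <- S + tree$Nnode
    sets <- vector("list", nmax)
    for (i in seq_len(S)) sets[[i]] <- tree$tip.label[i]
    edges <- tree$edge[order(tree$edge[, 1], decreasing = TRUE), , drop = FALSE]
    for (r in seq_len(nrow(edges)))
        sets[[edges[r, 1]]] <- c(sets[[edges[r, 1]]], sets[[edges[r, 2]]])
    sets
}

.as_dist_matrix <- function(d) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m)) stop("distance matrix must be square")
    if (max(abs(m - t(m))) > 1e-9) stop("distance matrix must be symmetric")
    m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with a permutation p
#' obtained by jointly permuting rows and columns of `d2`:
#' `p = (1 + #\{r_perm >= r_obs\}) / (permutations + 1)` (one-sided,
#' identity included). When all `n!` relabelings fit in the permutation
#' budget they are enumerated exactly.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples.
#' @param permutations number of random permutations (>= 1).
#' @param seed integer seed.
#' @return list with `r`, `p`, `permutations`, `exact`.
#' @export
mantelTest <- function(d1, d2, permutations = 999, seed = 1) {
    m1 <- .as_dist_matrix(d1); m2 <- .as_dist_matrix(d2)
    n <- nrow(m1)
    if (nrow(m2) != n) stop("matching sample sets required")
    lt <- lower.tri(m1)
    v1 <- m1[lt]
    if (sd(v1) == 0 || sd(m2[lt]) == 0)
        stop("undefined statistic: constant distance matrix")
    r_obs <- stats::cor(v1, m2[lt])
    exact <- factorial(n) <= permutations + 1
    set.seed(seed)
    if (exact) {
        perms <- .all_perms(n)
        rs <- vapply(perms, function(p) stats::cor(v1, m2[p, p][lt]),
                     numeric(1))
        p <- mean(rs >= r_obs - 1e-12)
        nperm <- length(perms)
    } else {
        hits <- 0L
        for (b in seq_len(permutations)) {
            p_ <- sample(n)
            if (stats::cor(v1, m2[p_, p_][lt]) >= r_obs - 1e-12)
                hits <- hits + 1L
        }
        p <- (1 + hits) / (permutations + 1)
        nperm <- permutations
    }
    list(r = r_obs, p = p, permutations = nperm, exact = exact)
}

.all_perms <- function(n) {
    if (n == 1) return(list(1L))
    sub <- .all_perms(n - 1L)
    out <- vector("list", n * length(sub))
    i <- 0L
    for (s in sub) for (pos in seq_len(n)) {
        i <- i + 1L
        out[[i]] <- append(s, n, after = pos - 1L)
    }
    out
}

#' Mantel correlogram over temporal distance classes
#'
#' Splits the sample pairs into classes of increasing temporal distance and
#' runs, for each class, a Mantel test between the community distance
#' matrix and the class-membership indicator matrix. The statistic's sign
#' is inverted so that phylogenetically similar communities at short
#' temporal lags yield positive values. P-values are one-tailed in the
#' direction of the statistic and corrected across all distance classes
#' (Holm by default), which holds the family-wise error of the whole
#' correlogram at the nominal level; `progressive = TRUE` instead corrects
#' class k over classes 1..k only (a common correlogram convention, but
#' one that lets the first classes escape correction).
#'
#' @param phylo_d community distance matrix (e.g. Euclidean distance of
#'   [philrTransform()] balances).
#' @param time_d temporal distance matrix (hours).
#' @param breaks bin edges on the time-distance axis; default Sturges on
#'   the observed pairwise lags.
#' @param permutations permutations per class test.
#' @param correction `p.adjust` method.
#' @param progressive correct class k across classes 1..k only.
#' @param seed integer seed.
#' @param min_pairs classes with fewer pairs are skipped with a warning.
#' @return data.frame: class midpoint, n_pairs, Mantel r, p, adjusted p,
#'   significance at adjusted p < 0.05.
#' @export
mantelCorrelogram <- function(phylo_d, time_d, breaks = NULL,
                              permutations = 999, correction = "holm",
                              progressive = FALSE, seed = 1,
                              min_pairs = 3) {
    mp <- .as_dist_matrix(phylo_d); mt <- .as_dist_matrix(time_d)
    n <- nrow(mp)
    lt <- lower.tri(mt)
    lags <- mt[lt]
    if (is.null(breaks)) {
        k <- max(2L, grDevices::nclass.Sturges(lags))
        breaks <- seq(min(lags), max(lags), length.out = k + 1)
    }
    v1 <- mp[lt]
    set.seed(seed)
    rows <- list()
    for (b in seq_len(length(breaks) - 1)) {
        lo <- breaks[b]; hi <- breaks[b + 1]
        inb <- if (b == 1) lags >= lo & lags <= hi else lags > lo & lags <= hi
        npairs <- sum(inb)
        if (npairs < min_pairs) {
            warning(sprintf("distance class %d (%.1f-%.1f h) has %d pairs; skipped",
                            b, lo, hi, npairs))
            next
        }
        ind <- matrix(0, n, n)
        ind[lt][inb] <- 1
        ind <- ind + t(ind)
        r_obs <- -stats::cor(v1, ind[lt])        # inverted sign
        hits <- 0L
        for (q in seq_len(permutations)) {
            p_ <- sample(n)
            r_p <- -stats::cor(v1, ind[p_, p_][lt])
            if (sign(r_obs) * r_p >= sign(r_obs) * r_obs - 1e-12)
                hits <- hits + 1L
        }
        rows[[length(rows) + 1]] <- data.frame(
            midpoint = (lo + hi) / 2, n_pairs = npairs, r = r_obs,
            p = (1 + hits) / (permutations + 1))
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(data.frame())
    out$p_adj <- if (progressive)
        vapply(seq_len(nrow(out)), function(i)
            p.adjust(out$p[seq_len(i)], method = correction)[i], numeric(1))
    else p.adjust(out$p, method = correction)
    out$significant <- out$p_adj < 0.05
    out
}

#' Abundance-weighted beta mean nearest taxon distance for one pair
#'
#' `betaMNTD(k, l) = 1/2 * [ sum_i f_i min_j D_ij + sum_j f_j min_i D_ji ]`
#' where `i` runs over taxa present in community `k`, `j` over taxa in
#' `l`, `f` are within-community relative abundances and `D` the patristic
#' (tip-to-tip) distance.
#'
#' @param f_k,f_l non-negative abundance vectors named by taxon (or aligned
#'   with `D`'s dimnames); normalized internally over present taxa.
#' @param D patristic distance matrix (or `ape::phylo`, from which
#'   cophenetic distances are taken).
#' @return the betaMNTD value (a single non-negative number).
#' @examples
#' D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' betaMNTD(c(A = 1, B = 0, C = 0), c(A = 0, B = .5, C = .5), D)  # 2.5
#' @export
betaMNTD <- function(f_k, f_l, D) {
    if (inherits(D, "phylo")) D <- ape::cophenetic.phylo(D)
    if (!is.null(names(f_k))) f_k <- f_k[rownames(D)]
    if (!is.null(names(f_l))) f_l <- f_l[rownames(D)]
    f_k[is.na(f_k)] <- 0; f_l[is.na(f_l)] <- 0
    if (sum(f_k) == 0 || sum(f_l) == 0)
        stop("undefined: empty community")
    f_k <- f_k / sum(f_k); f_l <- f_l / sum(f_l)
    ik <- which(f_k > 0); il <- which(f_l > 0)
    mk <- apply(D[ik, il, drop = FALSE], 1, min)
    ml <- apply(D[il, ik, drop = FALSE], 1, min)
    0.5 * (sum(f_k[ik] * mk) + sum(f_l[il] * ml))
}

## min distance from every taxon to each sample's community
.support_colmins <- function(D, supports) {
    vapply(supports, function(s) {
        m <- D[, s[1]]
        for (j in s[-1]) m <- pmin(m, D[, j])
        m
    }, numeric(nrow(D)))
}

.pairwise_bmntd <- function(F, D, supports) {
    Mn <- .support_colmins(D, supports)          # S x M
    A <- F %*% Mn                                # A[k, l] = sum_i f_ki m_l(i)
    0.5 * (A + t(A))
}

#' Pairwise beta nearest taxon index with a tip-shuffle null
#'
#' Computes observed pairwise [betaMNTD()] for all samples, then a null
#' distribution by shuffling taxon labels across all tree tips present in
#' the table (one shared sequence of `n_null` shuffles for the whole
#' matrix), and the z-score
#' `betaNTI = (betaMNTD - mean_null) / sd_null`. Pairs with `|betaNTI| > 2`
#' are flagged significant; `betaNTI < -2` is read as homogeneous
#' selection, `> 2` as variable selection, and in-between values as
#' indeterminate (drift and related processes). Pairs whose null SD is zero
#' (e.g. identical communities) are flagged undefined.
#'
#' @param table a [CountTable-class].
#' @param tree rooted `ape::phylo` containing all taxa as tips.
#' @param n_null number of tip shuffles (>= 99; default 999).
#' @param seed integer seed.
#' @return A [BNTIMatrix-class].
#' @export
betaNTI <- function(table, tree, n_null = 999, seed = 1) {
    stopifnot(is(table, "CountTable"))
    if (n_null < 99) stop("n_null must be >= 99")
    X <- counts(table)
    if (!all(colnames(X) %in% tree$tip.label))
        stop("all taxa must be on the tree")
    tree <- ape::keep.tip(tree, colnames(X))
    D <- ape::cophenetic.phylo(tree)[colnames(X), colnames(X)]
    F <- sweep(X, 1, rowSums(X), "/")
    supports <- apply(X > 0, 1, which, simplify = FALSE)
    if (any(vapply(supports, length, 1L) == 0))
        stop("undefined: empty community")
    obs <- .pairwise_bmntd(F, D, supports)
    S <- ncol(X)
    set.seed(seed)
    m1 <- matrix(0, nrow(X), nrow(X))
    m2 <- matrix(0, nrow(X), nrow(X))
    for (b in seq_len(n_null)) {
        perm <- sample(S)
        Bp <- .pairwise_bmntd(F, D[perm, perm], supports)
        m1 <- m1 + Bp
        m2 <- m2 + Bp^2
    }
    mu <- m1 / n_null
    sdv <- sqrt(pmax(m2 / n_null - mu^2, 0) * n_null / (n_null - 1))
    z <- (obs - mu) / sdv
    z[sdv == 0] <- NA
    diag(z) <- 0
    cls <- matrix("indeterminate", nrow(z), ncol(z))
    cls[!is.na(z) & z < -2] <- "homogeneous_selection"
    cls[!is.na(z) & z > 2] <- "variable_selection"
    cls[is.na(z)] <- "undefined"
    diag(cls) <- "self"
    dimnames(z) <- dimnames(obs) <- dimnames(mu) <- dimnames(sdv) <-
        dimnames(cls) <- list(rownames(X), rownames(X))
    new("BNTIMatrix", bmntd = obs, nullMean = mu, nullSD = sdv, bnti = z,
        significant = !is.na(z) & abs(z) > 2, classification = cls,
        nNull = as.integer(n_null))
}
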