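#' Parameter bundles for the synthetic-data generators
#'
#' `neutralParams()` collects the neutral-assembly parameters: the
#' fundamental biodiversity (speciation) parameter `theta` of the
#' metacommunity, per-sample immigration rates, the sequencing depth, and
#' the truncation cap of the stick-breaking measure.
#' `successionParams()` parameterizes the phase-structured succession
#' generator, and `zinbParams()` the per-taxon zero-inflated negative
#' binomial trajectory generator.
#'
#' @param theta positive speciation parameter.
#' @param immigration positive immigration rate(s), recycled across samples.
#' @param depth reads per sample.
#' @param n_taxa_cap truncation of the stick-breaking measure.
#' @return a named list of validated parameters.
#' @export
neutralParams <- function(theta = 20, immigration = 10, depth = 1000,
                          n_taxa_cap = 50) {
    if (theta <= 0) stop("theta must be positive")
    if (any(immigration <= 0)) stop("immigration rates must be positive")
    if (depth < 1 || n_taxa_cap < 1) stop("depth and n_taxa_cap must be >= 1")
    list(theta = theta, immigration = immigration, depth = depth,
         n_taxa_cap = as.integer(n_taxa_cap))
}

#' @rdname neutralParams
#' @param n_taxa_per_phase taxa in each phase-specific block of the shared
#'   taxon pool (attachment, selection, facilitation).
#' @param replicates flasks per time point.
#' @param noise Dirichlet concentration of within-phase compositional noise
#'   (per phase, recycled); higher values give more even communities over
#'   the occupied taxa.
#' @param occupancy fraction of its phase's taxon block each sample
#'   colonizes (patchy colonization: the subset is redrawn per sample, so
#'   replicate communities share a clade but not a taxon list).
#' @param sharpness in `[0, 1]`: 0 mixes adjacent phases linearly in time
#'   across the transition window, 1 snaps each transition sample to the
#'   nearer phase.
#' @param leak small probability mass each phase composition places outside
#'   its own taxon block (keeps tables irreducible).
#' @param substrates character vector of substrate names to emulate.
#' @export
successionParams <- function(n_taxa_per_phase = 80, replicates = 3,
                             noise = 300, occupancy = 0.5, sharpness = 0,
                             leak = 0.01, depth = 2000,
                             substrates = "alginate") {
    if (n_taxa_per_phase < 2) stop("need at least 2 taxa per phase")
    if (sharpness < 0 || sharpness > 1) stop("sharpness must be in [0, 1]")
    if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
    list(n_taxa_per_phase = as.integer(n_taxa_per_phase),
         replicates = as.integer(replicates),
         noise = rep_len(noise, 3), occupancy = occupancy,
         sharpness = sharpness, leak = leak,
         depth = as.integer(depth), substrates = substrates)
}

#' @rdname neutralParams
#' @param intercept count-part intercept (log scale, attachment reference).
#' @param selection,facilitation count-part phase effects (log scale).
#' @param zero_intercept,zero_selection,zero_facilitation zero-inflation
#'   coefficients (logit scale); `-Inf` intercept with zero phase effects
#'   gives a pure negative binomial.
#' @param dispersion negative binomial size parameter (> 0).
#' @export
zinbParams <- function(intercept = -6, selection = 0, facilitation = 0,
                       zero_intercept = -1, zero_selection = 0,
                       zero_facilitation = 0, dispersion = 1) {
    if (dispersion <= 0) stop("dispersion must be positive")
    list(intercept = intercept, selection = selection,
         facilitation = facilitation, zero_intercept = zero_intercept,
         zero_selection = zero_selection,
         zero_facilitation = zero_facilitation, dispersion = dispersion)
}

.rdirichlet <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    g / sum(g)
}

#' Draw a metacommunity distribution by truncated stick breaking
#'
#' Draws the metacommunity relative-abundance distribution of a neutral
#' (Hubbell-type) regional pool: stick-breaking weights `v_j ~ Beta(1,
#' theta)` truncated at `n_taxa_cap` sticks and renormalized. Larger `theta`
#' yields more, more-even taxa.
#'
#' @param theta positive speciation parameter.
#' @param n_taxa_cap number of sticks retained.
#' @param seed integer seed.
#' @return numeric simplex of length `n_taxa_cap` (sums to 1 within 1e-12).
#' @examples
#' beta <- sampleMetacommunity(20, 50, seed = 1)
#' sum(beta)
#' @export
sampleMetacommunity <- function(theta, n_taxa_cap, seed = 1) {
    if (theta <= 0) stop("theta must be positive")
    set.seed(seed)
    v <- rbeta(n_taxa_cap, 1, theta)
    w <- v * cumprod(c(1, 1 - v[-n_taxa_cap]))
    w / sum(w)
}

#' Sample neutral local communities from a metacommunity
#'
#' Each local community draws its composition `p_i ~ Dirichlet(I_i * beta)`
#' (immigration-limited sampling of the metacommunity) and its reads
#' `x_i ~ Multinomial(depth, p_i)` -- the generative layers of the
#' hierarchical Dirichlet process neutral model.
#'
#' @param beta metacommunity simplex (e.g. from [sampleMetacommunity()]).
#' @param params a [neutralParams()] bundle; `n_taxa_cap` must match
#'   `length(beta)`.
#' @param n_samples number of local communities.
#' @param seed integer seed.
#' @return A [CountTable-class] with one row per local community; every row
#'   total equals `params$depth`.
#' @export
sampleLocalCommunities <- function(beta, params, n_samples, seed = 1) {
    if (abs(sum(beta) - 1) > 1e-8) stop("beta must be on the simplex")
    if (length(beta) != params$n_taxa_cap)
        stop("dimension mismatch between beta and n_taxa_cap")
    if (n_samples < 1) stop("n_samples must be >= 1")
    set.seed(seed)
    I <- rep_len(params$immigration, n_samples)
    x <- matrix(0, n_samples, length(beta))
    for (i in seq_len(n_samples)) {
        p <- .rdirichlet(I[i] * beta)
        x[i, ] <- rmultinom(1, params$depth, p)
    }
    CountTable(x, sample_ids = paste0("local", seq_len(n_samples)),
               taxon_ids = paste0("taxon", seq_along(beta)))
}

.yule_subtree <- function(n, label_prefix) {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    tr$tip.label <- paste0(label_prefix, seq_len(n))
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tr
}

#' Simulate a phase-structured colonization succession
#'
#' Emulates one substrate's multi-flask time series: samples on the
#' experimental grid (11 time points, `replicates` flasks), each community
#' colonizing a random `occupancy` fraction of its phase's taxon block
#' (patchy colonization, so replicate communities share a clade but turn
#' over in membership) with composition drawn from a Dirichlet over the
#' occupied taxa; transition-time samples mix the selection and
#' facilitation blocks with a time-linear weight; and a random rooted tree
#' whose tips are the taxa with each phase's block forming a clade, so
#' that homogeneous selection (strongly negative beta nearest taxon index
#' within phases) is recoverable from the turnover statistics.
#'
#' @param params a [successionParams()] bundle.
#' @param seed integer seed.
#' @param equal_phases set all three phase compositions equal (a
#'   no-turnover negative control).
#' @return list with elements `table` ([CountTable-class]), `info` (sample
#'   metadata data.frame), `tree` (`ape::phylo`), and `phase_composition`
#'   (3 x S matrix of the generating phase means).
#' @export
simulateSuccession <- function(params = successionParams(), seed = 1,
                               equal_phases = FALSE) {
    set.seed(seed)
    npp <- params$n_taxa_per_phase
    S <- 3L * npp
    taxa <- paste0("taxon", seq_len(S))
    phases <- c("attachment", "selection", "facilitation")
    blocks <- lapply(1:3, function(k) ((k - 1L) * npp + 1L):(k * npp))
    if (equal_phases) blocks[[2]] <- blocks[[3]] <- blocks[[1]]
    # phase mean compositions (uniform over the block, plus leak)
    comp <- matrix(params$leak / (S - npp), 3, S,
                   dimnames = list(phases, taxa))
    for (k in 1:3)
        comp[k, blocks[[k]]] <- (1 - params$leak) / npp

    grid <- samplingGrid()
    rows <- expand.grid(substrate = params$substrates,
                        time_h = grid, replicate = seq_len(params$replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[order(rows$substrate, rows$time_h, rows$replicate), ]
    rows$phase <- phaseForTime(rows$time_h)
    rows$sample_id <- sprintf("%s_t%03d_r%d", rows$substrate, rows$time_h,
                              rows$replicate)
    w <- phaseWindows()
    tw <- w[w$phase == "transition", ]
    n_occ <- max(2L, round(params$occupancy * npp))
    x <- matrix(0, nrow(rows), S, dimnames = list(rows$sample_id, taxa))
    for (i in seq_len(nrow(rows))) {
        ph <- rows$phase[i]
        wt <- c(attachment = 0, selection = 0, facilitation = 0)
        if (ph == "transition") {
            lam <- (rows$time_h[i] - tw$lower) / (tw$upper - tw$lower)
            lam <- (1 - params$sharpness) * lam +
                params$sharpness * round(lam)
            wt["selection"] <- 1 - lam
            wt["facilitation"] <- lam
            conc <- mean(params$noise[2:3])
        } else {
            wt[ph] <- 1
            conc <- params$noise[match(ph, phases)]
        }
        # patchy colonization: a fresh random subset of the block(s)
        alpha <- rep(params$leak * conc / S, S)
        for (k in 1:3) if (wt[k] > 0) {
            occ <- sample(blocks[[k]], n_occ)
            alpha[occ] <- alpha[occ] + wt[k] * (1 - params$leak) * conc / n_occ
        }
        x[i, ] <- rmultinom(1, params$depth, .rdirichlet(alpha))
    }
    # one Yule clade per phase block, joined at the root by stems
    sub <- lapply(1:3, function(k)
        .yule_subtree(npp, sprintf("taxon_block%d_", k)))
    back <- ape::read.tree(text = "(b1:1.5,b2:1.5,b3:1.5);")
    tree <- back
    for (k in 1:3)
        tree <- ape::bind.tree(tree, sub[[k]],
                               where = which(tree$tip.label == paste0("b", k)))
    blk <- as.integer(sub("^taxon_block(\\d+)_\\d+$", "\\1", tree$tip.label))
    idx <- as.integer(sub("^taxon_block\\d+_(\\d+)$", "\\1", tree$tip.label))
    tree$tip.label <- taxa[(blk - 1L) * npp + idx]
    info <- rows[, c("sample_id", "substrate", "replicate", "time_h", "phase")]
    rownames(info) <- NULL
    list(table = CountTable(x), info = validateSampleInfo(info),
         tree = tree, phase_composition = comp)
}

#' Simulate one taxon's counts under a zero-inflated negative binomial
#'
#' Counts follow `pi * delta_0 + (1 - pi) * NegBin(mu, size)` with
#' `log mu = intercept + phase effects + log(total reads)` (the sequencing
#' depth enters as an offset) and `logit pi` linear in the same phase
#' design. Samples whose phase is not attachment, selection or facilitation
#' are not supported by the three-level design and raise an error.
#'
#' @param params a [zinbParams()] bundle.
#' @param design sample metadata data.frame (see [readSampleInfo()]) with
#'   phases among attachment/selection/facilitation.
#' @param totals per-sample total reads for the offset (recycled).
#' @param seed integer seed.
#' @return integer vector of counts, one per design row.
#' @export
simulateZINBCounts <- function(params, design, totals = 1000, seed = 1) {
    if (nrow(design) == 0) stop("design must be non-empty")
    bad <- !design$phase %in% c("attachment", "selection", "facilitation")
    if (any(bad))
        stop("design phases must be attachment/selection/facilitation")
    set.seed(seed)
    totals <- rep_len(totals, nrow(design))
    sel <- design$phase == "selection"
    fac <- design$phase == "facilitation"
    eta <- params$intercept + params$selection * sel +
        params$facilitation * fac + log(totals)
    if (any(!is.finite(eta))) stop("non-finite linear predictor")
    zeta <- params$zero_intercept + params$zero_selection * sel +
        params$zero_facilitation * fac
    pi0 <- stats::plogis(zeta)
    y <- rnbinom(nrow(design), size = params$dispersion, mu = exp(eta))
    drop <- runif(nrow(design)) < pi0
    y[drop] <- 0L
    y
}

#' Simulate gene-pathway proportion profiles with planted group effects
#'
#' Draws per-sample feature proportions by normalizing positive noise around
#' group-specific means; `shift` adds mass to `shift_feature` in
#' `shift_group` (compensated on the remaining features), planting a known
#' differential signal for the trait-comparison tests.
#'
#' @param n_features number of features.
#' @param groups per-sample group labels.
#' @param shift effect size added to the shifted feature's mean proportion.
#' @param shift_feature,shift_group where the effect is planted.
#' @param sdev Gaussian noise SD on the proportion scale before truncation.
#' @param seed integer seed.
#' @return A [GeneProfileTable-class].
#' @export
simulateGeneProfiles <- function(n_features = 20, groups, shift = 0,
                                 shift_feature = 1, shift_group = NULL,
                                 sdev = 0.02, seed = 1) {
    set.seed(seed)
    base <- .rdirichlet(rep(5, n_features))
    m <- matrix(0, n_features, length(groups))
    for (j in seq_along(groups)) {
        mu <- base
        if (!is.null(shift_group) && groups[j] == shift_group) {
            target <- mu[shift_feature] + shift
            if (target >= 1) stop("shifted mean proportion must stay below 1")
            mu[-shift_feature] <- mu[-shift_feature] *
                (1 - target) / (1 - mu[shift_feature])
            mu[shift_feature] <- target
        }
        p <- pmax(mu + rnorm(n_features, 0, sdev), 1e-6)
        m[, j] <- p / sum(p)
    }
    rownames(m) <- paste0("pathway", seq_len(n_features))
    colnames(m) <- paste0("sample", seq_along(groups))
    GeneProfileTable(m, groups)
}
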