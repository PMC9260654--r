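# shared fixture builders (all programmatic; no stored data)

rdirichlet1 <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
}

# samples from a single Dirichlet-multinomial source
dm_table <- function(alpha, n, depth = 800, seed = 1, prefix = "s") {
    set.seed(seed)
    X <- t(vapply(seq_len(n), function(i)
        rmultinom(1, depth, rdirichlet1(alpha))[, 1],
        numeric(length(alpha))))
    CountTable(X, sample_ids = paste0(prefix, seq_len(n)))
}

# two well-separated metacommunities on disjoint taxon blocks:
# block concentration 5, off-block 0.5
two_source_table <- function(seed, n_per = 15, S = 40, depth = 800) {
    half <- S / 2
    a1 <- c(rep(5, half), rep(0.5, half))
    a2 <- rev(a1)
    t1 <- counts(dm_table(a1, n_per, depth, seed = seed * 2 + 1))
    t2 <- counts(dm_table(a2, n_per, depth, seed = seed * 2 + 2))
    CountTable(rbind(t1, t2), sample_ids = paste0("s", seq_len(2 * n_per)))
}

# neutral HDP dataset: stick-breaking metacommunity + local communities
neutral_dataset <- function(seed, n_samples = 10, n_taxa = 50,
                            depth = 1000, theta = 20, immigration = 10) {
    beta <- sampleMetacommunity(theta, n_taxa, seed = seed)
    sampleLocalCommunities(
        beta, neutralParams(theta = theta, immigration = immigration,
                            depth = depth, n_taxa_cap = n_taxa),
        n_samples, seed = seed + 10000)
}

# neutral data at the calibration condition: effectively untruncated
# stick-breaking pool (about 50 observed taxa at depth 1000)
calibration_neutral_dataset <- function(seed) {
    ct <- neutral_dataset(seed, theta = 12, n_taxa = 200)
    X <- counts(ct)
    CountTable(X[, colSums(X) > 0])
}

# planted-selection dataset: two disjoint niche blocks inside one "class",
# with local communities tracking their block metacommunity tightly
# (strong homogeneous selection)
selected_dataset <- function(seed, n_samples = 10, n_taxa = 50,
                             depth = 1000) {
    half <- n_taxa / 2
    b1 <- sampleMetacommunity(10, half, seed = seed)
    b2 <- sampleMetacommunity(10, half, seed = seed + 500)
    p <- neutralParams(theta = 10, immigration = 30, depth = depth,
                       n_taxa_cap = half)
    x1 <- counts(sampleLocalCommunities(b1, p, n_samples / 2, seed = seed + 1))
    x2 <- counts(sampleLocalCommunities(b2, p, n_samples / 2, seed = seed + 2))
    X <- cbind(rbind(x1, matrix(0, n_samples / 2, half)),
               rbind(matrix(0, n_samples / 2, half), x2))
    CountTable(X, sample_ids = paste0("s", seq_len(n_samples)),
               taxon_ids = paste0("t", seq_len(n_taxa)))
}

# sparse random communities over the tips of a random tree (null model for
# betaNTI calibration): each community occupies a uniform random tip subset
uniform_tip_table <- function(tree, n_samples = 8, tips_per = 25,
                              depth = 500, seed = 1) {
    set.seed(seed)
    S <- length(tree$tip.label)
    X <- matrix(0, n_samples, S,
                dimnames = list(paste0("s", seq_len(n_samples)),
                                tree$tip.label))
    for (i in seq_len(n_samples)) {
        idx <- sample(S, tips_per)
        X[i, idx] <- rmultinom(1, depth, rep(1 / tips_per, tips_per))[, 1]
    }
    CountTable(X)
}

# central-difference gradient used by gradient-at-optimum checks
numDeriv_grad <- function(f, x, h = 1e-5) {
    vapply(seq_along(x), function(j) {
        e <- rep(0, length(x)); e[j] <- h
        (f(x + e) - f(x - e)) / (2 * h)
    }, numeric(1))
}

# design for the per-taxon phase models: 8 substrates x 11 times x 3 reps
full_design <- function(n_substrates = 8, replicates = 3) {
    grid <- samplingGrid()
    rows <- expand.grid(substrate = paste0("sub", seq_len(n_substrates)),
                        time_h = grid, replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows$phase <- phaseForTime(rows$time_h)
    rows$sample_id <- sprintf("%s_t%03d_r%d", rows$substrate, rows$time_h,
                              rows$replicate)
    rows[, c("sample_id", "substrate", "replicate", "time_h", "phase")]
}
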