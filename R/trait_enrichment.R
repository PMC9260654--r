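## Differential gene-pathway proportion analysis between community phases.

#' Welch comparison of feature proportions between two groups
#'
#' Per-feature two-sided Welch two-sample t test on proportions, an
#' effect-size filter on the absolute difference of mean proportions, and
#' Benjamini-Hochberg correction across the retained features. By default
#' (the convention of extended-error-bar workflows) the effect filter is
#' applied before the multiplicity correction; `filter_after = TRUE`
#' corrects across all features first and filters afterwards.
#'
#' @param profiles a [GeneProfileTable-class].
#' @param group_a,group_b group labels to contrast (each with >= 2
#'   samples).
#' @param effect_min minimum absolute difference of mean proportions; 0.1
#'   is the convention for measured (metagenome / isolate) profiles and
#'   0.05 for predicted profiles.
#' @param conf_level confidence level of the Welch CI of the difference.
#' @param filter_after apply BH before instead of after the effect filter.
#' @return data.frame ordered by adjusted p with per-feature means,
#'   difference (`group_a - group_b`), Welch CI, t, Welch-Satterthwaite df,
#'   raw and BH-adjusted p, and the filter threshold as an attribute.
#' @export
welchCompare <- function(profiles, group_a, group_b, effect_min = 0.1,
                         conf_level = 0.95, filter_after = FALSE) {
    stopifnot(is(profiles, "GeneProfileTable"))
    P <- profiles@proportions
    ia <- which(profiles@groups == group_a)
    ib <- which(profiles@groups == group_b)
    if (length(ia) < 2 || length(ib) < 2)
        stop("each group needs at least 2 samples")
    res <- lapply(rownames(P), function(f) {
        a <- P[f, ia]; b <- P[f, ib]
        d <- mean(a) - mean(b)
        if (var(a) == 0 && var(b) == 0) {
            # degenerate: no within-group variation
            p <- if (d == 0) 1 else 0
            return(data.frame(feature = f, mean_a = mean(a),
                              mean_b = mean(b), difference = d,
                              ci_lower = d, ci_upper = d,
                              t = if (d == 0) 0 else Inf * sign(d),
                              df = NA_real_, p = p))
        }
        tt <- t.test(a, b, var.equal = FALSE, conf.level = conf_level)
        data.frame(feature = f, mean_a = mean(a), mean_b = mean(b),
                   difference = d, ci_lower = tt$conf.int[1],
                   ci_upper = tt$conf.int[2], t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
    })
    out <- do.call(rbind, res)
    if (filter_after) {
        out$p_adj <- p.adjust(out$p, "BH")
        out <- out[abs(out$difference) >= effect_min, , drop = FALSE]
    } else {
        out <- out[abs(out$difference) >= effect_min, , drop = FALSE]
        out$p_adj <- p.adjust(out$p, "BH")
    }
    out <- out[order(out$p_adj, out$p), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "effect_min") <- effect_min
    attr(out, "groups") <- c(group_a, group_b)
    out
}

.eta_squared <- function(values, groups) {
    gm <- tapply(values, groups, mean)
    ns <- tapply(values, groups, length)
    ssb <- sum(ns * (gm - mean(values))^2)
    sst <- sum((values - mean(values))^2)
    if (sst == 0) NA_real_ else ssb / sst
}

.games_howell <- function(values, groups) {
    g <- unique(groups)
    k <- length(g)
    m <- tapply(values, groups, mean)[g]
    v <- tapply(values, groups, var)[g]
    n <- tapply(values, groups, length)[g]
    out <- list()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        se2 <- v[i] / n[i] + v[j] / n[j]
        t <- (m[i] - m[j]) / sqrt(se2)
        df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                       (v[j] / n[j])^2 / (n[j] - 1))
        p <- ptukey(abs(t) * sqrt(2), nmeans = k, df = df,
                    lower.tail = FALSE)
        out[[length(out) + 1]] <- data.frame(
            group1 = g[i], group2 = g[j], difference = unname(m[i] - m[j]),
            p_adj = unname(p))
    }
    do.call(rbind, out)
}

#' Multi-group comparison of feature proportions with post-hoc contrasts
#'
#' One-way ANOVA per feature with BH correction across features; features
#' passing adjusted p < `alpha` and an eta-squared effect size
#' `>= effect_min` receive pairwise post-hoc tests (Tukey-Kramer, or
#' Games-Howell for unequal variances).
#'
#' @param profiles a [GeneProfileTable-class] with at least 3 groups, each
#'   with at least 2 samples.
#' @param effect_min minimum eta-squared effect size (default 0.2).
#' @param posthoc `"tukey"` (Tukey-Kramer via `TukeyHSD`) or
#'   `"games_howell"`.
#' @param alpha significance level for the BH-adjusted ANOVA p.
#' @return list with `anova` (per-feature p, adjusted p, effect size) and
#'   `posthoc` (pairwise table for the selected features).
#' @export
multigroupCompare <- function(profiles, effect_min = 0.2,
                              posthoc = c("tukey", "games_howell"),
                              alpha = 0.05) {
    stopifnot(is(profiles, "GeneProfileTable"))
    posthoc <- match.arg(posthoc)
    grp <- factor(profiles@groups)
    if (nlevels(grp) < 3) stop("need at least 3 groups")
    if (any(table(grp) < 2)) stop("each group needs at least 2 samples")
    P <- profiles@proportions
    rows <- list()
    for (f in rownames(P)) {
        y <- P[f, ]
        if (all(tapply(y, grp, var) == 0)) {
            warning("feature ", f, " has no within-group variance; skipped")
            next
        }
        fit <- aov(y ~ grp)
        p <- summary(fit)[[1]][["Pr(>F)"]][1]
        rows[[f]] <- data.frame(feature = f, p = p,
                                effect = .eta_squared(y, grp))
    }
    an <- do.call(rbind, rows)
    rownames(an) <- NULL
    an$p_adj <- p.adjust(an$p, "BH")
    sel <- an$feature[an$p_adj < alpha & an$effect >= effect_min &
                      !is.na(an$effect)]
    ph <- list()
    for (f in sel) {
        y <- P[f, ]
        tab <- if (posthoc == "tukey") {
            tk <- TukeyHSD(aov(y ~ grp))$grp
            pairs <- do.call(rbind, strsplit(rownames(tk), "-"))
            data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                       difference = tk[, "diff"], p_adj = tk[, "p adj"])
        } else .games_howell(y, as.character(grp))
        tab$feature <- f
        ph[[f]] <- tab
    }
    posthoc_tab <- if (length(ph)) do.call(rbind, c(ph, make.row.names = FALSE))
                   else data.frame()
    list(anova = an[order(an$p_adj), ], posthoc = posthoc_tab)
}
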