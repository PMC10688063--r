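#' Kruskal-Wallis test with post hoc pairwise comparisons
#'
#' Omnibus Kruskal-Wallis rank-sum test across groups, followed by either
#' the Conover-Iman rank t-test or pairwise Wilcoxon tests, with p-value
#' adjustment (Bonferroni by default). Used for per-generation epimutation
#' and mutation rates compared across exposure conditions.
#'
#' @param values numeric vector of observations
#' @param groups grouping vector parallel to \code{values}
#' @param posthoc \code{"conover"} or \code{"wilcoxon"}
#' @param p.adjust.method passed to \code{\link[stats]{p.adjust}}
#' @return list with \code{kw} (H statistic, df, p) and \code{pairwise}
#'   (data.frame group1, group2, p_raw, p_adj)
#' @export
rateTests <- function(values, groups, posthoc = c("conover", "wilcoxon"),
                      p.adjust.method = "bonferroni") {
    posthoc <- match.arg(posthoc)
    g <- factor(groups)
    if (nlevels(g) < 2 || any(table(g) < 2))
        .stopf("need >= 2 groups with >= 2 observations each")
    kw <- stats::kruskal.test(values, g)
    pw <- if (posthoc == "conover") {
        .conoverIman(values, g, H = unname(kw$statistic))
    } else {
        pm <- stats::pairwise.wilcox.test(values, g, p.adjust.method = "none",
                                          exact = FALSE)$p.value
        idx <- which(!is.na(pm), arr.ind = TRUE)
        data.frame(group1 = rownames(pm)[idx[, 1]],
                   group2 = colnames(pm)[idx[, 2]],
                   p_raw = pm[idx])
    }
    pw$p_adj <- pmin(1, stats::p.adjust(pw$p_raw, p.adjust.method))
    list(kw = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p = kw$p.value),
         pairwise = pw)
}

# Conover-Iman post hoc: t statistics on pooled ranks with the
# ties-corrected pooled variance, N - k degrees of freedom.
.conoverIman <- function(values, g, H) {
    r <- rank(values)
    N <- length(r); k <- nlevels(g)
    n <- tabulate(g)
    rbar <- tapply(r, g, mean)
    S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
    pairs <- utils::combn(levels(g), 2)
    p <- apply(pairs, 2, function(pr) {
        i <- match(pr[1], levels(g)); j <- match(pr[2], levels(g))
        se <- sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / n[i] + 1 / n[j]))
        tstat <- (rbar[[i]] - rbar[[j]]) / se
        2 * stats::pt(abs(tstat), N - k, lower.tail = FALSE)
    })
    data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_raw = p)
}

# J statistic with the half-tie convention
.jstat <- function(groups) {
    k <- length(groups)
    J <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        cmpv <- outer(groups[[i]], groups[[j]], "<")
        ties <- outer(groups[[i]], groups[[j]], "==")
        J <- J + sum(cmpv) + 0.5 * sum(ties)
    }
    J
}

#' Jonckheere-Terpstra test for an ordered alternative
#'
#' Tests whether group locations follow the supplied order (e.g. control <
#' low dose < high dose). J is the sum over ordered group pairs of
#' Mann-Whitney counts (ties counted half). For small samples the null
#' distribution is computed exactly by enumerating all distinct assignments
#' of the pooled observations to the groups (feasible when the multinomial
#' arrangement count is at most \code{maxExact}); otherwise a normal
#' approximation with tie-corrected variance is used.
#'
#' @param groups list of numeric vectors in hypothesised increasing order
#' @param alternative \code{"increasing"} or \code{"decreasing"}
#' @param maxExact use exact enumeration when the number of label
#'   arrangements does not exceed this (default 2e5)
#' @return list (J, z, p, method); \code{z} is NA on the exact path. Fully
#'   tied input gives z = 0 and one-sided p = 0.5.
#' @export
jonckheereTest <- function(groups, alternative = c("increasing",
                                                   "decreasing"),
                           maxExact = 2e5) {
    alternative <- match.arg(alternative)
    if (length(groups) < 3) .stopf("need >= 3 ordered groups")
    if (alternative == "decreasing") groups <- rev(groups)
    J <- .jstat(groups)
    n <- lengths(groups)
    N <- sum(n)
    pooled <- unlist(groups, use.names = FALSE)
    if (length(unique(pooled)) == 1L)   # tie-saturated: no ordering signal
        return(list(J = J, z = 0, p = 0.5, method = "degenerate"))
    nArrange <- exp(lgamma(N + 1) - sum(lgamma(n + 1)))
    if (N <= 30 && nArrange <= maxExact) {
        Js <- .enumerateJ(pooled, n)
        p <- mean(Js >= J - 1e-9)
        return(list(J = J, z = NA_real_, p = p, method = "exact"))
    }
    mu <- (N^2 - sum(n^2)) / 4
    tt <- table(pooled)
    A <- N * (N - 1) * (2 * N + 5) -
        sum(n * (n - 1) * (2 * n + 5)) -
        sum(tt * (tt - 1) * (2 * tt + 5))
    B <- sum(n * (n - 1) * (n - 2)) * sum(tt * (tt - 1) * (tt - 2))
    C <- sum(n * (n - 1)) * sum(tt * (tt - 1))
    v <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) + C / (8 * N * (N - 1))
    if (!is.finite(v) || v <= 1e-12) {
        z <- 0
    } else {
        z <- (J - mu) / sqrt(v)
    }
    list(J = J, z = z, p = stats::pnorm(z, lower.tail = FALSE),
         method = "normal")
}

# all J values over distinct assignments of pooled values to group sizes
.enumerateJ <- function(pooled, sizes) {
    res <- numeric(0)
    recur <- function(idx, si, acc) {
        if (si > length(sizes)) {
            res[length(res) + 1L] <<- .jstat(acc)
            return()
        }
        if (si == length(sizes)) {
            recur(integer(0), si + 1L, c(acc, list(pooled[idx])))
            return()
        }
        picks <- utils::combn(idx, sizes[si], simplify = FALSE)
        for (pk in picks)
            recur(setdiff(idx, pk), si + 1L, c(acc, list(pooled[pk])))
    }
    recur(seq_along(pooled), 1L, list())
    res
}
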