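#' Detect epimutation runs from a ternary call matrix
#'
#' A run is a maximal stretch of sampled generations in one lineage where a
#' locus carries the same nonzero call direction. A direction flip closes
#' the preceding run and starts a new one at the flip generation; a zero
#' call closes the run. A sampled generation missing from the data bridges
#' a run when both flanking available generations carry the same direction
#' (the interpolation assumption: an epimutation present at generations 2
#' and 4 is taken to exist at 3); with \code{strict = TRUE} any gap closes
#' the run instead. A run whose last generation is the lineage's final
#' available generation is censored (its full duration is unobserved).
#'
#' @param x \linkS4class{EpimutationCalls}, or an integer call matrix if
#'   \code{meta} is supplied
#' @param meta data.frame(lineage, generation) parallel to the columns of
#'   the matrix form
#' @param strict close runs at any missing sampled generation
#' @return data.frame (locus, lineage, direction, start_gen, end_gen,
#'   n_sampled, censored); durations are in sampled-generation units, with
#'   an \code{organismal_generations} column at twice the sampled count
#'   since samples are two generations apart
#' @export
detectRuns <- function(x, meta = NULL, strict = FALSE) {
    if (is(x, "EpimutationCalls")) {
        calls <- callMatrix(x)
        meta <- data.frame(lineage = lineages(x), generation = generations(x))
    } else {
        calls <- x
        if (is.null(meta)) .stopf("matrix input requires meta")
    }
    loci <- rownames(calls) %||% as.character(seq_len(nrow(calls)))
    out <- list()
    for (ln in unique(meta$lineage)) {
        idx <- which(meta$lineage == ln)
        idx <- idx[order(meta$generation[idx])]
        gens <- meta$generation[idx]
        lastGen <- gens[length(gens)]
        n <- nrow(calls)
        cur <- integer(n); startG <- integer(n); endG <- integer(n)
        cnt <- integer(n)
        close <- function(which) {
            if (!any(which)) return()
            out[[length(out) + 1L]] <<- data.frame(
                locus = loci[which], lineage = ln,
                direction = cur[which], start_gen = startG[which],
                end_gen = endG[which], n_sampled = cnt[which],
                censored = endG[which] == lastGen)
        }
        for (j in seq_along(idx)) {
            d <- calls[, idx[j]]
            if (strict && j > 1L && gens[j] - gens[j - 1L] > 2L) {
                close(cur != 0L)
                cur[] <- 0L
            }
            ended <- cur != 0L & d != cur
            close(ended)
            starting <- d != 0L & d != cur
            cont <- d != 0L & d == cur
            cur[ended & d == 0L] <- 0L
            cur[starting] <- d[starting]
            startG[starting] <- gens[j]
            cnt[starting] <- 1L
            endG[starting] <- gens[j]
            cnt[cont] <- cnt[cont] + 1L
            endG[cont] <- gens[j]
        }
        close(cur != 0L)
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(locus = character(), lineage = character(),
                   direction = integer(), start_gen = integer(),
                   end_gen = integer(), n_sampled = integer(),
                   censored = logical())
    res$organismal_generations <- 2L * res$n_sampled
    rownames(res) <- NULL
    res
}

#' Per-generation counts of newly arising epimutations
#'
#' Number of runs starting at each available (lineage, generation);
#' generation 0 (the founder) is excluded.
#'
#' @param runs data.frame from \code{\link{detectRuns}}
#' @param available data.frame(lineage, generation) of sampled pairs
#' @return data.frame (lineage, generation, n_new) covering every available
#'   pair with generation > 0, zeros included
#' @export
newEpimutationRate <- function(runs, available) {
    av <- available[available$generation > 0L, , drop = FALSE]
    key <- paste(av$lineage, av$generation)
    cnt <- table(paste(runs$lineage, runs$start_gen))
    av$n_new <- as.integer(cnt[key])
    av$n_new[is.na(av$n_new)] <- 0L
    rownames(av) <- NULL
    av
}

#' Fraction of epimutations inherited for two or more sampled generations
#'
#' A run is inherited when it spans at least two sampled generations.
#' Runs starting at a lineage's final available generation are excluded
#' from the denominator: their inheritance is unobservable.
#'
#' @param runs data.frame from \code{\link{detectRuns}}
#' @param available data.frame(lineage, generation); needed to locate each
#'   lineage's final generation
#' @param by grouping column of \code{runs} (e.g. "lineage"); NULL for a
#'   single overall fraction
#' @return data.frame (group, n_runs, n_inherited, fraction_pct), with a
#'   per-start-generation decomposition in \code{attr(, "per_generation")}
#' @export
inheritedFraction <- function(runs, available, by = NULL) {
    lastGen <- vapply(split(as.numeric(available$generation),
                            available$lineage), max, numeric(1))
    eligible <- runs[runs$start_gen < lastGen[runs$lineage], , drop = FALSE]
    grp <- if (is.null(by)) rep("all", nrow(eligible)) else eligible[[by]]
    agg <- function(sub) {
        data.frame(n_runs = nrow(sub),
                   n_inherited = sum(sub$n_sampled >= 2L),
                   fraction_pct = 100 * mean(sub$n_sampled >= 2L))
    }
    res <- do.call(rbind, lapply(split(eligible, grp), agg))
    res <- cbind(group = rownames(res), res)
    rownames(res) <- NULL
    perGen <- do.call(rbind, lapply(
        split(eligible, list(eligible$lineage, eligible$start_gen),
              drop = TRUE), agg))
    attr(res, "per_generation") <- perGen
    res
}

#' Kaplan-Meier curve of epimutation durations
#'
#' Duration is the number of sampled generations a run persisted
#' (\code{n_sampled}); runs still active at the lineage's last available
#' generation are censored at their observed duration. The product-limit
#' estimate is computed with \code{survival::survfit}.
#'
#' @param runs data.frame from \code{\link{detectRuns}}
#' @return data.frame (time, n_risk, n_event, n_censor, surv) with the
#'   \code{survfit} object in \code{attr(, "survfit")}
#' @export
kmCurve <- function(runs) {
    if (!nrow(runs)) .stopf("no runs")
    fit <- survival::survfit(
        survival::Surv(runs$n_sampled, !runs$censored) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               n_censor = fit$n.censor, surv = fit$surv) |>
        structure(survfit = fit)
}

#' @rdname kmCurve
#' @details \code{kmMeanDuration} is the restricted mean survival time
#'   (area under the KM curve up to the largest observed duration), which
#'   for integer durations equals the expected duration when follow-up is
#'   complete.
#' @export
kmMeanDuration <- function(runs) {
    fit <- attr(kmCurve(runs), "survfit")
    tab <- summary(fit, rmean = max(fit$time))$table
    unname(tab["rmean"])
}

#' k-sample log-rank test on run durations
#'
#' @param runs data.frame of runs
#' @param group grouping vector parallel to rows of \code{runs} (e.g.
#'   condition), or the name of a column of \code{runs}
#' @return list (statistic, df, p)
#' @export
logrankTest <- function(runs, group) {
    if (is.character(group) && length(group) == 1L) group <- runs[[group]]
    g <- factor(group)
    if (nlevels(g) < 2) .stopf("need >= 2 groups")
    sd <- survival::survdiff(
        survival::Surv(runs$n_sampled, !runs$censored) ~ g)
    df <- length(sd$n) - 1L
    list(statistic = unname(sd$chisq), df = df,
         p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}
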