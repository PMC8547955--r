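#' Significance stars for a p-value
#'
#' The star convention used in the figure legends: **** p < 0.0001,
#' *** p < 0.001, ** p < 0.01, * p < 0.05, "ns" otherwise.
#'
#' @param p p-value(s).
#' @return character vector of star codes.
#' @export
significanceStars <- function(p) {
    cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
        labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

newTestResult <- function(procedure, statistic, df, p, pairwise = NULL,
                          note = NULL) {
    structure(list(procedure = procedure, statistic = statistic, df = df,
                   p_value = p, stars = significanceStars(p),
                   pairwise = pairwise, note = note),
              class = "testResult")
}

#' @export
print.testResult <- function(x, ...) {
    cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g (%s)\n",
        x$procedure, x$statistic, x$df, x$p_value, x$stars))
    if (!is.null(x$pairwise)) {
        cat("pairwise (Tukey-adjusted):\n")
        print(x$pairwise, row.names = FALSE)
    }
    invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Welch's unequal-variance form by default (the robust choice when group
#' variances differ, as stiffness and intensity cohorts typically do);
#' Student's equal-variance form on request. The chosen form is recorded in
#' the result. Two groups with zero variance and equal means return
#' statistic 0, p = 1; zero variance with unequal means has no defined
#' degrees of freedom and is rejected.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param equalVariance use the Student pooled-variance form (default FALSE,
#'   i.e. Welch).
#' @return a \code{"testResult"} list: \code{statistic} (t),
#'   \code{df}, \code{p_value}, \code{stars}, \code{procedure}.
#' @examples
#' unpairedTTest(c(10, 11, 12), c(13, 14, 15))
#' @export
unpairedTTest <- function(a, b, equalVariance = FALSE) {
    if (length(a) < 2L || length(b) < 2L)
        stop("both groups need n >= 2")
    proc <- if (equalVariance) "Student t-test (unpaired)" else
        "Welch t-test (unpaired, unequal variance)"
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) return(newTestResult(proc, 0, NA_real_, 1,
            note = "degenerate: zero variance in both groups"))
        stop("undefined degrees of freedom: zero variance in both groups with unequal means")
    }
    tt <- stats::t.test(a, b, var.equal = equalVariance)
    newTestResult(proc, unname(tt$statistic), unname(tt$parameter),
                  tt$p.value)
}

#' One-way ANOVA with Tukey's multiple-comparison procedure
#'
#' Omnibus one-way ANOVA across three or more groups followed by Tukey's
#' honestly-significant-difference adjusted p-values for every pair
#' (studentized-range distribution).
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 2).
#' @return a \code{"testResult"}: \code{statistic} (F), \code{df}
#'   (numerator), \code{p_value} (omnibus), and \code{pairwise} data.frame
#'   (\code{group_a}, \code{group_b}, \code{diff}, \code{p_adj},
#'   \code{stars}).
#' @export
anovaTukey <- function(groups) {
    if (is.null(names(groups)) || any(names(groups) == ""))
        names(groups) <- paste0("group", seq_along(groups))
    if (length(groups) < 3L)
        stop("fewer than 3 groups: use unpairedTTest() for two-group comparisons")
    if (any(vapply(groups, length, 1L) < 2L))
        stop("every group needs n >= 2")
    df <- data.frame(
        value = unlist(groups, use.names = FALSE),
        group = factor(rep(names(groups), vapply(groups, length, 1L)),
                       levels = names(groups)))
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1L]]
    fstat <- an[["F value"]][1L]
    pval <- an[["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)$group
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pw <- data.frame(group_a = pairs[, 1L], group_b = pairs[, 2L],
                     diff = tk[, "diff"], p_adj = tk[, "p adj"],
                     stars = significanceStars(tk[, "p adj"]),
                     row.names = NULL)
    newTestResult("one-way ANOVA with Tukey HSD", fstat,
                  an[["Df"]][1L], pval, pairwise = pw)
}

#' Group summary: mean, sample SD, n
#'
#' @param values numeric vector (n >= 1).
#' @return list: \code{mean}, \code{sd} (sample, n-1 denominator; \code{NA}
#'   when n = 1), \code{n}.
#' @export
summarizeGroup <- function(values) {
    if (length(values) == 0L) stop("empty group")
    list(mean = mean(values),
         sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
         n = length(values))
}

#' Compare measurement groups from a tidy table
#'
#' Dispatches to \code{\link{unpairedTTest}} for two groups and
#' \code{\link{anovaTukey}} for three or more, and returns a tidy comparison
#' table of the kind written next to each figure panel.
#'
#' @param data data.frame with columns \code{group} and \code{value}.
#' @param equalVariance passed to the two-group test.
#' @return data.frame: \code{group_a}, \code{group_b}, \code{procedure},
#'   \code{statistic}, \code{df}, \code{p}, \code{stars}.
#' @export
compareGroups <- function(data, equalVariance = FALSE) {
    stopifnot(all(c("group", "value") %in% names(data)))
    groups <- split(data$value, factor(data$group, levels = unique(data$group)))
    if (length(groups) < 2L) stop("need at least 2 groups")
    if (length(groups) == 2L) {
        r <- unpairedTTest(groups[[1L]], groups[[2L]], equalVariance)
        data.frame(group_a = names(groups)[1L], group_b = names(groups)[2L],
                   procedure = r$procedure, statistic = r$statistic,
                   df = r$df, p = r$p_value, stars = r$stars)
    } else {
        r <- anovaTukey(groups)
        data.frame(group_a = r$pairwise$group_a, group_b = r$pairwise$group_b,
                   procedure = r$procedure, statistic = r$statistic,
                   df = r$df, p = r$pairwise$p_adj, stars = r$pairwise$stars)
    }
}
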