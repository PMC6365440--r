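# Co-transfer counting statistics: per-islet normalization, treated:control
# ratio tests against a hypothetical value of 1, percent impairment from
# group means, paired / pooled-variance two-sample t tests, and the >= 90%
# CD11c-depletion inclusion filter.

#' Normalize islet counts to cells per islet
#'
#' Islet rows are divided by the number of islets harvested from that mouse;
#' all other tissues pass through unchanged.
#'
#' @param counts a TraffickingCounts data.frame (see
#'   [generateTraffickingCounts()]).
#' @return the table with a \code{norm_count} column (cells, or cells per
#'   islet for islet rows).
#' @export
normalizePerIslet <- function(counts) {
    stopifnot(all(c("tissue", "count") %in% names(counts)))
    isl <- counts$tissue == "islets"
    if (any(isl & (is.na(counts$n_islets) | counts$n_islets == 0)))
        stop("islet rows must carry a positive n_islets")
    counts$norm_count <- counts$count
    counts$norm_count[isl] <- counts$count[isl] / counts$n_islets[isl]
    counts
}

#' One-sample ratio test of treated:control homing
#'
#' Forms the per-mouse ratio of treated to control counts for one population
#' and tissue, then tests the mean ratio against the hypothetical value 1
#' with a two-sided one-sample t test on the raw ratio scale (t =
#' (mean - 1) / (sd / sqrt(n))). Pairs with a zero control count are
#' excluded with a warning; a zero-variance ratio vector is reported as
#' degenerate instead of producing an infinite t.
#'
#' @param counts TraffickingCounts (paired design).
#' @param population population label to test.
#' @param tissue tissue label to test.
#' @param conditionPair length-2: treated then control condition labels.
#' @param log_scale test log ratios against 0 instead (off by default: the
#'   plotted quantity is the raw ratio).
#' @return list: \code{ratios} (per mouse), \code{mean_ratio}, \code{t},
#'   \code{df}, \code{p_value}, \code{hypothetical} (1), \code{degenerate}.
#' @export
ratioTest <- function(counts, population, tissue,
                      conditionPair = c("treated", "control"),
                      log_scale = FALSE) {
    sub <- counts[counts$population == population & counts$tissue == tissue, ,
                  drop = FALSE]
    if (!nrow(sub)) stop("no rows for population/tissue")
    tr <- sub[sub$condition == conditionPair[1L], ]
    ct <- sub[sub$condition == conditionPair[2L], ]
    m <- merge(tr[, c("mouse_id", "count")], ct[, c("mouse_id", "count")],
               by = "mouse_id", suffixes = c("_treated", "_control"))
    zero <- m$count_control == 0
    if (any(zero)) {
        warning(sum(zero), " pair(s) with zero control count excluded")
        m <- m[!zero, , drop = FALSE]
    }
    if (nrow(m) < 2L) stop("need >= 2 complete pairs for the ratio test")
    ratios <- m$count_treated / m$count_control
    x <- if (log_scale) log(ratios) else ratios
    mu0 <- if (log_scale) 0 else 1
    if (stats::sd(x) == 0) {
        # sd = 0: t is 0/0 when the mean sits at the hypothetical value
        # (report t = 0, p = 1), +-Inf otherwise (flagged, no finite t)
        atNull <- mean(x) == mu0
        return(list(ratios = ratios, mean_ratio = mean(ratios),
                    t = if (atNull) 0 else NA_real_,
                    df = length(x) - 1L,
                    p_value = if (atNull) 1 else NA_real_,
                    hypothetical = 1, degenerate = !atNull))
    }
    tt <- stats::t.test(x, mu = mu0)
    list(ratios = ratios, mean_ratio = mean(ratios),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, hypothetical = 1, degenerate = FALSE)
}

#' Percent impairment of homing from group means
#'
#' impairment = (1 - mean_treated / mean_control) * 100, computed on
#' per-islet-normalized counts for islet rows. Group means (not the mean of
#' per-mouse impairments) give the single headline percentage; a per-mouse
#' variant is available.
#'
#' @param counts TraffickingCounts.
#' @param population population label.
#' @param tissue tissue label.
#' @param conditionPair length-2: treated/depleted then control/intact.
#' @param per_mouse also return per-mouse impairments (paired designs).
#' @return list: \code{impairment_pct}, \code{mean_treated},
#'   \code{mean_control}, \code{n_treated}, \code{n_control}, and optionally
#'   \code{per_mouse_pct}.
#' @export
percentImpairment <- function(counts, population, tissue,
                              conditionPair = c("treated", "control"),
                              per_mouse = FALSE) {
    counts <- normalizePerIslet(counts)
    sub <- counts[counts$population == population & counts$tissue == tissue, ,
                  drop = FALSE]
    a <- sub$norm_count[sub$condition == conditionPair[1L]]
    b <- sub$norm_count[sub$condition == conditionPair[2L]]
    if (!length(a) || !length(b)) stop("both condition groups must be non-empty")
    if (mean(b) == 0) stop("control mean is zero; impairment undefined")
    out <- list(impairment_pct = (1 - mean(a) / mean(b)) * 100,
                mean_treated = mean(a), mean_control = mean(b),
                n_treated = length(a), n_control = length(b))
    if (per_mouse && length(a) == length(b))
        out$per_mouse_pct <- (1 - a / b) * 100
    out
}

#' Paired or pooled-variance two-sample t test
#'
#' Classical Student t tests as used for co-transfer comparisons: paired
#' when both measurements come from the same mouse, otherwise a pooled-
#' variance two-sample test (Welch by flag). Identical inputs give the
#' degenerate sd = 0 case, reported with t = 0 and p = 1.
#'
#' @param a,b numeric vectors (equal length when \code{paired}).
#' @param paired logical.
#' @param welch use Welch's unequal-variance form instead of pooled.
#' @return list: \code{t}, \code{df}, \code{p_value}, \code{degenerate}.
#' @export
groupTest <- function(a, b, paired = FALSE, welch = FALSE) {
    if (paired && length(a) != length(b))
        stop("paired test needs equal-length vectors")
    if (length(a) < 2L || length(b) < 2L)
        stop("need n >= 2 per group")
    degenerate <- if (paired) stats::sd(a - b) == 0
                  else stats::sd(c(a - mean(a), b - mean(b))) == 0
    if (degenerate)
        return(list(t = 0, df = if (paired) length(a) - 1L
                    else length(a) + length(b) - 2L,
                    p_value = 1, degenerate = TRUE))
    tt <- stats::t.test(a, b, paired = paired, var.equal = !welch)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, degenerate = FALSE)
}

#' CD11c depletion inclusion filter
#'
#' A depleted mouse is included only when at least 90% of islet CD11c+ cells
#' are gone: depleted count <= 0.10 x control mean (boundary inclusive).
#'
#' @param depletedCounts numeric islet CD11c counts in depleted mice.
#' @param controlMean mean islet CD11c count in intact controls (> 0).
#' @param minDepletion required depletion fraction (default 0.9).
#' @return logical vector, TRUE = include.
#' @export
depletionFilter <- function(depletedCounts, controlMean, minDepletion = 0.9) {
    if (controlMean <= 0) stop("control mean must be positive")
    # boundary inclusive: exactly 90% depletion passes
    (controlMean - depletedCounts) / controlMean >= minDepletion - 1e-12
}
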