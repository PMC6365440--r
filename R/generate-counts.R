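#' Simulate co-transfer trafficking count tables
#'
#' Emulates the co-transfer design: differentially labeled treated and
#' control populations recovered from each tissue by flow cytometry. In a
#' paired design both populations are counted in the same mouse; in a
#' two-arm design (e.g. depleted vs intact hosts) each arm has its own mice
#' and every arm receives every population. Counts are Poisson (or
#' negative-binomial) around \code{baseline_rate[tissue] *
#' effect_multiplier[population, tissue]}.
#'
#' @param preset a [countsPreset()] bundle.
#' @return data.frame of class \code{TraffickingCounts}: \code{mouse_id},
#'   \code{tissue}, \code{population}, \code{condition} (\code{treated} /
#'   \code{control} for paired designs, \code{depleted} / \code{intact} for
#'   two-arm), \code{count}, \code{n_islets} (NA outside islet rows).
#' @export
generateTraffickingCounts <- function(preset) {
    stopifnot(inherits(preset, "CountsPreset"))
    withr::with_seed(preset$seed, .generateCountsImpl(preset))
}

.generateCountsImpl <- function(preset) {
    pops <- rownames(preset$effect_multiplier)
    tissues <- preset$tissues
    if (preset$design == "paired") {
        grid <- expand.grid(condition = c("treated", "control"),
                            population = pops, tissue = tissues,
                            mouse_id = seq_len(preset$n_mice),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        eff <- ifelse(grid$condition == "treated",
                      preset$effect_multiplier[cbind(grid$population,
                                                     grid$tissue)], 1)
    } else {
        grid <- expand.grid(population = pops, tissue = tissues,
                            mouse_id = seq_len(preset$n_mice),
                            condition = c("depleted", "intact"),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        grid$mouse_id <- paste0(grid$condition, "_", grid$mouse_id)
        eff <- ifelse(grid$condition == "depleted",
                      preset$effect_multiplier[cbind(grid$population,
                                                     grid$tissue)], 1)
    }
    mu <- pmax(preset$baseline_rate[grid$tissue] * eff, 0)
    grid$count <- if (preset$noise_family == "poisson")
        stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = preset$dispersion)
    grid$n_islets <- ifelse(grid$tissue == "islets",
                            preset$n_islets_per_mouse, NA_integer_)
    out <- grid[, c("mouse_id", "tissue", "population", "condition",
                    "count", "n_islets")]
    rownames(out) <- NULL
    class(out) <- c("TraffickingCounts", "data.frame")
    out
}
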