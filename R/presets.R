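# Parameter presets for the synthetic-data generator. Each preset bundle is a
# validated named list; the named presets encode the study conditions the
# downstream analyses are checked against (imaging geometry at 0.994 um/pixel
# in xy and 3 um z steps; contact-zone coverage 18.7% of the vascular
# surface; 86.6% of intravascular T cells in zone and 75.0% in direct CD11c
# contact; a 90%-extravascular 24-h snapshot; median release 43 min and
# median extravasation 63 min; chemokine-blockade and CD11c-depletion homing
# effects; the islet chemokine ligand/receptor expression pattern).

#' Geometry preset for islet phantom generation
#'
#' @param name one of \code{"fig2_geometry"} (advanced-infiltration islet with
#'   target contact-zone coverage 18.7\%, 86.6\% of intravascular T cells in
#'   zone, 75.0\% in direct contact) or \code{"suppl1_snapshot"} (24-h
#'   post-transfer snapshot with 90\% of T cells extravascular).
#' @param ... named overrides of individual fields.
#' @return validated list of class \code{GeometryPreset} with fields
#'   \code{islet_radius}, \code{vessel_segments}, \code{vessel_radius},
#'   \code{cd11c_count}, \code{cd11c_radius}, \code{target_zone_fraction},
#'   \code{p_in_zone}, \code{p_direct_contact} (conditional on in-zone),
#'   \code{frac_extravascular}, \code{infiltration_fraction},
#'   \code{tcell_radius}, \code{spacing}, \code{seed}.
#' @export
geometryPreset <- function(name = c("fig2_geometry", "suppl1_snapshot"), ...) {
    name <- match.arg(name)
    p <- list(
        islet_radius = 55, vessel_segments = 7L, vessel_radius = 13,
        cd11c_count = 150L, cd11c_radius = 6,
        target_zone_fraction = 0.187,
        p_in_zone = 0.866,
        p_direct_contact = 0.750 / 0.866,
        frac_extravascular = 0.35,
        infiltration_fraction = 0.045,
        tcell_radius = 4,
        spacing = c(0.994, 0.994, 3.0),
        seed = 1L,
        name = name)
    if (name == "suppl1_snapshot") {
        p$frac_extravascular <- 0.90
        p$infiltration_fraction <- 0.077
    }
    p <- utils::modifyList(p, list(...))
    validateGeometryPreset(p)
    structure(p, class = c("GeometryPreset", "list"))
}

validateGeometryPreset <- function(p) {
    fr <- c(p$target_zone_fraction, p$p_in_zone, p$p_direct_contact,
            p$frac_extravascular, p$infiltration_fraction)
    if (any(fr < 0 | fr > 1))
        stop("all fractions/probabilities must lie in [0, 1]")
    if (length(p$spacing) != 3L || any(p$spacing <= 0))
        stop("spacing must be 3 strictly positive numbers (um/voxel)")
    if (p$islet_radius <= p$vessel_radius + p$cd11c_radius)
        stop("islet radius too small for the vessel and CD11c geometry")
    invisible(TRUE)
}

#' Kinetics preset for track generation
#'
#' @param name \code{"fig1_kinetics"} (advanced-infiltration islet: release
#'   and completed extravasation both occur, with median waiting times 43 and
#'   63 min from arrest) or \code{"fig1_kinetics_mild"} (mild infiltration:
#'   completed extravasation is never observed, \code{p_extravasate = 0}).
#' @param ... named overrides.
#' @return validated list of class \code{KineticsPreset} with fields
#'   \code{p_release}, \code{p_extravasate}, \code{median_release_time},
#'   \code{median_extravasation_time}, \code{waiting_time_family},
#'   \code{sigma_log}, \code{frame_interval} (s), \code{duration} (min),
#'   \code{frac_left_censored}, \code{seed}. The remainder
#'   \code{1 - p_release - p_extravasate} stays arrested.
#' @export
kineticsPreset <- function(name = c("fig1_kinetics", "fig1_kinetics_mild"),
                           ...) {
    name <- match.arg(name)
    p <- list(
        p_release = 0.5, p_extravasate = 0.3,
        median_release_time = 43, median_extravasation_time = 63,
        waiting_time_family = "lognormal", sigma_log = 0.5,
        frame_interval = 20, duration = 120,
        frac_left_censored = 0.5,
        infiltration = "advanced",
        seed = 7L, name = name)
    if (name == "fig1_kinetics_mild") {
        p$p_release <- 0.6
        p$p_extravasate <- 0
        p$infiltration <- "mild"
    }
    p <- utils::modifyList(p, list(...))
    if (p$p_release + p$p_extravasate > 1)
        stop("p_release + p_extravasate must be <= 1")
    if (p$median_release_time <= 0 || p$median_extravasation_time <= 0)
        stop("median waiting times must be positive")
    if (p$duration * 60 < p$frame_interval)
        stop("duration must cover at least one frame interval")
    structure(p, class = c("KineticsPreset", "list"))
}

#' Counts preset for co-transfer trafficking simulations
#'
#' Encodes a co-transfer design: per mouse and tissue, a treated/KO/depleted
#' population and its control, with multiplicative homing effects on a
#' Poisson (or negative-binomial) baseline.
#'
#' @param name \code{"ptx_effect"} (chemokine-receptor blockade of
#'   co-transferred CD4/CD8 T cells: islet multipliers 0.044 and 0.087 for a
#'   95.6\%/91.3\% trafficking impairment, lymph-node impairment, blood
#'   enrichment; paired within mouse), \code{"cd11c_depletion"} (depleted vs
#'   intact host arms: islet multipliers CD8 0.08/0.09, CD4 0.25/0.23 for
#'   ex vivo/activated cells and B cells 0.08; lymph nodes unaffected), or
#'   \code{"null_effect"} (all multipliers 1).
#' @param ... named overrides.
#' @return validated list of class \code{CountsPreset}: \code{n_mice} (per
#'   arm for two-arm designs), \code{tissues}, \code{baseline_rate} (named by
#'   tissue, expected control cells recovered), \code{effect_multiplier}
#'   (population x tissue matrix), \code{n_islets_per_mouse},
#'   \code{noise_family} ("poisson" or "nbinom"), \code{dispersion},
#'   \code{design} ("paired" or "two_arm"), \code{seed}.
#' @export
countsPreset <- function(name = c("ptx_effect", "cd11c_depletion",
                                  "null_effect"), ...) {
    name <- match.arg(name)
    tissues <- c("ILN", "PLN", "blood", "islets")
    baseline <- c(ILN = 2000, PLN = 2500, blood = 1500, islets = 400)
    if (name == "ptx_effect") {
        eff <- rbind(
            CD4 = c(ILN = 0.30, PLN = 0.30, blood = 2.0, islets = 0.044),
            CD8 = c(ILN = 0.35, PLN = 0.35, blood = 2.0, islets = 0.087))
        design <- "paired"; n_mice <- 7L
    } else if (name == "cd11c_depletion") {
        eff <- rbind(
            CD8_exvivo    = c(ILN = 1, PLN = 1, blood = 1, islets = 0.08),
            CD8_activated = c(ILN = 1, PLN = 1, blood = 1, islets = 0.09),
            CD4_exvivo    = c(ILN = 1, PLN = 1, blood = 1, islets = 0.25),
            CD4_activated = c(ILN = 1, PLN = 1, blood = 1, islets = 0.23),
            B             = c(ILN = 1, PLN = 1, blood = 1, islets = 0.08))
        design <- "two_arm"; n_mice <- 10L
    } else {
        eff <- rbind(
            CD4 = c(ILN = 1, PLN = 1, blood = 1, islets = 1),
            CD8 = c(ILN = 1, PLN = 1, blood = 1, islets = 1))
        design <- "paired"; n_mice <- 7L
    }
    p <- list(n_mice = n_mice, tissues = tissues, baseline_rate = baseline,
              effect_multiplier = eff, n_islets_per_mouse = 25L,
              noise_family = "poisson", dispersion = 10,
              design = design, seed = 3L, name = name)
    p <- utils::modifyList(p, list(...))
    if (any(p$baseline_rate < 0) || any(p$effect_multiplier < 0))
        stop("rates and multipliers must be non-negative")
    if (p$n_mice < 2L) stop("n_mice must be >= 2 for paired tests")
    structure(p, class = c("CountsPreset", "list"))
}

# Negative-binomial mean profiles for the islet expression preset. Ligand
# means for the CD11c population put Cxcl9 first and Cxcl16 third with 22
# ligands well above the default expressed threshold (robust to +-5x);
# receptor means for the T-cell population put Cxcr6 first and Cxcr3 second.
fig5MeanProfiles <- function() {
    lig_cd11c <- c(
        Cxcl9 = 3000, Cxcl10 = 2200, Cxcl16 = 1600,
        Ccl5 = 1200, Ccl2 = 950, Ccl4 = 800, Ccl3 = 680, Ccl8 = 560,
        Ccl12 = 470, Cxcl11 = 390, Ccl7 = 320, Ccl6 = 270, Cxcl12 = 230,
        Ccl9 = 190, Cxcl13 = 160, Ccl22 = 130, Cxcl1 = 110, Ccl19 = 95,
        Cx3cl1 = 85, Ccl17 = 75, Cxcl2 = 65, Xcl1 = 60,
        Ccl11 = 0.5, Ccl20 = 0.5, Ccl21 = 0.5, Ccl24 = 0.5, Ccl25 = 0.5,
        Ccl27 = 0.5, Ccl28 = 0.5, Cxcl3 = 0.5, Cxcl5 = 0.5)
    rec_tcell <- c(
        Cxcr6 = 2500, Cxcr3 = 1800, Ccr5 = 900, Ccr2 = 600, Ccr7 = 500,
        Cxcr4 = 450, Ccr1 = 300, Ccr4 = 150, Cxcr5 = 90, Cx3cr1 = 60,
        Ccr6 = 50, Ccr8 = 40, Ccr9 = 30, Ccr10 = 20, Ccr3 = 15, Xcr1 = 5)
    hk <- paste0("Hk", sprintf("%02d", 1:30))
    hk_mean <- round(exp(seq(log(200), log(5000), length.out = 30)))
    names(hk_mean) <- hk
    list(ligand_cd11c = lig_cd11c, receptor_tcell = rec_tcell,
         housekeeping = hk_mean)
}

#' Expression preset for islet CD11c / T-cell count matrices
#'
#' @param name currently \code{"fig5_expression"}: a gene panel of murine
#'   chemokine ligands, their receptors and housekeeping genes, with
#'   negative-binomial means placing Cxcl9 first and Cxcl16 third among
#'   CD11c-expressed ligands (22 ligands above the expressed threshold) and
#'   Cxcr6 first among T-cell receptors.
#' @param ... named overrides.
#' @return validated list of class \code{ExpressionPreset}: \code{gene_panel},
#'   \code{mean_counts} (gene x population matrix, populations CD11c and
#'   Tcell), \code{dispersion} (per gene), \code{n_samples_per_population},
#'   \code{library_size_range}, \code{seed}.
#' @export
expressionPreset <- function(name = "fig5_expression", ...) {
    name <- match.arg(name)
    prof <- fig5MeanProfiles()
    pairing <- chemokinePairingMap()
    ligands <- names(prof$ligand_cd11c)
    receptors <- names(prof$receptor_tcell)
    genes <- c(ligands, receptors, names(prof$housekeeping))
    mu <- matrix(0, length(genes), 2,
                 dimnames = list(genes, c("CD11c", "Tcell")))
    mu[ligands, "CD11c"] <- prof$ligand_cd11c
    mu[ligands, "Tcell"] <- 2           # T cells barely transcribe ligands
    mu[receptors, "CD11c"] <- 5         # low receptor signal on CD11c
    mu[receptors, "Tcell"] <- prof$receptor_tcell
    mu[names(prof$housekeeping), ] <- cbind(prof$housekeeping,
                                            prof$housekeeping)
    p <- list(gene_panel = genes, mean_counts = mu,
              dispersion = stats::setNames(rep(0.1, length(genes)), genes),
              n_samples_per_population = 4L,
              library_size_range = c(0.7, 1.4),
              seed = 11L, name = name)
    p <- utils::modifyList(p, list(...))
    if (any(p$mean_counts < 0)) stop("negative-binomial means must be >= 0")
    if (any(p$dispersion <= 0)) stop("dispersions must be > 0")
    looks_ligand <- grepl("^(Ccl|Cxcl|Cx3cl|Xcl)[0-9]+$", p$gene_panel)
    missing <- setdiff(p$gene_panel[looks_ligand], pairing$ligand)
    if (length(missing))
        stop("ligand(s) without receptor in pairing map: ",
             paste(missing, collapse = ", "))
    structure(p, class = c("ExpressionPreset", "list"))
}
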