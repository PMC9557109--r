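#' Pre- and post-silking dry matter accumulation
#'
#' Splits total aboveground dry matter accumulation (DMA) at the silking
#' boundary:
#' \describe{
#'   \item{PrSDMAR}{pre-silking DMA ratio, `100 * DMA(R1) / DMA(R6)` (%)}
#'   \item{PoSDMA}{post-silking DMA, `DMA(R6) - DMA(R1)` (g plant^-1)}
#'   \item{PoSDMAR}{post-silking DMA ratio, `100 * PoSDMA / DMA(R6)` (%)}
#' }
#' PrSDMAR + PoSDMAR = 100 by construction. A plant that lost mass after
#' silking (`dma_r1 > dma_r6`) gives a negative PoSDMA; this is flagged with
#' a warning, not rejected.
#'
#' @param dma_r1 Total aboveground DMA at silking (g plant^-1), > 0.
#' @param dma_r6 Total aboveground DMA at physiological maturity (g plant^-1).
#' @return List with `prsdmar`, `posdma`, `posdmar`.
#' @export
pre_post_silking <- function(dma_r1, dma_r6) {
  if (any(dma_r1 <= 0) || any(dma_r6 <= 0)) stop("dry matter must be positive")
  if (any(dma_r1 > dma_r6)) warning("DMA at R1 exceeds DMA at R6: negative post-silking accumulation")
  list(prsdmar = 100 * dma_r1 / dma_r6,
       posdma = dma_r6 - dma_r1,
       posdmar = 100 * (dma_r6 - dma_r1) / dma_r6)
}

#' Average crop growth rate over an interval
#'
#' @param dma_start,dma_end Total DMA at the interval boundaries (g plant^-1).
#' @param days Interval length (d), > 0.
#' @return Growth rate (g plant^-1 d^-1).
#' @export
crop_growth_rate <- function(dma_start, dma_end, days) {
  if (any(days <= 0)) stop("days must be positive")
  (dma_end - dma_start) / days
}

#' Dry matter remobilization and remobilization efficiency of an organ
#'
#' DMR is the organ's dry-mass loss from silking to maturity,
#' `mass(R1) - mass(R6)`; DMRE expresses it as a percentage of the organ's
#' mass at silking. An organ that gained mass gives a negative DMR — retained
#' and reported, since apparent remobilization can be negative, but floored
#' at zero downstream in [dmr_to_grain()].
#'
#' @param organ_r1 Organ dry mass at R1 (g plant^-1), > 0.
#' @param organ_r6 Organ dry mass at R6 (g plant^-1).
#' @return List with `dmr` (g) and `dmre` (%).
#' @export
dmr_and_dmre <- function(organ_r1, organ_r6) {
  if (any(organ_r1 <= 0)) stop("organ mass at R1 must be positive")
  dmr <- organ_r1 - organ_r6
  list(dmr = dmr, dmre = 100 * dmr / organ_r1)
}

#' Carbon-13 tracer distribution across organs
#'
#' For plants pulse-labeled with 13CO2 at silking and harvested at maturity,
#' computes the fraction of recovered tracer in each organ. Per organ, the
#' tracer-mass proxy is
#' `(mean labeled atom-% - mean reference atom-%)/100 x organ dry mass`,
#' assuming a constant carbon fraction across organs. Negative excesses
#' (sampling noise) are floored at zero before normalizing.
#'
#' @param organ Character vector of organ labels per sample
#'   (`"stalk"`, `"leaf"`, `"grain"`, `"other"`).
#' @param labeled Logical vector: `TRUE` for labeled plants, `FALSE` for the
#'   unlabeled reference cohort.
#' @param mass_g Organ dry mass per sample (g). Masses of the labeled cohort
#'   are used for the tracer bookkeeping.
#' @param atom_pct 13C abundance (atom-%), in (0, 100).
#' @return List with `fraction` (named numeric summing to 1 over organs) and
#'   `excess_g` (named tracer-mass proxy per organ, g).
#' @export
c13_distribution <- function(organ, labeled, mass_g, atom_pct) {
  stopifnot(length(organ) == length(labeled),
            length(organ) == length(mass_g),
            length(organ) == length(atom_pct))
  if (!any(labeled)) stop("no labeled plants")
  if (all(labeled)) stop("no reference plants")
  if (any(atom_pct <= 0 | atom_pct >= 100)) stop("atom-% must lie in (0, 100)")
  organs <- unique(organ[labeled])
  excess <- vapply(organs, function(o) {
    lab <- labeled & organ == o
    ref <- !labeled & organ == o
    if (!any(ref)) stop("no reference plants for organ '", o, "'")
    d <- mean(atom_pct[lab]) - mean(atom_pct[ref])
    max(0, d / 100) * mean(mass_g[lab])
  }, numeric(1))
  total <- sum(excess)
  if (total <= 0) stop("labeling failure: no positive 13C excess in any organ")
  list(fraction = excess / total, excess_g = excess)
}

#' Remobilized dry matter delivered to grain
#'
#' Vegetative remobilization corrected by the tracer evidence: the summed
#' leaf and stalk DMR (each floored at zero — mass flow to grain cannot be
#' negative) multiplied by the fraction of 13C recovered in grain.
#'
#' @param dmr_leaf,dmr_stalk Leaf and stalk DMR (g plant^-1); negative values
#'   (organ gain) contribute zero.
#' @param grain_fraction Fraction of tracer recovered in grain, in \[0, 1\].
#' @return Remobilized mass reaching grain (g plant^-1).
#' @export
dmr_to_grain <- function(dmr_leaf, dmr_stalk, grain_fraction) {
  if (any(grain_fraction < 0 | grain_fraction > 1)) stop("grain_fraction must lie in [0, 1]")
  (pmax(dmr_leaf, 0) + pmax(dmr_stalk, 0)) * grain_fraction
}

#' Remobilization contribution to grain dry matter
#'
#' DMRC: remobilized leaf-plus-stalk mass reaching grain as a percentage of
#' grain DMA at maturity. Its complement, `100 - DMRC`, is the contribution
#' of post-silking assimilation.
#'
#' @param dmr_to_grain Remobilized mass reaching grain (g plant^-1).
#' @param grain_dma_r6 Grain DMA at R6 (g plant^-1), > 0.
#' @return DMRC (%).
#' @export
dmrc <- function(dmr_to_grain, grain_dma_r6) {
  if (any(grain_dma_r6 <= 0)) stop("grain DMA must be positive")
  100 * dmr_to_grain / grain_dma_r6
}

#' Harvest index
#'
#' Grain dry matter as a fraction of total aboveground dry matter at
#' physiological maturity.
#'
#' @param grain_dma Grain DMA at R6 (g plant^-1), > 0.
#' @param total_dma Total aboveground DMA at R6 (g plant^-1), >= grain.
#' @return HI as a fraction in (0, 1].
#' @export
harvest_index <- function(grain_dma, total_dma) {
  if (any(grain_dma <= 0)) stop("grain DMA must be positive")
  if (any(grain_dma > total_dma)) stop("grain DMA exceeds total DMA")
  grain_dma / total_dma
}

#' Sink capacity of the grain population
#'
#' `ears m^-2 x grains per ear x single-grain weight (g)`. Note the grain
#' weight is per kernel: thousand-grain weight divided by 1000.
#'
#' @param ears_per_m2 Harvest ear density (m^-2).
#' @param grains_per_ear Kernels per ear.
#' @param grain_weight_g Single-kernel weight (g), i.e. TGW/1000.
#' @return Sink capacity (g m^-2).
#' @export
sink_capacity <- function(ears_per_m2, grains_per_ear, grain_weight_g) {
  if (any(ears_per_m2 <= 0) || any(grains_per_ear <= 0) || any(grain_weight_g <= 0))
    stop("all sink components must be positive")
  ears_per_m2 * grains_per_ear * grain_weight_g
}

#' Grain/leaf ratio
#'
#' Sink capacity per unit leaf area at silking, in kg m^-2 — a source-sink
#' balance indicator (values above ~0.25 kg m^-2 indicate a non-limiting
#' source for current maize populations).
#'
#' @param sink_g_m2 Sink capacity (g m^-2).
#' @param la_r1 Leaf area index at R1 (m^2 leaf m^-2 ground), > 0.
#' @return Grain/leaf ratio (kg m^-2).
#' @export
grain_leaf_ratio <- function(sink_g_m2, la_r1) {
  if (any(la_r1 <= 0)) stop("leaf area at R1 must be positive")
  sink_g_m2 / 1000 / la_r1
}

#' Standardize grain yield to 14% moisture
#'
#' @param fresh_kg_ha Fresh grain mass (kg ha^-1).
#' @param moisture Grain moisture fraction at weighing, in \[0, 0.4).
#' @return Yield (kg ha^-1) at the 14% moisture standard.
#' @export
standardize_yield <- function(fresh_kg_ha, moisture) {
  if (any(moisture < 0 | moisture >= 0.4)) stop("moisture must lie in [0, 0.4)")
  fresh_kg_ha * (1 - moisture) / (1 - 0.14)
}
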