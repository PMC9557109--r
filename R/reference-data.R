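#' Published summary tables from a five-year maize hybrid trial
#'
#' Per-year x hybrid summary tables from a published 2017-2021 field trial
#' in Shandong, China, comparing the early-maturity summer maize hybrid
#' Denghai 518 (DH518) with the mid-late hybrid Denghai 605 (DH605) at
#' 75,000 plants ha^-1. The raw plot data were not deposited; these are the
#' printed treatment means, shipped so that every cross-table derived
#' quantity (percent-difference ranges, DLAI and APD closed forms,
#' correlation of harvest index with pre-silking duration) can be recomputed
#' from them.
#'
#' @return Named list of data frames:
#' \describe{
#'   \item{yield}{grains per ear, 1000-grain weight (g), harvest ears
#'     (10^4 ha^-1), grain yield (kg ha^-1 at 14% moisture)}
#'   \item{stage_gdd}{days and accumulated GDD (degC d) before/after silking
#'     and totals}
#'   \item{remobilization}{DMR (g) and DMRE (%) of stalk and leaf}
#'   \item{dmrc}{DMR of leaf + stalk to grain (g), DMRC (%), yield per GDD
#'     (kg ha^-1 (degC d)^-1); four labeled years only}
#'   \item{pn_fits}{linear Pn decline: intercept `a`, decline rate `b`,
#'     correlation `r`, initial rate `Pi`, APD (d)}
#'   \item{gaussian_fits}{Gaussian LAI parameters `A`, `B`, `C`,
#'     determination coefficient `R`, DLAI (d)}
#'   \item{grain_leaf_hi}{grain/leaf ratio (kg m^-2) and harvest index}
#' }
#' @export
reference_tables <- function() {
  yrs <- rep(2017:2021, each = 2)
  hyb <- rep(c("DH518", "DH605"), 5)
  list(
    yield = data.frame(
      year = yrs, hybrid = hyb,
      grains_per_ear = c(497, 487, 495, 514, 521, 570, 518, 520, 543, 561),
      tgw_g = c(355, 378, 349, 361, 359, 334, 346, 363, 299, 308),
      ears_10k_ha = c(6.91, 6.94, 6.86, 6.86, 6.57, 6.67, 6.83, 6.89, 7.32, 7.39),
      yield_kg_ha = c(12245, 12796, 11860, 12720, 12286, 12701, 12238, 13009,
                      11889, 12754),
      stringsAsFactors = FALSE),
    stage_gdd = data.frame(
      year = yrs, hybrid = hyb,
      days_before_silking = c(45, 51, 46, 52, 46, 51, 46, 51, 46, 52),
      gdd_before_silking = c(806.9, 904.6, 826.5, 918.2, 846.1, 931.5,
                             708.3, 785.6, 794.8, 895.6),
      days_after_silking = c(58, 62, 58, 60, 63, 65, 60, 62, 59, 61),
      gdd_after_silking = c(933.3, 955.8, 952.5, 940.3, 860.3, 807.2,
                            923.7, 915.9, 864.9, 853.7),
      total_days = c(104, 114, 104, 111, 109, 116, 106, 113, 105, 113),
      total_gdd = c(1740.2, 1860.4, 1779.0, 1858.4, 1647.1, 1719.9,
                    1632.0, 1701.5, 1659.7, 1749.3),
      stringsAsFactors = FALSE),
    remobilization = data.frame(
      year = yrs, hybrid = hyb,
      dmr_stalk = c(17.81, 15.75, 19.36, 18.38, 19.68, 18.38, 19.16, 18.40,
                    18.82, 18.16),
      dmre_stalk = c(25.49, 19.99, 27.20, 21.98, 24.65, 22.03, 26.51, 21.40,
                     27.34, 21.45),
      dmr_leaf = c(5.26, 1.98, 5.36, 2.55, 5.19, 2.09, 6.01, 1.95, 5.87, 1.73),
      dmre_leaf = c(15.38, 5.62, 14.21, 6.22, 14.07, 5.38, 16.13, 4.88,
                    15.82, 4.65),
      stringsAsFactors = FALSE),
    dmrc = data.frame(
      year = rep(c(2017, 2018, 2020, 2021), each = 2),
      hybrid = rep(c("DH518", "DH605"), 4),
      dmr_to_grain = c(14.34, 10.53, 14.75, 13.29, 13.76, 10.32, 14.75, 11.03),
      dmrc = c(9.50, 6.61, 9.99, 8.20, 9.04, 6.43, 9.87, 6.95),
      yield_per_gdd = c(11.83, 12.49, 11.21, 12.42, 12.05, 13.29, 12.39, 13.90),
      stringsAsFactors = FALSE),
    pn_fits = data.frame(
      year = yrs, hybrid = hyb,
      a = c(43.34, 45.04, 43.97, 45.40, 44.94, 45.93, 45.07, 46.04, 44.75, 46.19),
      b = c(0.58, 0.47, 0.52, 0.41, 0.54, 0.43, 0.55, 0.42, 0.51, 0.43),
      r = c(0.994, 0.989, 0.946, 0.958, 0.952, 0.973, 0.967, 0.966, 0.952, 0.983),
      Pi = c(46.07, 48.23, 46.33, 48.13, 47.83, 48.37, 48.57, 49.27, 47.63, 48.70),
      apd = c(40.27, 50.67, 44.34, 57.02, 43.11, 55.76, 41.79, 55.57, 45.09, 55.84),
      stringsAsFactors = FALSE),
    gaussian_fits = data.frame(
      year = yrs, hybrid = hyb,
      A = c(4.56, 5.07, 4.40, 5.15, 4.48, 4.91, 4.83, 5.39, 4.45, 5.12),
      B = c(5.41, 5.65, 7.96, 5.72, 6.28, 3.28, 5.75, 4.73, 7.66, 4.97),
      C = c(42.62, 48.34, 40.45, 48.03, 42.31, 52.39, 43.10, 50.88, 42.89, 48.60),
      R = c(0.996, 0.992, 0.995, 0.996, 0.999, 0.996, 0.997, 0.993, 0.997, 0.996),
      dlai = c(50.09, 56.95, 47.64, 56.48, 49.92, 61.72, 50.75, 59.87,
               50.34, 57.23),
      stringsAsFactors = FALSE),
    grain_leaf_hi = data.frame(
      year = yrs, hybrid = hyb,
      grain_leaf = c(0.268, 0.252, 0.269, 0.247, 0.274, 0.259, 0.253, 0.241,
                     0.267, 0.249),
      hi = c(0.582, 0.559, 0.567, 0.544, 0.576, 0.554, 0.572, 0.537,
             0.578, 0.544),
      stringsAsFactors = FALSE)
  )
}
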