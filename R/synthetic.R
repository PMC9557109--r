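# run code under a locally-seeded RNG without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Ground-truth parameter set for one synthetic hybrid
#'
#' The stated world of the generator: thermal-time requirements, canopy
#' trajectory, organ masses, tracer partitioning and yield components for a
#' single hybrid, from which every derived metric has a closed form.
#' Defaults (see [default_hybrid_truths()]) are centred on published values
#' for early- and mid-late-maturity summer maize.
#'
#' @param gdd_silking,gdd_maturity GDD requirements from sowing to R1 and to
#'   R6 (degC d).
#' @param A,B,C Gaussian LAI truth: maximum LAI, day of maximum (d after
#'   silking), curve width (d).
#' @param pn_a,pn_b Linear Pn decline truth: intercept at silking (umol m^-2
#'   s^-1) and decline rate (umol m^-2 s^-1 d^-1).
#' @param leaf_r1,stalk_r1 Organ dry masses at R1 (g plant^-1).
#' @param leaf_r6,stalk_r6,grain_r6,other_r6 Organ dry masses at R6
#'   (g plant^-1); `other` is bract + cob.
#' @param f 13C distribution truth: named fractions for grain, other, stalk,
#'   leaf; must sum to 1.
#' @param ears_ha,grains_per_ear,tgw_g Yield component truths.
#' @return A `hybrid_truth` list.
#' @export
hybrid_truth <- function(gdd_silking, gdd_maturity, A, B, C, pn_a, pn_b,
                         leaf_r1, stalk_r1, leaf_r6, stalk_r6, grain_r6,
                         other_r6, f, ears_ha, grains_per_ear, tgw_g) {
  stopifnot(gdd_maturity > gdd_silking, A > 0, C > 0, pn_b > 0,
            abs(sum(f) - 1) < 1e-9, all(f >= 0),
            all(c(leaf_r1, stalk_r1, leaf_r6, stalk_r6, grain_r6, other_r6) > 0))
  structure(as.list(environment()), class = "hybrid_truth")
}

#' Default truths for an early and a mid-late maturity hybrid
#'
#' Two [hybrid_truth()] sets reproducing the magnitudes of published
#' five-year trial tables: the early hybrid silks ~50 d after sowing with a
#' smaller, faster-senescing canopy and higher remobilization; the mid-late
#' hybrid needs ~90 degC d more thermal time to silking, holds LAI and Pn
#' longer, and yields more through heavier kernels.
#'
#' @return Named list of two `hybrid_truth` objects (`DH518`, `DH605`).
#' @export
default_hybrid_truths <- function() {
  list(
    DH518 = hybrid_truth(
      gdd_silking = 800, gdd_maturity = 1700,
      A = 4.55, B = 6.0, C = 42.0, pn_a = 47.0, pn_b = 0.54,
      leaf_r1 = 34.2, stalk_r1 = 69.9,
      leaf_r6 = 28.9, stalk_r6 = 52.1, grain_r6 = 151.0, other_r6 = 28.0,
      f = c(grain = 0.62, other = 0.18, stalk = 0.13, leaf = 0.07),
      ears_ha = 6.9e4, grains_per_ear = 510, tgw_g = 340
    ),
    DH605 = hybrid_truth(
      gdd_silking = 890, gdd_maturity = 1780,
      A = 5.10, B = 5.0, C = 49.5, pn_a = 48.3, pn_b = 0.43,
      leaf_r1 = 38.5, stalk_r1 = 78.8,
      leaf_r6 = 36.4, stalk_r6 = 61.9, grain_r6 = 160.0, other_r6 = 30.6,
      f = c(grain = 0.59, other = 0.19, stalk = 0.145, leaf = 0.075),
      ears_ha = 6.95e4, grains_per_ear = 530, tgw_g = 350
    )
  )
}

# plot noise scales: "+-" table values read as SE of n = 3, so plot-level
# sd = SE * sqrt(3); scaled jointly by the `noise` multiplier
.noise_scales <- list(
  weather = 1.5,  # degC sd of the AR(1) mean-temperature deviation
  lai = 0.08, pn = 1.2, gs = 0.015, ci = 6, spad = 1.5,
  organ = 1.7,    # g plant^-1 (organ SE ~1 g)
  atom = 0.004,   # atom-% on reference and labeled plants
  ears = 0.12e4, grains = 17, tgw = 4, yield_rel = 0.012
)

#' Generate a season of synthetic daily weather
#'
#' Daily Tmax/Tmin from an annual sinusoid for the daily mean temperature
#' plus AR(1) noise, with a jittered diurnal range. Parameterized for a
#' warm-temperate summer season (mean ~26 degC in mid June easing to ~23
#' degC in early October, i.e. ~16 degC d of daily thermal time over a 10
#' degC base).
#'
#' @param year Season label (also used for the calendar).
#' @param start First day (default June 1 of `year`).
#' @param n_days Season length, >= 120 (default 160).
#' @param mean_annual,amplitude,peak_doy Sinusoid parameters (degC, degC,
#'   day-of-year of the warmest day).
#' @param diurnal_range Mean Tmax - Tmin (degC).
#' @param noise Multiplier on the AR(1) noise sd (0 = smooth sinusoid).
#' @param seed Optional integer seed (local to this call).
#' @return Weather data frame (`year`, `date`, `tmax_c`, `tmin_c`).
#' @export
generate_weather <- function(year, start = NULL, n_days = 160,
                             mean_annual = 20, amplitude = 9, peak_doy = 205,
                             diurnal_range = 10, noise = 1, seed = NULL) {
  if (n_days < 120) stop("season length must be >= 120 days")
  start <- as.Date(start %||% paste0(year, "-06-01"))
  dates <- start + seq_len(n_days) - 1
  doy <- as.integer(format(dates, "%j"))
  tmean <- mean_annual + amplitude * cos(2 * pi * (doy - peak_doy) / 365)
  with_seed(seed, {
    if (noise > 0) {
      eps <- as.numeric(stats::arima.sim(list(ar = 0.6), n_days,
                                         sd = .noise_scales$weather * noise))
      rng <- pmax(2, diurnal_range + stats::rnorm(n_days, 0, noise))
    } else {
      eps <- 0
      rng <- rep(diurnal_range, n_days)
    }
    data.frame(year = year, date = dates,
               tmax_c = tmean + eps + rng / 2,
               tmin_c = tmean + eps - rng / 2)
  })
}

# first date at which start-exclusive accumulated GDD reaches `target`
.gdd_crossing <- function(weather, sowing, target, tbase = 10) {
  after <- weather[as.Date(weather$date) > as.Date(sowing), , drop = FALSE]
  cum <- cumsum(daily_gdd(after$tmax_c, after$tmin_c, tbase))
  i <- which(cum >= target)[1]
  if (is.na(i)) stop("GDD threshold ", target, " unreachable within season")
  as.Date(after$date[i])
}

#' Generate a complete synthetic trial with analytic ground truth
#'
#' Builds a multi-year, multi-hybrid, replicated trial dataset from
#' [hybrid_truth()] parameter sets: weather is simulated per year, phenology
#' dates are solved so accumulated GDD hits each hybrid's thresholds (R3 is
#' placed 15 d and R5 45 d after silking), LAI and Pn observations are
#' sampled from the Gaussian and linear truths at stage days, organ masses,
#' isotope atom-% (natural-abundance baseline 1.08 atom-% plus a label
#' excess consistent with the configured tracer fractions) and yield
#' components are drawn with additive zero-mean plot noise. The returned
#' ground truth carries every derived metric in closed form, so at
#' `noise = 0` the full pipeline reproduces it exactly.
#'
#' @param truths Named list of `hybrid_truth` (default
#'   [default_hybrid_truths()]).
#' @param years Vector of season labels (default 2017:2021).
#' @param replicates Plots per year x hybrid (default 3).
#' @param noise Multiplier on every noise scale; 0 gives a noise-free
#'   dataset (default 1).
#' @param density Planting density (plants ha^-1, default 75000).
#' @param seed Optional integer seed (local to this call).
#' @return List with `dataset` (a [trial_dataset()]) and `truth` (data frame
#'   of analytic values per year x hybrid: Gaussian/linear parameters, DLAI,
#'   APD, PrSDMAR, PoSDMA, PoSDMAR, DMR/DMRE per organ, DMR to grain, DMRC,
#'   HI, yield and yield per GDD on both denominators).
#' @export
generate_trial <- function(truths = default_hybrid_truths(), years = 2017:2021,
                           replicates = 3, noise = 1, density = 75000,
                           seed = NULL) {
  if (length(truths) < 2) stop("need at least 2 hybrids")
  if (replicates < 2) stop("need at least 2 replicates")
  if (is.null(names(truths)) || any(!nzchar(names(truths))))
    stop("truths must be a named list")
  with_seed(seed, {
    ns <- lapply(.noise_scales, function(s) s * noise)
    weather <- do.call(rbind, lapply(years, function(y)
      generate_weather(y, noise = noise)))
    phen <- list(); samp <- list(); lai <- list(); gx <- list()
    iso <- list(); yld <- list(); tru <- list()
    label_excess_g <- 0.35  # total tracer-mass proxy per labeled plant
    ref_atom <- 1.08        # natural 13C abundance, atom-%

    for (y in years) {
      wy <- weather[weather$year == y, , drop = FALSE]
      sowing <- as.Date(paste0(y, "-06-10"))
      for (h in names(truths)) {
        tr <- truths[[h]]
        r1 <- .gdd_crossing(wy, sowing, tr$gdd_silking)
        r6 <- .gdd_crossing(wy, sowing, tr$gdd_maturity)
        v6 <- .gdd_crossing(wy, sowing, 0.35 * tr$gdd_silking)
        v12 <- .gdd_crossing(wy, sowing, 0.75 * tr$gdd_silking)
        r3 <- r1 + 15; r5 <- r1 + 45
        if (r6 <= r5) r6 <- r5 + 1
        phen[[length(phen) + 1L]] <- data.frame(
          year = y, hybrid = h, sowing = sowing, v6 = v6, v12 = v12,
          r1 = r1, r3 = r3, r5 = r5, r6 = r6, stringsAsFactors = FALSE)

        stage_days <- c(v6 = as.integer(v6 - r1), v12 = as.integer(v12 - r1),
                        r1 = 0L, r3 = 15L, r5 = 45L, r6 = as.integer(r6 - r1))
        lai_true <- tr$A * exp(-(stage_days - tr$B)^2 / (2 * tr$C^2))
        lai[[length(lai) + 1L]] <- data.frame(
          year = y, hybrid = h, stage = toupper(names(stage_days)),
          day = as.integer(stage_days),
          lai = pmax(0, lai_true + stats::rnorm(length(stage_days), 0, ns$lai)),
          stringsAsFactors = FALSE)

        gx_days <- c(R1 = 0L, R3 = 15L, R5 = 45L)
        gx[[length(gx) + 1L]] <- data.frame(
          year = y, hybrid = h, stage = names(gx_days), day = as.integer(gx_days),
          pn = pmax(0, tr$pn_a - tr$pn_b * gx_days + stats::rnorm(3, 0, ns$pn)),
          gs = pmax(0.01, 0.25 - 0.002 * gx_days + stats::rnorm(3, 0, ns$gs)),
          ci = pmax(10, 150 + 0.5 * gx_days + stats::rnorm(3, 0, ns$ci)),
          spad = pmax(0, 55 - 0.15 * gx_days + stats::rnorm(3, 0, ns$spad)),
          stringsAsFactors = FALSE)

        for (rep in seq_len(replicates)) {
          samp[[length(samp) + 1L]] <- data.frame(
            year = y, hybrid = h, replicate = rep, stage = c("R1", "R6"),
            leaf_g = pmax(0.1, c(tr$leaf_r1, tr$leaf_r6) + stats::rnorm(2, 0, ns$organ)),
            stalk_g = pmax(0.1, c(tr$stalk_r1, tr$stalk_r6) + stats::rnorm(2, 0, ns$organ)),
            grain_g = c(0, max(0.1, tr$grain_r6 + stats::rnorm(1, 0, ns$organ))),
            other_g = c(0, max(0.1, tr$other_r6 + stats::rnorm(1, 0, ns$organ))),
            stringsAsFactors = FALSE)
        }

        organs <- c("grain", "other", "stalk", "leaf")
        mass6 <- c(grain = tr$grain_r6, other = tr$other_r6,
                   stalk = tr$stalk_r6, leaf = tr$leaf_r6)
        for (p in 1:3) {
          for (lab in c(TRUE, FALSE)) {
            atom <- ref_atom +
              (if (lab) 100 * label_excess_g * tr$f[organs] / mass6[organs] else 0) +
              stats::rnorm(4, 0, ns$atom)
            iso[[length(iso) + 1L]] <- data.frame(
              year = y, hybrid = h,
              plant = paste0(h, "-", if (lab) "L" else "R", p),
              labeled = lab, organ = organs,
              mass_g = pmax(0.1, mass6[organs] + stats::rnorm(4, 0, ns$organ)),
              atom_pct = pmin(99, pmax(0.5, atom)), stringsAsFactors = FALSE)
          }
        }

        for (rep in seq_len(replicates)) {
          ears <- max(1e4, tr$ears_ha + stats::rnorm(1, 0, ns$ears))
          grains <- max(50, tr$grains_per_ear + stats::rnorm(1, 0, ns$grains))
          tgw <- max(50, tr$tgw_g + stats::rnorm(1, 0, ns$tgw))
          yv <- ears * grains * tgw / 1e6
          yv <- yv * (1 + stats::rnorm(1, 0, ns$yield_rel))
          yld[[length(yld) + 1L]] <- data.frame(
            year = y, hybrid = h, replicate = rep, ears_ha = ears,
            grains_per_ear = grains, tgw_g = tgw, moisture = 0.14,
            yield_kg_ha = yv, stringsAsFactors = FALSE)
        }

        # analytic ground truth for this year x hybrid
        tot1 <- tr$leaf_r1 + tr$stalk_r1
        tot6 <- tr$leaf_r6 + tr$stalk_r6 + tr$grain_r6 + tr$other_r6
        dmr_l <- tr$leaf_r1 - tr$leaf_r6
        dmr_s <- tr$stalk_r1 - tr$stalk_r6
        d2g <- (max(dmr_l, 0) + max(dmr_s, 0)) * tr$f[["grain"]]
        g_before <- accumulate_gdd(wy, sowing, r1)
        g_after <- accumulate_gdd(wy, r1, r6)
        yield_true <- tr$ears_ha * tr$grains_per_ear * tr$tgw_g / 1e6
        tru[[length(tru) + 1L]] <- data.frame(
          year = y, hybrid = h, A = tr$A, B = tr$B, C = tr$C,
          dlai = tr$C * sqrt(2 * log(2)),
          Pi = tr$pn_a, b = tr$pn_b, apd = tr$pn_a / (2 * tr$pn_b),
          dma_r1 = tot1, dma_r6 = tot6,
          prsdmar = 100 * tot1 / tot6, posdma = tot6 - tot1,
          posdmar = 100 * (tot6 - tot1) / tot6,
          dmr_leaf = dmr_l, dmr_stalk = dmr_s,
          dmre_leaf = 100 * dmr_l / tr$leaf_r1,
          dmre_stalk = 100 * dmr_s / tr$stalk_r1,
          f_grain = tr$f[["grain"]], dmr_to_grain = d2g,
          dmrc = 100 * d2g / tr$grain_r6, hi = tr$grain_r6 / tot6,
          gdd_before = g_before, gdd_after = g_after,
          gdd_total = g_before + g_after, yield_kg_ha = yield_true,
          yield_per_gdd_total = yield_true / (g_before + g_after),
          yield_per_gdd_post = yield_true / g_after,
          stringsAsFactors = FALSE)
      }
    }
    ds <- trial_dataset(
      weather = weather, phenology = do.call(rbind, phen),
      plant_samples = do.call(rbind, samp), lai = do.call(rbind, lai),
      gas_exchange = do.call(rbind, gx), isotope = do.call(rbind, iso),
      yield = do.call(rbind, yld),
      meta = list(density = density, replicates = replicates))
    truth <- do.call(rbind, tru)
    rownames(truth) <- NULL
    list(dataset = ds, truth = truth)
  })
}

#' Inject a named invariant violation into a dataset
#'
#' Produces corrupted copies of a valid dataset for validator tests.
#'
#' @param ds A valid `trial_dataset`.
#' @param violation One of `"stage_order"` (R6 moved before R1),
#'   `"tmin_gt_tmax"` (one inverted weather day), `"negative_mass"` (one
#'   negative organ mass), `"missing_reference_plants"` (one isotope cohort
#'   stripped of its reference plants), `"orphan_year_hybrid"` (one LAI row
#'   pointing at a year x hybrid without phenology).
#' @param seed Optional seed choosing which row is corrupted.
#' @return The corrupted `trial_dataset`.
#' @export
corrupt_dataset <- function(ds, violation, seed = NULL) {
  with_seed(seed, {
    pick <- function(n) sample.int(n, 1)
    switch(violation,
      stage_order = {
        i <- pick(nrow(ds$phenology))
        ds$phenology$r6[i] <- ds$phenology$r1[i] - 5
      },
      tmin_gt_tmax = {
        i <- pick(nrow(ds$weather))
        tmp <- ds$weather$tmax_c[i]
        ds$weather$tmax_c[i] <- ds$weather$tmin_c[i] - 1
        ds$weather$tmin_c[i] <- tmp
      },
      negative_mass = {
        i <- pick(nrow(ds$plant_samples))
        ds$plant_samples$leaf_g[i] <- -abs(ds$plant_samples$leaf_g[i])
      },
      missing_reference_plants = {
        yh <- paste(ds$isotope$year, ds$isotope$hybrid)
        drop_yh <- yh[pick(length(yh))]
        ds$isotope <- ds$isotope[!(yh == drop_yh & !ds$isotope$labeled), ,
                                 drop = FALSE]
      },
      orphan_year_hybrid = {
        i <- pick(nrow(ds$lai))
        ds$lai$hybrid[i] <- "NO_SUCH_HYBRID"
      },
      stop("unknown violation: ", violation)
    )
    ds
  })
}
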