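# mean per (year, hybrid) with within-year LSD letters; `df` has columns
# year, hybrid, replicate, value
summarize_with_letters <- function(df, alpha = 0.05) {
  out <- list()
  for (y in unique(df$year)) {
    sub <- df[df$year == y, , drop = FALSE]
    means <- tapply(sub$value, sub$hybrid, mean)
    n <- as.vector(table(sub$hybrid))
    if (length(means) >= 2 && all(n >= 2) && length(unique(n)) == 1) {
      fit <- stats::aov(value ~ factor(hybrid), data = sub)
      mse <- stats::deviance(fit) / stats::df.residual(fit)
      lt <- lsd_letters(means, mse, stats::df.residual(fit), n[1], alpha)$letters
    } else {
      lt <- stats::setNames(rep(NA_character_, length(means)), names(means))
    }
    se <- tapply(sub$value, sub$hybrid, function(v) stats::sd(v) / sqrt(length(v)))
    out[[length(out) + 1L]] <- data.frame(
      year = y, hybrid = names(means), mean = as.vector(means),
      se = as.vector(se), letter = as.vector(lt[names(means)]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ANOVA footer (Year, Hybrid, Year:Hybrid F and significance stars) for one
# replicate-level metric
anova_footer <- function(df) {
  # not estimable (single year, unbalanced cells): omit the footer
  tab <- tryCatch(two_way_anova(df$value, df$year, df$hybrid),
                  error = function(e) NULL)
  if (is.null(tab)) return(NULL)
  star <- function(p) ifelse(is.na(p), "", ifelse(p < 0.01, "**",
                             ifelse(p < 0.05, "*", "")))
  data.frame(effect = tab$effect[1:3], F = tab$F[1:3],
             p = round(tab$p[1:3], 3), signif = star(tab$p[1:3]),
             stringsAsFactors = FALSE)
}

# replicate-level partitioning metrics from the plant_samples table
replicate_partitioning <- function(ps, phen) {
  key <- unique(ps[c("year", "hybrid", "replicate")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    sub <- ps[ps$year == k$year & ps$hybrid == k$hybrid &
                ps$replicate == k$replicate, , drop = FALSE]
    r1 <- sub[sub$stage == "R1", ]; r6 <- sub[sub$stage == "R6", ]
    if (nrow(r1) != 1 || nrow(r6) != 1) return(NULL)
    z <- function(x) ifelse(is.na(x), 0, x)
    tot1 <- r1$leaf_g + r1$stalk_g + z(r1$grain_g) + z(r1$other_g)
    tot6 <- r6$leaf_g + r6$stalk_g + z(r6$grain_g) + z(r6$other_g)
    pp <- pre_post_silking(tot1, tot6)
    dl <- dmr_and_dmre(r1$leaf_g, r6$leaf_g)
    st <- dmr_and_dmre(r1$stalk_g, r6$stalk_g)
    ph <- phen[phen$year == k$year & phen$hybrid == k$hybrid, ]
    data.frame(
      year = k$year, hybrid = k$hybrid, replicate = k$replicate,
      dma_r1 = tot1, dma_r6 = tot6, grain_r6 = z(r6$grain_g),
      prsdmar = pp$prsdmar, posdma = pp$posdma, posdmar = pp$posdmar,
      cgr_pre = crop_growth_rate(0, tot1, as.integer(ph$r1 - ph$sowing)),
      cgr_post = crop_growth_rate(tot1, tot6, as.integer(ph$r6 - ph$r1)),
      dmr_leaf = dl$dmr, dmre_leaf = dl$dmre,
      dmr_stalk = st$dmr, dmre_stalk = st$dmre,
      hi = harvest_index(z(r6$grain_g), tot6),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full trial-analysis pipeline
#'
#' Loads or takes a trial dataset and produces the standard report tables of
#' a growth-duration hybrid comparison: yield components, stage durations
#' and thermal time, dry-matter partitioning, remobilization, tracer-
#' corrected remobilization contribution (DMRC), canopy-dynamics fits
#' (Gaussian LAI and linear Pn decline), grain/leaf ratio and harvest index
#' — each with within-year LSD letters and a Year/Hybrid/Year x Hybrid ANOVA
#' footer where replicate-level data exist — plus a correlation report
#' (pre-silking days vs HI across year x hybrid means; yield vs DMA and
#' yield vs HI per year x hybrid on replicate-level points).
#'
#' @param ds A `trial_dataset`, or a directory path for
#'   [read_trial_dataset()].
#' @param out_dir Optional output directory; tables are written as
#'   full-precision CSVs plus a formatted `report.txt`.
#' @param tbase Base temperature for thermal time (degC, default 10).
#' @param alpha Significance level for LSD letters (default 0.05).
#' @return Invisibly, a named list of data frames: `yield_components`,
#'   `stage_gdd`, `partitioning`, `remobilization`, `dmrc` (NULL with a
#'   warning when the isotope table is absent), `canopy_fits`,
#'   `grain_leaf_hi`, `correlations`, `anova` (footers per metric).
#' @export
run_pipeline <- function(ds, out_dir = NULL, tbase = 10, alpha = 0.05) {
  if (is.character(ds)) ds <- read_trial_dataset(ds)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  phen <- ds$phenology
  footers <- list()

  # --- stage durations and thermal time ------------------------------------
  stage_gdd <- do.call(rbind, lapply(seq_len(nrow(phen)), function(i) {
    wy <- ds$weather[ds$weather$year == phen$year[i], , drop = FALSE]
    stage_durations(phen[i, ], wy, tbase)
  }))

  # --- yield components -----------------------------------------------------
  yield_components <- NULL
  if (!is.null(ds$yield)) {
    yc <- ds$yield
    pieces <- lapply(c("grains_per_ear", "tgw_g", "ears_ha", "yield_kg_ha"),
                     function(v) {
      df <- data.frame(year = yc$year, hybrid = yc$hybrid,
                       replicate = yc$replicate, value = yc[[v]])
      s <- summarize_with_letters(df, alpha)
      names(s)[3:5] <- paste0(v, c("", "_se", "_letter"))
      footers[[v]] <<- anova_footer(df)
      s
    })
    yield_components <- Reduce(function(a, b) merge(a, b, by = c("year", "hybrid")),
                               pieces)
    yield_components <- yield_components[order(yield_components$year,
                                               yield_components$hybrid), ]
  }

  # --- partitioning / remobilization / HI ----------------------------------
  rp <- replicate_partitioning(ds$plant_samples, phen)
  summarize_metric <- function(v) {
    df <- data.frame(year = rp$year, hybrid = rp$hybrid,
                     replicate = rp$replicate, value = rp[[v]])
    footers[[v]] <<- anova_footer(df)
    s <- summarize_with_letters(df, alpha)
    names(s)[3:5] <- paste0(v, c("", "_se", "_letter"))
    s
  }
  part_cols <- c("dma_r1", "dma_r6", "prsdmar", "posdma", "posdmar",
                 "cgr_pre", "cgr_post")
  partitioning <- Reduce(function(a, b) merge(a, b, by = c("year", "hybrid")),
                         lapply(part_cols, summarize_metric))
  remobilization <- Reduce(function(a, b) merge(a, b, by = c("year", "hybrid")),
                           lapply(c("dmr_stalk", "dmre_stalk", "dmr_leaf",
                                    "dmre_leaf"), summarize_metric))

  # --- canopy dynamics ------------------------------------------------------
  yh <- unique(phen[c("year", "hybrid")])
  canopy_fits <- do.call(rbind, lapply(seq_len(nrow(yh)), function(i) {
    sel <- function(t) t[t$year == yh$year[i] & t$hybrid == yh$hybrid[i], ,
                         drop = FALSE]
    lf <- fit_lai_gaussian(sel(ds$lai)$day, sel(ds$lai)$lai)
    row <- data.frame(year = yh$year[i], hybrid = yh$hybrid[i],
                      A = lf$A, B = lf$B, C = lf$C, R = lf$R, dlai = lf$DLAI,
                      stringsAsFactors = FALSE)
    if (!is.null(ds$gas_exchange)) {
      gx <- sel(ds$gas_exchange); gx <- gx[gx$day >= 0, , drop = FALSE]
      pf <- fit_pn_linear(gx$day, gx$pn)
      row <- cbind(row, data.frame(pn_a = pf$a, pn_b = pf$b, pn_r = pf$r,
                                   Pi = pf$Pi, apd = pf$APD))
    }
    row
  }))

  # --- DMRC (needs the isotope table) --------------------------------------
  dmrc_tab <- NULL
  if (is.null(ds$isotope)) {
    warning("isotope table absent: DMRC table omitted")
  } else {
    iso <- ds$isotope
    fr <- do.call(rbind, lapply(seq_len(nrow(yh)), function(i) {
      sub <- iso[iso$year == yh$year[i] & iso$hybrid == yh$hybrid[i], ,
                 drop = FALSE]
      if (!nrow(sub)) return(NULL)
      cd <- c13_distribution(sub$organ, sub$labeled, sub$mass_g, sub$atom_pct)
      data.frame(year = yh$year[i], hybrid = yh$hybrid[i],
                 f_grain = cd$fraction[["grain"]], stringsAsFactors = FALSE)
    }))
    dmrc_rep <- merge(rp, fr, by = c("year", "hybrid"))
    dmrc_rep$dmr_to_grain <- dmr_to_grain(dmrc_rep$dmr_leaf, dmrc_rep$dmr_stalk,
                                          dmrc_rep$f_grain)
    dmrc_rep$dmrc <- dmrc(dmrc_rep$dmr_to_grain, dmrc_rep$grain_r6)
    summarize_from <- function(src, v) {
      df <- data.frame(year = src$year, hybrid = src$hybrid,
                       replicate = src$replicate, value = src[[v]])
      footers[[v]] <<- anova_footer(df)
      s <- summarize_with_letters(df, alpha)
      names(s)[3:5] <- paste0(v, c("", "_se", "_letter"))
      s
    }
    dmrc_tab <- merge(summarize_from(dmrc_rep, "dmr_to_grain"),
                      summarize_from(dmrc_rep, "dmrc"), by = c("year", "hybrid"))
    dmrc_tab <- merge(dmrc_tab, fr, by = c("year", "hybrid"))
    dmrc_tab$posdma_contribution <- 100 - dmrc_tab$dmrc
  }

  # --- grain/leaf, HI, yield per GDD ---------------------------------------
  grain_leaf_hi <- NULL
  if (!is.null(ds$yield)) {
    ym <- merge(ds$yield, canopy_fits[c("year", "hybrid", "A")],
                by = c("year", "hybrid"))
    ym$sink <- sink_capacity(ym$ears_ha / 1e4, ym$grains_per_ear,
                             ym$tgw_g / 1000)
    ym$grain_leaf <- grain_leaf_ratio(ym$sink, ym$A)
    gl <- {
      df <- data.frame(year = ym$year, hybrid = ym$hybrid,
                       replicate = ym$replicate, value = ym$grain_leaf)
      footers[["grain_leaf"]] <- anova_footer(df)
      s <- summarize_with_letters(df, alpha)
      names(s)[3:5] <- c("grain_leaf", "grain_leaf_se", "grain_leaf_letter")
      s
    }
    grain_leaf_hi <- merge(gl, summarize_metric("hi"), by = c("year", "hybrid"))
    ypg <- merge(ds$yield, stage_gdd, by = c("year", "hybrid"))
    ypg$value <- yield_per_gdd(ypg$yield_kg_ha, ypg$gdd_after_silking)
    s1 <- summarize_with_letters(ypg[c("year", "hybrid", "replicate", "value")],
                                 alpha)
    names(s1)[3:5] <- c("yield_per_gdd_post", "yield_per_gdd_post_se",
                        "yield_per_gdd_post_letter")
    ypg$value <- yield_per_gdd(ypg$yield_kg_ha, ypg$total_gdd)
    s2 <- summarize_with_letters(ypg[c("year", "hybrid", "replicate", "value")],
                                 alpha)
    names(s2)[3:5] <- c("yield_per_gdd_total", "yield_per_gdd_total_se",
                        "yield_per_gdd_total_letter")
    grain_leaf_hi <- Reduce(function(a, b) merge(a, b, by = c("year", "hybrid")),
                            list(grain_leaf_hi, s1, s2))
  }

  # --- correlation report ---------------------------------------------------
  correlations <- NULL
  if (!is.null(grain_leaf_hi)) {
    m <- merge(stage_gdd[c("year", "hybrid", "days_before_silking")],
               grain_leaf_hi[c("year", "hybrid", "hi")], by = c("year", "hybrid"))
    ct <- tryCatch(pearson(m$days_before_silking, m$hi),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    correlations <- list(hi_vs_days_to_silking = ct, yield_regressions = NULL)
    ym2 <- merge(ds$yield, rp, by = c("year", "hybrid", "replicate"))
    regs <- do.call(rbind, lapply(seq_len(nrow(yh)), function(i) {
      sub <- ym2[ym2$year == yh$year[i] & ym2$hybrid == yh$hybrid[i], ,
                 drop = FALSE]
      if (nrow(sub) < 3 || stats::var(sub$dma_r6) == 0 ||
          stats::var(sub$hi) == 0) return(NULL)  # degenerate (noise-free) cells
      r1 <- linear_regression(sub$dma_r6, sub$yield_kg_ha)
      r2 <- linear_regression(sub$hi, sub$yield_kg_ha)
      data.frame(year = yh$year[i], hybrid = yh$hybrid[i],
                 dma_a = r1$a, dma_b = r1$b, dma_r = r1$r,
                 hi_a = r2$a, hi_b = r2$b, hi_r = r2$r,
                 stringsAsFactors = FALSE)
    }))
    correlations$yield_regressions <- regs
  }

  bundle <- list(yield_components = yield_components, stage_gdd = stage_gdd,
                 partitioning = partitioning, remobilization = remobilization,
                 dmrc = dmrc_tab, canopy_fits = canopy_fits,
                 grain_leaf_hi = grain_leaf_hi, correlations = correlations,
                 anova = footers)

  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  invisible(bundle)
}

# write full-precision CSVs plus a formatted report.txt
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- options(digits = 15); on.exit(options(old))
  for (nm in c("yield_components", "stage_gdd", "partitioning",
               "remobilization", "dmrc", "canopy_fits", "grain_leaf_hi")) {
    t <- bundle[[nm]]
    if (is.null(t)) next
    t <- t[order(t$year, t$hybrid), , drop = FALSE]
    utils::write.csv(t, file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  con <- file(file.path(out_dir, "report.txt"), "w"); on.exit(close(con), add = TRUE)
  fmt_tab <- function(t, digits) {
    num <- vapply(t, is.numeric, logical(1))
    t[num] <- lapply(t[num], function(x) formatC(x, digits = digits,
                                                 format = "fg", flag = "#"))
    writeLines(utils::capture.output(print(t, row.names = FALSE)), con)
  }
  for (nm in names(bundle)) {
    t <- bundle[[nm]]
    if (!is.data.frame(t)) next
    writeLines(c(paste0("== ", nm, " =="), ""), con)
    fmt_tab(t[order(t$year, t$hybrid), , drop = FALSE], 4)
    writeLines("", con)
  }
  if (!is.null(bundle$correlations)) {
    writeLines(c("== correlations ==", sprintf(
      "HI vs days to silking: r = %.3f, p = %.4g",
      bundle$correlations$hi_vs_days_to_silking$r,
      bundle$correlations$hi_vs_days_to_silking$p)), con)
  }
  for (nm in names(bundle$anova)) {
    f <- bundle$anova[[nm]]
    writeLines(c("", paste0("-- ANOVA: ", nm, " --"),
                 utils::capture.output(print(f, row.names = FALSE))), con)
  }
  invisible(out_dir)
}
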