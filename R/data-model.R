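# CSV schemas: one table per file, ISO-8601 dates, units fixed per column.
.schemas <- list(
  weather = c("year", "date", "tmax_c", "tmin_c"),
  phenology = c("year", "hybrid", "sowing", "v6", "v12", "r1", "r3", "r5", "r6"),
  plant_samples = c("year", "hybrid", "replicate", "stage",
                    "leaf_g", "stalk_g", "grain_g", "other_g"),
  lai = c("year", "hybrid", "stage", "day", "lai"),
  gas_exchange = c("year", "hybrid", "stage", "day", "pn", "gs", "ci", "spad"),
  isotope = c("year", "hybrid", "plant", "labeled", "organ", "mass_g", "atom_pct"),
  yield = c("year", "hybrid", "replicate", "ears_ha", "grains_per_ear",
            "tgw_g", "moisture", "yield_kg_ha")
)
.date_cols <- list(weather = "date",
                   phenology = c("sowing", "v6", "v12", "r1", "r3", "r5", "r6"))

#' Construct a trial dataset
#'
#' Bundles the seven tables of a multi-year hybrid trial into a single
#' validated object. Tables are plain data frames with the documented
#' columns; `meta` carries design constants.
#'
#' @param weather Daily weather: `year`, `date`, `tmax_c`, `tmin_c`.
#' @param phenology Stage dates per year x hybrid: `sowing`, `v6`, `v12`,
#'   `r1`, `r3`, `r5`, `r6` (Date).
#' @param plant_samples Per-plant organ dry masses (g plant^-1) at stages R1
#'   and R6: `leaf_g`, `stalk_g`, `grain_g`, `other_g` (grain and other are
#'   `NA`/0 at R1).
#' @param lai LAI observations by stage: `day` (days after silking, may be
#'   negative), `lai`.
#' @param gas_exchange Ear-leaf gas exchange by stage: `pn`, `gs`, `ci`,
#'   optional `spad`.
#' @param isotope 13C samples: `plant`, `labeled` (logical), `organ`,
#'   `mass_g`, `atom_pct`.
#' @param yield Plot yield components: `ears_ha`, `grains_per_ear`, `tgw_g`,
#'   `moisture` (fraction), `yield_kg_ha` (at 14% moisture).
#' @param meta List of design constants: `density` (plants ha^-1, default
#'   75000), `replicates` (default 3).
#' @return An object of class `trial_dataset`.
#' @seealso [read_trial_dataset()], [validate_dataset()], [generate_trial()]
#' @export
trial_dataset <- function(weather, phenology, plant_samples, lai,
                          gas_exchange = NULL, isotope = NULL, yield = NULL,
                          meta = list()) {
  meta$density <- meta$density %||% 75000
  meta$replicates <- meta$replicates %||% 3
  ds <- structure(list(weather = weather, phenology = phenology,
                       plant_samples = plant_samples, lai = lai,
                       gas_exchange = gas_exchange, isotope = isotope,
                       yield = yield, meta = meta),
                  class = "trial_dataset")
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trial_dataset <- function(x, ...) {
  yh <- unique(x$phenology[c("year", "hybrid")])
  cat("Maize hybrid trial dataset\n")
  cat(sprintf("  %d year(s) x %d hybrid(s), %d replicate plots, density %g plants ha-1\n",
              length(unique(yh$year)), length(unique(yh$hybrid)),
              x$meta$replicates, x$meta$density))
  for (tb in names(.schemas)) {
    t <- x[[tb]]
    cat(sprintf("  %-14s %s\n", tb,
                if (is.null(t)) "(absent)" else paste(nrow(t), "rows")))
  }
  invisible(x)
}

#' Read a trial dataset from CSV files
#'
#' Reads the seven standard tables (any subset containing at least weather,
#' phenology, plant_samples and lai) and validates invariants. Hard
#' invariant violations (e.g. `tmin > tmax`) are raised as errors naming the
#' offending table and row.
#'
#' @param dir Directory containing `weather.csv`, `phenology.csv`,
#'   `plant_samples.csv`, `lai.csv` and optionally `gas_exchange.csv`,
#'   `isotope.csv`, `yield.csv`, `meta.csv`.
#' @return A validated `trial_dataset`.
#' @export
read_trial_dataset <- function(dir) {
  read1 <- function(name, required = TRUE) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      if (required) stop("missing required table: ", path)
      return(NULL)
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(.schemas[[name]], c(names(df), "spad"))
    if (length(missing))
      stop("table '", name, "' lacks required column(s): ",
           paste(missing, collapse = ", "))
    for (dc in intersect(.date_cols[[name]] %||% character(), names(df))) {
      parsed <- as.Date(df[[dc]], format = "%Y-%m-%d")
      if (anyNA(parsed) && !all(is.na(df[[dc]])))
        stop("table '", name, "', column '", dc, "': unparsable date at row ",
             which(is.na(parsed) & !is.na(df[[dc]]))[1])
      df[[dc]] <- parsed
    }
    df
  }
  meta <- list()
  mpath <- file.path(dir, "meta.csv")
  if (file.exists(mpath)) {
    m <- utils::read.csv(mpath, stringsAsFactors = FALSE)
    meta <- stats::setNames(as.list(m$value), m$key)
  }
  ds <- trial_dataset(
    weather = read1("weather"), phenology = read1("phenology"),
    plant_samples = read1("plant_samples"), lai = read1("lai"),
    gas_exchange = read1("gas_exchange", required = FALSE),
    isotope = read1("isotope", required = FALSE),
    yield = read1("yield", required = FALSE),
    meta = meta
  )
  rep <- validate_dataset(ds)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("dataset invariant violations:\n  ",
         paste(errs$message, collapse = "\n  "))
  ds
}

#' Write a trial dataset to CSV files
#'
#' Inverse of [read_trial_dataset()]: one CSV per table plus `meta.csv`.
#' read-after-write reproduces the dataset up to float formatting (15
#' significant digits are written).
#'
#' @param ds A `trial_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- options(digits = 15); on.exit(options(old))
  for (tb in names(.schemas)) {
    if (is.null(ds[[tb]])) next
    df <- ds[[tb]]
    for (dc in intersect(.date_cols[[tb]] %||% character(), names(df)))
      df[[dc]] <- format(df[[dc]], "%Y-%m-%d")
    utils::write.csv(df, file.path(dir, paste0(tb, ".csv")), row.names = FALSE)
  }
  meta <- ds$meta
  utils::write.csv(data.frame(key = names(meta),
                              value = unlist(meta, use.names = FALSE)),
                   file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Validate a trial dataset
#'
#' Checks every type invariant and cross-table reference and returns all
#' violations as a report, without raising. Severity is `"error"` for hard
#' invariants (temperature order, stage order, negative masses, missing
#' isotope reference cohorts, broken year x hybrid references) and
#' `"warning"` for soft ones (unbalanced replicate counts).
#'
#' @param ds A `trial_dataset`.
#' @return Data frame with columns `table`, `severity`, `message`; zero rows
#'   iff the dataset is clean.
#' @export
validate_dataset <- function(ds) {
  v <- list()
  add <- function(table, severity, message)
    v[[length(v) + 1L]] <<- data.frame(table = table, severity = severity,
                                       message = message, stringsAsFactors = FALSE)

  w <- ds$weather
  bad <- which(w$tmax_c < w$tmin_c)
  for (i in bad)
    add("weather", "error", paste0("tmax < tmin on ", format(w$date[i])))
  dup <- w$date[duplicated(paste(w$year, w$date))]
  if (length(dup))
    add("weather", "error", paste0("duplicate weather date(s): ",
                                   paste(format(unique(dup)), collapse = ", ")))

  ph <- ds$phenology
  stage_cols <- c("sowing", "v6", "v12", "r1", "r3", "r5", "r6")
  for (i in seq_len(nrow(ph))) {
    dts <- as.numeric(unlist(ph[i, intersect(stage_cols, names(ph))]))
    dts <- dts[!is.na(dts)]
    if (is.unsorted(dts, strictly = TRUE))
      add("phenology", "error",
          paste0("stage dates not strictly increasing for ", ph$year[i], " ",
                 ph$hybrid[i]))
  }

  yh_known <- paste(ph$year, ph$hybrid)
  check_ref <- function(tb) {
    t <- ds[[tb]]
    if (is.null(t)) return()
    miss <- unique(paste(t$year, t$hybrid)[!(paste(t$year, t$hybrid) %in% yh_known)])
    for (m in miss)
      add(tb, "error", paste0("year x hybrid '", m, "' has no phenology record"))
  }
  for (tb in c("plant_samples", "lai", "gas_exchange", "isotope", "yield")) check_ref(tb)

  ps <- ds$plant_samples
  if (!is.null(ps)) {
    mass_cols <- c("leaf_g", "stalk_g", "grain_g", "other_g")
    if (any(ps[mass_cols] < 0, na.rm = TRUE))
      add("plant_samples", "error", "negative organ mass")
    r1 <- ps[ps$stage == "R1", , drop = FALSE]
    if (any(r1$grain_g > 0, na.rm = TRUE) || any(r1$other_g > 0, na.rm = TRUE))
      add("plant_samples", "error", "grain/other mass present at R1")
    cnt <- table(paste(ps$year, ps$hybrid, ps$stage))
    if (length(unique(as.vector(cnt))) > 1)
      add("plant_samples", "warning", "unbalanced replicate counts across cells")
  }

  if (!is.null(ds$lai) && any(ds$lai$lai < 0, na.rm = TRUE))
    add("lai", "error", "negative LAI")

  gx <- ds$gas_exchange
  if (!is.null(gx)) {
    for (cl in intersect(c("pn", "gs", "ci"), names(gx)))
      if (any(gx[[cl]] < 0, na.rm = TRUE))
        add("gas_exchange", "error", paste0("negative ", cl))
  }

  iso <- ds$isotope
  if (!is.null(iso)) {
    if (any(iso$atom_pct <= 0 | iso$atom_pct >= 100, na.rm = TRUE))
      add("isotope", "error", "atom-% outside (0, 100)")
    for (yh in unique(paste(iso$year, iso$hybrid))) {
      sub <- iso[paste(iso$year, iso$hybrid) == yh, , drop = FALSE]
      if (any(sub$labeled) && !any(!sub$labeled))
        add("isotope", "error",
            paste0("labeled plants without reference cohort for ", yh))
    }
  }

  yd <- ds$yield
  if (!is.null(yd)) {
    num <- c("ears_ha", "grains_per_ear", "tgw_g", "yield_kg_ha")
    if (any(yd[num] <= 0, na.rm = TRUE))
      add("yield", "error", "non-positive yield component")
    if (any(yd$moisture <= 0 | yd$moisture >= 0.40, na.rm = TRUE))
      add("yield", "error", "grain moisture outside (0, 0.40)")
  }

  if (length(v)) do.call(rbind, v)
  else data.frame(table = character(), severity = character(),
                  message = character(), stringsAsFactors = FALSE)
}
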