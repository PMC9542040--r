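# Reading, validating and standardizing the Pcrit measurement database and
# the species-trait table.

.db_columns <- c(
  species = "species", pcrit = "pcrit", pcrit_unit = "pcrit_unit",
  temp_meas = "temp_meas", temp_acclim = "temp_acclim",
  salinity = "salinity", body_mass_g = "body_mass_g",
  metabolic_rate = "metabolic_rate", mr_unit = "mr_unit",
  respirometry = "respirometry", source_id = "source_id"
)
.traits_columns <- c(
  species = "species", genome_size_pg = "genome_size_pg",
  max_body_mass_g = "max_body_mass_g"
)
.mr_units <- c("umol_O2_per_h", "mg_O2_per_h", "mg_O2_per_kg_per_h",
               "umol_O2_per_g_per_h", "mg_O2_per_g_per_h")
.respirometry_levels <- c("intermittent", "closed", "unknown")

#' Read the Pcrit measurement database and species-trait table
#'
#' Reads two CSV files (UTF-8, header row): one row per respirometry
#' measurement, and one row per species with genome size and maximum body
#' mass. Rows missing a mandatory field (species, pcrit, pcrit_unit,
#' temp_meas, body_mass_g) or carrying an unknown unit token are rejected
#' with row-level diagnostics rather than silently dropped. Duplicate
#' species entries in the trait table are averaged (with a message), so a
#' trait table with multiple genome-size sources per species can be fed in
#' directly.
#'
#' The expected column names are
#' `species, pcrit, pcrit_unit, temp_meas, temp_acclim, salinity,
#' body_mass_g, metabolic_rate, mr_unit, respirometry, source_id` (database)
#' and `species, genome_size_pg, max_body_mass_g` (traits). Files using
#' other headers can be adapted through `col_map` / `traits_col_map`, named
#' character vectors mapping canonical name -> actual column name.
#'
#' @param path Path to the measurement CSV.
#' @param species_traits_path Path to the species-trait CSV.
#' @param col_map,traits_col_map Optional renaming maps (see Details).
#' @return A list of class `pcrit_db` with elements `records` (data.frame,
#'   one row per accepted measurement), `traits` (one row per species),
#'   and `rejections` (data.frame with `row` and `reason`).
#' @export
read_database <- function(path, species_traits_path,
                          col_map = NULL, traits_col_map = NULL) {
  records <- .read_csv_checked(path)
  traits <- .read_csv_checked(species_traits_path)
  records <- .apply_col_map(records, .db_columns, col_map, basename(path))
  traits <- .apply_col_map(traits, .traits_columns, traits_col_map,
                           basename(species_traits_path))
  val <- validate_records(records)
  traits <- .collapse_traits(traits)
  no_traits <- !(val$records$species %in% traits$species)
  if (any(no_traits)) {
    message(sum(no_traits), " record(s) from species absent in the trait ",
            "table; retained but flagged 'traits_missing'")
  }
  val$records$traits_missing <- no_traits
  .warn_overweight(val$records, traits)
  structure(
    list(records = val$records, traits = traits, rejections = val$rejections),
    class = "pcrit_db"
  )
}

#' @export
print.pcrit_db <- function(x, ...) {
  cat(sprintf(
    "<pcrit_db> %d records, %d species in trait table, %d rejected row(s)\n",
    nrow(x$records), nrow(x$traits), nrow(x$rejections)
  ))
  invisible(x)
}

.read_csv_checked <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

.apply_col_map <- function(df, canonical, map, label) {
  if (!is.null(map)) {
    for (canon in names(map)) {
      i <- match(map[[canon]], names(df))
      if (is.na(i)) {
        stop("column '", map[[canon]], "' (mapped to '", canon,
             "') not found in ", label, call. = FALSE)
      }
      names(df)[i] <- canon
    }
  }
  missing <- setdiff(canonical, names(df))
  if (length(missing)) {
    stop(label, " lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df[, canonical, drop = FALSE]
}

#' Validate raw measurement rows
#'
#' Applies the row-level acceptance rules: mandatory fields present, known
#' unit tokens, positive Pcrit and body mass, measurement temperature in
#' \[-2, 45\]. Returns accepted rows (typed, with respirometry normalized to
#' intermittent/closed/unknown) and a rejection log.
#'
#' @param records Raw data.frame with the canonical database columns.
#' @return List with `records` and `rejections`.
#' @export
validate_records <- function(records) {
  reasons <- character(0)
  rows <- integer(0)
  reject <- function(idx, why) {
    rows <<- c(rows, idx)
    reasons <<- c(reasons, why)
  }
  n <- nrow(records)
  records$respirometry[is.na(records$respirometry) |
                         records$respirometry == ""] <- "unknown"
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (is.na(r$species) || r$species == "") {
      reject(i, "missing species"); next
    }
    if (is.na(r$pcrit)) { reject(i, "missing pcrit"); next }
    if (is.na(r$pcrit_unit) || !(r$pcrit_unit %in% .pcrit_units)) {
      reject(i, paste0("unknown pcrit_unit '", r$pcrit_unit, "'")); next
    }
    if (is.na(r$temp_meas)) { reject(i, "missing temp_meas"); next }
    if (is.na(r$body_mass_g)) { reject(i, "missing body_mass_g"); next }
    if (r$pcrit <= 0) { reject(i, "pcrit must be > 0"); next }
    if (r$body_mass_g <= 0) { reject(i, "body_mass_g must be > 0"); next }
    if (r$temp_meas < -2 || r$temp_meas > 45) {
      reject(i, "temp_meas outside [-2, 45]"); next
    }
    if (!is.na(r$mr_unit) && r$mr_unit != "" &&
        !(r$mr_unit %in% .mr_units)) {
      reject(i, paste0("unknown mr_unit '", r$mr_unit, "'")); next
    }
    if (!(r$respirometry %in% .respirometry_levels)) {
      reject(i, paste0("unknown respirometry '", r$respirometry, "'")); next
    }
  }
  if (length(rows)) {
    message(length(rows), " row(s) rejected: ",
            paste0("row ", rows, " (", reasons, ")", collapse = "; "))
  }
  kept <- if (length(rows)) records[-rows, , drop = FALSE] else records
  rownames(kept) <- NULL
  list(
    records = kept,
    rejections = data.frame(row = rows, reason = reasons,
                            stringsAsFactors = FALSE)
  )
}

.collapse_traits <- function(traits) {
  if (anyNA(traits$genome_size_pg) || anyNA(traits$max_body_mass_g)) {
    stop("trait table has missing genome_size_pg or max_body_mass_g",
         call. = FALSE)
  }
  if (any(traits$genome_size_pg <= 0) || any(traits$max_body_mass_g <= 0)) {
    stop("trait values must be > 0", call. = FALSE)
  }
  if (anyDuplicated(traits$species)) {
    dup <- unique(traits$species[duplicated(traits$species)])
    message("averaging duplicate trait entries for: ",
            paste(dup, collapse = ", "))
    traits <- do.call(rbind, lapply(split(traits, traits$species), function(d) {
      data.frame(species = d$species[1],
                 genome_size_pg = mean(d$genome_size_pg),
                 max_body_mass_g = mean(d$max_body_mass_g),
                 stringsAsFactors = FALSE)
    }))
    rownames(traits) <- NULL
  }
  traits
}

.warn_overweight <- function(records, traits) {
  m <- match(records$species, traits$species)
  over <- !is.na(m) & records$body_mass_g > traits$max_body_mass_g[m]
  if (any(over)) {
    warning(sum(over), " record(s) with body mass above the species maximum ",
            "(length-weight conversions are approximate)", call. = FALSE)
  }
}

#' Resolve a salinity entry to numeric PSU
#'
#' Database entries give salinity either numerically (PSU) or as the
#' qualitative token `"seawater"`, which is mapped to the average ocean
#' salinity of 35 PSU.
#'
#' @param salinity_raw Vector of numbers and/or the token `"seawater"`
#'   (case-insensitive).
#' @return A data.frame with `salinity` (PSU) and logical
#'   `salinity_imputed`, TRUE where the token was mapped.
#' @examples
#' resolve_salinity(c("seawater", "0", "12.5"))
#' @export
resolve_salinity <- function(salinity_raw) {
  raw <- trimws(as.character(salinity_raw))
  is_token <- tolower(raw) == "seawater"
  num <- suppressWarnings(as.numeric(raw))
  bad <- !is_token & (is.na(num) & !is.na(raw) & raw != "")
  if (any(bad)) {
    stop("unparseable salinity value(s): ",
         paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
  }
  num[is_token] <- 35
  if (any(num < 0, na.rm = TRUE)) {
    stop("negative salinity is not physical", call. = FALSE)
  }
  data.frame(salinity = num, salinity_imputed = is_token)
}

#' Standardize accepted records to analysis units and covariates
#'
#' Converts every Pcrit value to kPa through the oxygen module (accounting
#' for temperature, salinity and atmospheric pressure where the unit
#' requires it), metabolic rate to umol O2/h, and derives the model
#' covariates: relative acclimation temperature (`temp_acclim - temp_meas`),
#' log10 body mass, log10 genome size, percent of maximum body mass and its
#' log10, and log10 maximum body mass.
#'
#' @param db A `pcrit_db` from [read_database()], or a list with `records`
#'   and `traits` in the same shape.
#' @param pressure_kpa Atmospheric pressure assumed for unit conversions,
#'   default 101.325 kPa (760 mmHg).
#' @param drop_missing_traits Drop (with a message) records whose species
#'   has no trait entry; if `FALSE`, such records raise an error.
#' @return A data.frame of class `pcrit_clean`, one row per measurement,
#'   with columns `species, pcrit_kpa, temp_meas, rel_acclim, salinity,
#'   salinity_imputed, body_mass_g, log10_mass, log10_gs, pct_max_mass,
#'   log10_pct, log10_maxbm, mr_umol_h, respirometry, source_id`.
#' @export
standardize <- function(db, pressure_kpa = 101.325,
                        drop_missing_traits = TRUE) {
  records <- db$records
  traits <- db$traits
  m <- match(records$species, traits$species)
  if (anyNA(m)) {
    if (!drop_missing_traits) {
      stop("species without trait entries: ",
           paste(unique(records$species[is.na(m)]), collapse = ", "),
           call. = FALSE)
    }
    message(sum(is.na(m)), " record(s) dropped: no species-trait entry")
    records <- records[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  sal <- resolve_salinity(records$salinity)
  if (anyNA(sal$salinity)) {
    stop("missing salinity cannot be standardized", call. = FALSE)
  }
  if (any(sal$salinity > 45)) {
    stop("salinity above 45 PSU outside supported range", call. = FALSE)
  }
  n <- nrow(records)
  pcrit_kpa <- numeric(n)
  for (i in seq_len(n)) {
    st <- water_state(records$temp_meas[i], sal$salinity[i], pressure_kpa)
    pcrit_kpa[i] <- to_kpa(records$pcrit[i], records$pcrit_unit[i], st)
  }
  mr <- .mr_to_umol_h(records$metabolic_rate, records$mr_unit,
                      records$body_mass_g)
  pct <- 100 * records$body_mass_g / traits$max_body_mass_g[m]
  if (any(pct > 100)) {
    warning(sum(pct > 100), " record(s) heavier than the species maximum; ",
            "pct_max_mass > 100 retained", call. = FALSE)
  }
  rel_acclim <- records$temp_acclim - records$temp_meas
  rel_acclim[is.na(rel_acclim)] <- 0
  out <- data.frame(
    species = records$species,
    pcrit_kpa = pcrit_kpa,
    temp_meas = records$temp_meas,
    rel_acclim = rel_acclim,
    salinity = sal$salinity,
    salinity_imputed = sal$salinity_imputed,
    body_mass_g = records$body_mass_g,
    log10_mass = log10(records$body_mass_g),
    log10_gs = log10(traits$genome_size_pg[m]),
    pct_max_mass = pct,
    log10_pct = log10(pct),
    log10_maxbm = log10(traits$max_body_mass_g[m]),
    mr_umol_h = mr,
    respirometry = records$respirometry,
    source_id = records$source_id,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pcrit_clean", "data.frame")
  out
}

.mr_to_umol_h <- function(value, unit, body_mass_g) {
  out <- rep(NA_real_, length(value))
  for (i in seq_along(value)) {
    if (is.na(value[i]) || is.na(unit[i]) || unit[i] == "") next
    out[i] <- switch(unit[i],
      umol_O2_per_h = value[i],
      mg_O2_per_h = value[i] * 1000 / .o2_molar_mass,
      mg_O2_per_kg_per_h =
        value[i] * (body_mass_g[i] / 1000) * 1000 / .o2_molar_mass,
      umol_O2_per_g_per_h = value[i] * body_mass_g[i],
      mg_O2_per_g_per_h = value[i] * body_mass_g[i] * 1000 / .o2_molar_mass,
      stop("unknown mr_unit '", unit[i], "' in row ", i, call. = FALSE)
    )
  }
  out
}

#' Write a cleaned table and its JSON validation report
#'
#' @param clean A `pcrit_clean` data.frame from [standardize()].
#' @param db The `pcrit_db` the table came from (for the rejection log).
#' @param csv_path,report_path Output paths.
#' @return Invisibly, the report list.
#' @export
write_clean <- function(clean, db, csv_path, report_path = NULL) {
  utils::write.csv(clean, csv_path, row.names = FALSE)
  report <- list(
    n_records = nrow(clean),
    n_species = length(unique(clean$species)),
    n_rejections = nrow(db$rejections),
    rejections = db$rejections,
    n_salinity_imputed = sum(clean$salinity_imputed),
    n_mr_missing = sum(is.na(clean$mr_umol_h))
  )
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
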