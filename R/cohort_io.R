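## Canonical data model for the monitoring study and long-format CSV IO.
##
## A cohort bundle holds five tables:
##   piglets    — one row per animal: litter, birth weight, baseline
##                hematocrit, NEC severity group, symptom onset and death time
##   vitals     — 2-second samples per (piglet, channel in HR/SPO2/STO2)
##   feeds      — enteral feed events on the 3-hour grid from 48 h
##   biomarkers — 6-hourly plasma I-FABP and SAA draws
##   necropsy   — histologic NEC score (ordinal 0-6) and jejunal I-FABP
##                densitometry per animal
##
## Time is fractional hours since birth; missing values are empty CSV cells.

COHORT_FILES <- c(
  piglets = "piglets.csv", vitals = "vitals.csv", feeds = "feeds.csv",
  biomarkers = "biomarkers.csv", necropsy = "necropsy.csv"
)

COHORT_SCHEMA <- list(
  piglets = c(
    piglet_id = "character", litter_id = "character",
    birth_weight_g = "numeric", baseline_hct = "numeric", group = "character",
    symptom_onset_h = "numeric", death_h = "numeric"
  ),
  vitals = c(
    piglet_id = "character", channel = "character",
    t_h = "numeric", value = "numeric"
  ),
  feeds = c(piglet_id = "character", t_h = "numeric", volume_ml_per_kg = "numeric"),
  biomarkers = c(
    piglet_id = "character", t_h = "numeric",
    ifabp_ng_ml = "numeric", saa_ng_ml = "numeric"
  ),
  necropsy = c(
    piglet_id = "character", nec_score = "integer", densitometry_au = "numeric"
  )
)

#' Assemble a cohort bundle from its five component tables
#'
#' Coerces each table to `data.table` with the canonical column set and order,
#' normalizes row order (by piglet, then time), and validates all invariants.
#'
#' @param piglets,vitals,feeds,biomarkers,necropsy data.frames matching the
#'   schemas in `necnirs:::COHORT_SCHEMA`.
#' @param validate run [validate_cohort()] (default `TRUE`).
#' @return A list of five data.tables with class `"nec_cohort"`.
#' @export
nec_cohort <- function(piglets, vitals, feeds, biomarkers, necropsy,
                       validate = TRUE) {
  tables <- list(
    piglets = piglets, vitals = vitals, feeds = feeds,
    biomarkers = biomarkers, necropsy = necropsy
  )
  bundle <- vector("list", length(tables))
  names(bundle) <- names(tables)
  for (nm in names(tables)) {
    tab <- as.data.table(tables[[nm]])
    schema <- COHORT_SCHEMA[[nm]]
    missing_cols <- setdiff(names(schema), names(tab))
    if (length(missing_cols)) {
      nec_abort(
        sprintf("table '%s' is missing column(s): %s",
                nm, paste(missing_cols, collapse = ", ")),
        "nec_schema_error"
      )
    }
    tab <- tab[, names(schema), with = FALSE]
    for (col in names(schema)) {
      target <- schema[[col]]
      if (target == "numeric" && !is.numeric(tab[[col]])) {
        if (is.logical(tab[[col]]) && all(is.na(tab[[col]]))) {
          set(tab, j = col, value = as.numeric(tab[[col]]))
        } else {
          nec_abort(sprintf("column '%s' of '%s' must be numeric", col, nm),
                    "nec_schema_error")
        }
      }
      if (target == "integer" && !is.integer(tab[[col]])) {
        v <- tab[[col]]
        if (is.numeric(v) && all(is.na(v) | v == floor(v))) {
          set(tab, j = col, value = as.integer(v))
        } else {
          nec_abort(sprintf("column '%s' of '%s' must be integer", col, nm),
                    "nec_schema_error")
        }
      }
      if (target == "character" && !is.character(tab[[col]])) {
        set(tab, j = col, value = as.character(tab[[col]]))
      }
    }
    bundle[[nm]] <- tab
  }
  setorder(bundle$piglets, piglet_id)
  setorder(bundle$vitals, piglet_id, channel, t_h)
  setorder(bundle$feeds, piglet_id, t_h)
  setorder(bundle$biomarkers, piglet_id, t_h)
  setorder(bundle$necropsy, piglet_id)
  class(bundle) <- "nec_cohort"
  if (validate) validate_cohort(bundle)
  bundle
}

#' @export
print.nec_cohort <- function(x, ...) {
  counts <- x$piglets[, .N, by = group]
  cat("<nec_cohort>", nrow(x$piglets), "piglets (",
      paste(sprintf("%s:%d", counts$group, counts$N), collapse = ", "), ")\n")
  cat(sprintf("  vitals: %s samples | feeds: %d | biomarker draws: %d | necropsy: %d\n",
              format(nrow(x$vitals), big.mark = ","), nrow(x$feeds),
              nrow(x$biomarkers), nrow(x$necropsy)))
  invisible(x)
}

row_err <- function(table, rows, msg) {
  nec_abort(
    sprintf("%s: %s (row %s)", table, msg,
            paste(head(rows, 5L), collapse = ", ")),
    "nec_validation_error"
  )
}

check_fk <- function(tab, nm, ids) {
  orphan <- !(tab$piglet_id %in% ids)
  if (any(orphan)) {
    nec_abort(
      sprintf("%s: piglet_id '%s' not present in piglets table (row %d)",
              nm, tab$piglet_id[which(orphan)[1L]], which(orphan)[1L]),
      "nec_referential_error"
    )
  }
}

#' Validate a cohort bundle against the study-design invariants
#'
#' Checks schemas, enumerations, value ranges, referential integrity
#' (`piglet_id` foreign keys), per-channel strict time ordering, the feed grid
#' (3-hourly from 48 h), the 6-hour biomarker grid with at most one draw per
#' time, censoring consistency (vitals and feeds strictly before `death_h`,
#' biomarker draws at or before it), and group/outcome coherence (symptom
#' onset implies NEC; fulminant NEC implies a recorded death; No-NEC implies
#' histologic score <= 1).
#'
#' @param bundle a `"nec_cohort"` object (or plain list of the five tables).
#' @return the bundle, invisibly. Raises classed conditions
#'   (`nec_schema_error`, `nec_referential_error`, `nec_validation_error`)
#'   citing the offending table and row.
#' @export
validate_cohort <- function(bundle) {
  p <- bundle$piglets
  if (anyDuplicated(p$piglet_id)) {
    row_err("piglets", which(duplicated(p$piglet_id)), "duplicate piglet_id")
  }
  bad <- which(!(p$group %in% GROUPS))
  if (length(bad)) row_err("piglets", bad, "group must be F_NEC/NF_NEC/NO_NEC")
  bad <- which(!(p$birth_weight_g > 0))
  if (length(bad)) row_err("piglets", bad, "birth_weight_g must be > 0")
  bad <- which(!(p$baseline_hct > 0 & p$baseline_hct <= 100))
  if (length(bad)) row_err("piglets", bad, "baseline_hct must lie in (0,100]")
  bad <- which(!is.na(p$symptom_onset_h) &
                 (p$symptom_onset_h < 48 | p$symptom_onset_h > 96))
  if (length(bad)) row_err("piglets", bad, "symptom_onset_h must lie in [48,96]")
  bad <- which(!is.na(p$death_h) & (p$death_h <= 0 | p$death_h > 96))
  if (length(bad)) row_err("piglets", bad, "death_h must lie in (0,96]")
  bad <- which(!is.na(p$symptom_onset_h) & p$group == "NO_NEC")
  if (length(bad)) row_err("piglets", bad, "NO_NEC piglets cannot have symptom_onset_h")
  bad <- which(!is.na(p$death_h) & !is.na(p$symptom_onset_h) &
                 p$death_h < p$symptom_onset_h)
  if (length(bad)) row_err("piglets", bad, "death_h must be >= symptom_onset_h")
  bad <- which(p$group == "F_NEC" & is.na(p$death_h))
  if (length(bad)) row_err("piglets", bad, "F_NEC piglets must have death_h")

  ids <- p$piglet_id
  death_of <- function(tab) p$death_h[match(tab$piglet_id, ids)]

  v <- bundle$vitals
  if (nrow(v)) {
    check_fk(v, "vitals", ids)
    if (!all(v$channel %in% CHANNELS)) {
      row_err("vitals", which(!(v$channel %in% CHANNELS)),
              "channel must be HR/SPO2/STO2")
    }
    if (any(v$t_h < 0)) row_err("vitals", which(v$t_h < 0), "t_h must be >= 0")
    ## strict increase within (piglet, channel); table is sorted, so a
    ## non-positive first difference marks the offending row
    ord <- v[, .(first_bad = {
      w <- which(diff(t_h) <= 0)
      if (length(w)) .I[w[1L] + 1L] else NA_integer_
    }), by = .(piglet_id, channel)]
    if (any(!is.na(ord$first_bad))) {
      row_err("vitals", ord$first_bad[!is.na(ord$first_bad)],
              "t_h not strictly increasing within (piglet_id, channel)")
    }
    hr <- v$channel == "HR"
    ok <- ifelse(hr, v$value > 0 & v$value <= 400,
                 v$value >= 0 & v$value <= 100)
    if (!all(ok)) {
      row_err("vitals", which(!ok), "value outside channel bounds")
    }
    dh <- death_of(v)
    late <- !is.na(dh) & v$t_h >= dh
    if (any(late)) row_err("vitals", which(late), "vitals sample at/after death_h")
  }

  f <- bundle$feeds
  if (nrow(f)) {
    check_fk(f, "feeds", ids)
    on_grid <- f$t_h >= 48 & f$t_h <= 93 &
      abs((f$t_h - 48) / 3 - round((f$t_h - 48) / 3)) < 1e-9
    if (any(!on_grid)) {
      row_err("feeds", which(!on_grid), "feeds must fall on 48,51,...,93 h")
    }
    bad <- which(f$volume_ml_per_kg < 0)
    if (length(bad)) row_err("feeds", bad, "volume_ml_per_kg must be >= 0")
    dh <- death_of(f)
    bad <- which(!is.na(dh) & f$t_h >= dh)
    if (length(bad)) row_err("feeds", bad, "feed event at/after death_h")
  }

  b <- bundle$biomarkers
  if (nrow(b)) {
    check_fk(b, "biomarkers", ids)
    on_grid <- b$t_h >= 0 & b$t_h <= 96 &
      abs(b$t_h / 6 - round(b$t_h / 6)) < 1e-9
    if (any(!on_grid)) {
      row_err("biomarkers", which(!on_grid),
              "draws must fall on the 6-h grid in [0,96]")
    }
    dup <- which(duplicated(b[, .(piglet_id, t_h)]))
    if (length(dup)) row_err("biomarkers", dup, "duplicate draw for (piglet_id, t_h)")
    bad <- which(b$ifabp_ng_ml < 0 | b$saa_ng_ml < 0)
    if (length(bad)) row_err("biomarkers", bad, "analyte values must be >= 0")
    dh <- death_of(b)
    bad <- which(!is.na(dh) & b$t_h > dh)
    if (length(bad)) row_err("biomarkers", bad, "biomarker draw after death_h")
  }

  n <- bundle$necropsy
  if (nrow(n)) {
    check_fk(n, "necropsy", ids)
    if (anyDuplicated(n$piglet_id)) {
      row_err("necropsy", which(duplicated(n$piglet_id)), "duplicate necropsy record")
    }
    bad <- which(is.na(n$nec_score) | n$nec_score < 0L | n$nec_score > 6L)
    if (length(bad)) row_err("necropsy", bad, "nec_score must be an integer in 0..6")
    bad <- which(n$densitometry_au < 0)
    if (length(bad)) row_err("necropsy", bad, "densitometry_au must be >= 0")
    grp <- p$group[match(n$piglet_id, ids)]
    bad <- which(grp == "NO_NEC" & n$nec_score > 1L)
    if (length(bad)) row_err("necropsy", bad, "NO_NEC piglets must have nec_score <= 1")
  }
  invisible(bundle)
}

#' Read a cohort bundle from a directory of long-format CSV files
#'
#' Expects `piglets.csv`, `vitals.csv`, `feeds.csv`, `biomarkers.csv` and
#' `necropsy.csv` (headers mandatory; empty cells encode missing values).
#' Row order is normalized by (piglet_id, time) and all invariants are
#' enforced via [validate_cohort()].
#'
#' @param dir directory containing the five CSV files.
#' @return a validated `"nec_cohort"` bundle.
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, COHORT_FILES)
  names(paths) <- names(COHORT_FILES)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    nec_abort(paste0("missing cohort file(s): ", paste(missing, collapse = ", ")),
              "nec_io_error")
  }
  tables <- lapply(names(paths), function(nm) {
    schema <- COHORT_SCHEMA[[nm]]
    hdr <- names(fread(paths[[nm]], nrows = 0L, header = TRUE))
    missing_cols <- setdiff(names(schema), hdr)
    if (length(missing_cols)) {
      nec_abort(
        sprintf("%s is missing column(s): %s", basename(paths[[nm]]),
                paste(missing_cols, collapse = ", ")),
        "nec_schema_error"
      )
    }
    classes <- ifelse(schema == "integer", "integer",
                      ifelse(schema == "character", "character", "numeric"))
    names(classes) <- names(schema)
    fread(paths[[nm]], na.strings = "", colClasses = classes, header = TRUE)
  })
  names(tables) <- names(paths)
  nec_cohort(tables$piglets, tables$vitals, tables$feeds, tables$biomarkers,
             tables$necropsy)
}

#' Write a cohort bundle to a directory of CSV files
#'
#' Missing values are written as empty cells; numeric fields are emitted so
#' that `read_cohort(write_cohort(b))` reproduces `b` field-for-field.
#'
#' @param bundle a validated `"nec_cohort"` bundle.
#' @param dir output directory (created if needed).
#' @return named character vector of the five file paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) nec_abort(sprintf("cannot create directory '%s'", dir), "nec_io_error")
  }
  if (file.access(dir, mode = 2L) != 0L) {
    nec_abort(sprintf("directory '%s' is not writable", dir), "nec_io_error")
  }
  paths <- file.path(dir, COHORT_FILES)
  names(paths) <- names(COHORT_FILES)
  for (nm in names(paths)) {
    fwrite(bundle[[nm]], paths[[nm]], na = "", quote = FALSE)
  }
  invisible(paths)
}
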