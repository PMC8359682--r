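#' Canonical gas-exchange CSV columns
#'
#' Mandatory columns of the canonical long-format gas-exchange file: one row
#' per chamber observation, grouped into curves by `sample_id`.
#' @export
gas_exchange_columns <- c(
  "sample_id", "species", "season", "leaf_area_cm2", "co2_ref_ppm",
  "A_umol_m2_s", "Ci_ppm", "gsw_mol_m2_s", "Tleaf_C", "Q_umol_m2_s",
  "P_Pa", "rh_pct")

#' Study species and their functional-type assignments
#'
#' The six temperate/boreal woody species of the study design, with
#' functional type (deciduous/evergreen x broadleaf/conifer) and successional
#' status (primary = early/mid successional, climax = late successional).
#'
#' @return A data.frame with columns `species`, `functional_type`,
#'   `succession`.
#' @export
study_species <- function() {
  data.frame(
    species = c("Betula pendula", "Quercus robur", "Larix decidua",
                "Pinus sylvestris", "Picea abies", "Vaccinium vitis-idaea"),
    functional_type = c("deciduous-broadleaf", "deciduous-broadleaf",
                        "deciduous-conifer", "evergreen-conifer",
                        "evergreen-conifer", "evergreen-broadleaf"),
    succession = c("primary", "primary", "primary", "primary",
                   "climax", "climax"),
    stringsAsFactors = FALSE)
}

season_levels <- c("early", "mid", "late")

#' One leaf's A/Ci curve
#'
#' Bundles the ordered chamber records of a single leaf with its sample
#' metadata. Records are stored in acquisition order; the fitter sorts by Ci
#' internally and the "first 400-p.p.m. record" convention refers to
#' acquisition order.
#'
#' @param sample_id unique sample identifier.
#' @param species species name; if one of the study species, functional type
#'   and succession are filled in automatically.
#' @param season one of `"early"`, `"mid"`, `"late"`.
#' @param records data.frame with the per-record columns of
#'   [gas_exchange_columns] (`co2_ref_ppm` .. `rh_pct`).
#' @param leaf_area_cm2 projected leaf area in the chamber (cm2).
#' @param functional_type,succession overrides for non-study species.
#' @return An object of class `aci_curve`.
#' @export
aci_curve <- function(sample_id, species, season, records,
                      leaf_area_cm2 = NA_real_, functional_type = NULL,
                      succession = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  season <- match.arg(season, season_levels)
  needed <- setdiff(gas_exchange_columns,
                    c("sample_id", "species", "season", "leaf_area_cm2"))
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(records$Ci_ppm)) || any(records$Ci_ppm <= 0))
    stop("all Ci values must be positive")
  if (any(records$P_Pa <= 0)) stop("atmospheric pressure must be positive")
  sp <- study_species()
  i <- match(species, sp$species)
  if (is.null(functional_type))
    functional_type <- if (!is.na(i)) sp$functional_type[i] else NA_character_
  if (is.null(succession))
    succession <- if (!is.na(i)) sp$succession[i] else NA_character_
  structure(list(sample_id = sample_id, species = species, season = season,
                 functional_type = functional_type, succession = succession,
                 leaf_area_cm2 = leaf_area_cm2,
                 records = records[, needed, drop = FALSE]),
            class = "aci_curve")
}

#' @export
print.aci_curve <- function(x, ...) {
  cat(sprintf("A/Ci curve %s: %s (%s, %s), %d records\n", x$sample_id,
              x$species, x$functional_type, x$season, nrow(x$records)))
  invisible(x)
}

#' Read a canonical gas-exchange CSV into A/Ci curves
#'
#' Rows are grouped by `sample_id`; within a curve, acquisition order is the
#' file order. A missing mandatory column is a hard error naming the column;
#' rows with non-numeric or non-positive `Ci`/`P` are skipped with a logged
#' line number. A validation summary is attached as attribute `"validation"`.
#'
#' @param path CSV file path.
#' @return A (possibly empty) list of [aci_curve()] objects.
#' @export
read_gas_exchange <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(gas_exchange_columns, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    warning("gas-exchange file contains only a header: empty curve list")
    out <- list()
    attr(out, "validation") <- list(n_rows = 0L, skipped = integer(0))
    return(out)
  }
  num_cols <- setdiff(gas_exchange_columns,
                      c("sample_id", "species", "season"))
  for (cl in num_cols) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  bad <- !is.finite(df$Ci_ppm) | df$Ci_ppm <= 0 | !is.finite(df$P_Pa) |
    df$P_Pa <= 0 | !is.finite(df$A_umol_m2_s)
  if (any(bad)) {
    message("skipping ", sum(bad), " malformed row(s) at line(s): ",
            paste(utils::head(which(bad) + 1L, 10), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  curves <- lapply(split(df, factor(df$sample_id, unique(df$sample_id))),
    function(g) {
      aci_curve(g$sample_id[1], g$species[1], g$season[1], g,
                leaf_area_cm2 = g$leaf_area_cm2[1])
    })
  curves <- unname(curves)
  attr(curves, "validation") <- list(
    n_rows = nrow(df), skipped = which(bad),
    duplicate_steps = sum(duplicated(df[, c("sample_id", "co2_ref_ppm")])))
  curves
}

#' Write A/Ci curves to the canonical gas-exchange CSV
#'
#' @param curves a list of [aci_curve()] objects, or an already-flat
#'   data.frame with the canonical columns.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_gas_exchange <- function(curves, path) {
  df <- if (is.data.frame(curves)) curves else curves_to_df(curves)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

curves_to_df <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    rec <- cv$records
    cbind(data.frame(sample_id = cv$sample_id, species = cv$species,
                     season = cv$season, leaf_area_cm2 = cv$leaf_area_cm2,
                     stringsAsFactors = FALSE),
          rec)[, gas_exchange_columns]
  }))
}
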