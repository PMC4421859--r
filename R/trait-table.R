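# Trait-table ingestion, unit conversion, genus averaging, and
# representative-genome selection.

TAXON_GROUPS <- c("mammal", "bird", "ectothermic_vertebrate", "insect",
                  "protozoan", "prokaryote")

#' Read an organism trait table
#'
#' Reads a CSV/TSV table of per-species ecological and physiological
#' measurements. Recognised columns: `species`, `genus`, `taxon_group`,
#' `mass_g`, `rate_W`, `q_W_per_g`, `temp_C`, `lifespan_y`, `volant`,
#' `fossorial`, `foraging_env`, `daily_activity`, `genome_code`,
#' `genome_bp`, `genome_year`. Missing values are empty fields. Units are
#' fixed by the column names: grams, watts, watts per gram, degrees
#' Celsius, years.
#'
#' @param path File path; the delimiter is chosen from the extension
#'   (`.csv` vs anything else, read as tab-separated).
#' @return A validated trait tibble.
#' @export
read_trait_table <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  out <- reader(path, na = c("", "NA"), show_col_types = FALSE, progress = FALSE)
  validate_traits(out)
}

validate_traits <- function(data) {
  need <- c("species", "genus", "taxon_group", "mass_g")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Trait table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  bad_taxon <- setdiff(unique(data$taxon_group), c(TAXON_GROUPS, NA))
  if (length(bad_taxon) > 0L) {
    abort(sprintf("Unknown taxon_group value(s): %s. Expected one of: %s",
                  paste(bad_taxon, collapse = ", "),
                  paste(TAXON_GROUPS, collapse = ", ")))
  }
  check_pos <- function(col) {
    if (col %in% names(data) && any(!is.na(data[[col]]) & data[[col]] <= 0)) {
      abort(sprintf("`%s` must be positive where present.", col))
    }
  }
  check_pos("mass_g"); check_pos("q_W_per_g"); check_pos("lifespan_y")
  check_pos("rate_W"); check_pos("genome_bp")
  as_tibble(data)
}

#' Write a trait table to TSV
#' @param data Trait tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(data, path) {
  readr::write_tsv(data, path, na = "")
  invisible(path)
}

MASS_FACTORS <- c(g = 1, kg = 1e3, mg = 1e-3, ug = 1e-6, "µg" = 1e-6,
                  pg = 1e-12)
RATE_FACTORS <- c(W = 1, mW = 1e-3, uW = 1e-6, "µW" = 1e-6)

convert_with_factors <- function(x, unit, factors, what) {
  unit <- rep_len(as.character(unit), length(x))
  bad <- !is.na(x) & !(unit %in% names(factors))
  if (any(bad)) {
    abort(sprintf("Unknown %s unit(s): %s", what,
                  paste(unique(unit[bad]), collapse = ", ")))
  }
  x * unname(factors[unit])
}

#' Unit conversions to the canonical trait units
#'
#' Canonical units are grams (mass), watts (metabolic rate), watts per gram
#' (mass-specific rate), degrees Celsius (temperature) and years (lifespan).
#'
#' @param x Numeric vector of values.
#' @param unit Unit string(s): mass `g`/`kg`/`mg`/`ug`/`pg`; rate
#'   `W`/`mW`/`uW`; temperature `C` (or `°C`) / `K`.
#' @return Numeric vector in canonical units.
#' @export
convert_mass <- function(x, unit) convert_with_factors(x, unit, MASS_FACTORS, "mass")

#' @rdname convert_mass
#' @export
convert_rate <- function(x, unit) convert_with_factors(x, unit, RATE_FACTORS, "rate")

#' @rdname convert_mass
#' @export
convert_temperature <- function(x, unit) {
  unit <- rep_len(as.character(unit), length(x))
  unit_norm <- sub("^°", "", unit)
  bad <- !is.na(x) & !(unit_norm %in% c("C", "K"))
  if (any(bad)) {
    abort(sprintf("Unknown temperature unit(s): %s",
                  paste(unique(unit[bad]), collapse = ", ")))
  }
  ifelse(unit_norm == "K", x - 273.15, x)
}

#' Convert a raw trait table with unit columns to canonical units
#'
#' Looks for value/unit column pairs -- `mass` + `mass_unit`, `rate` +
#' `rate_unit`, `temp` + `temp_unit` -- and produces `mass_g`, `rate_W`,
#' `temp_C`. Unknown units raise an error naming the offending records.
#'
#' @param data A data frame with value and `*_unit` columns.
#' @return The tibble with canonical-unit columns added.
#' @export
convert_units <- function(data) {
  data <- as_tibble(data)
  pairs <- list(
    c("mass", "mass_unit", "mass_g", "convert_mass"),
    c("rate", "rate_unit", "rate_W", "convert_rate"),
    c("temp", "temp_unit", "temp_C", "convert_temperature")
  )
  for (p in pairs) {
    if (all(p[1:2] %in% names(data))) {
      fun <- get(p[4], mode = "function")
      data[[p[3]]] <- fun(data[[p[1]]], data[[p[2]]])
    }
  }
  data
}

#' Derive mass-specific metabolic rate
#'
#' Mass-specific metabolic rate is metabolic rate per unit body mass
#' (W/g).
#'
#' @param rate_W Metabolic rate in watts (positive).
#' @param mass_g Body mass in grams (positive).
#' @return Mass-specific rate in W/g.
#' @export
derive_mass_specific <- function(rate_W, mass_g) {
  if (any(!is.na(mass_g) & mass_g <= 0)) {
    abort("`mass_g` must be positive.")
  }
  if (any(!is.na(rate_W) & rate_W <= 0)) {
    abort("`rate_W` must be positive.")
  }
  rate_W / mass_g
}

#' Fill or check the mass-specific rate column of a trait table
#'
#' Where `q_W_per_g` is present alongside `rate_W` and `mass_g`, the
#' recomputed quotient must agree within `tolerance` (relative); conflicts
#' are reported with a warning naming the species. Missing `q_W_per_g`
#' values are filled from the quotient where possible.
#'
#' @param data Trait tibble.
#' @param tolerance Relative tolerance for agreement (default 1e-6).
#' @return The tibble with a complete-as-possible `q_W_per_g` column.
#' @export
add_mass_specific <- function(data, tolerance = 1e-6) {
  data <- as_tibble(data)
  if (!"q_W_per_g" %in% names(data)) {
    data$q_W_per_g <- NA_real_
  }
  if (!all(c("rate_W", "mass_g") %in% names(data))) {
    return(data)
  }
  derivable <- !is.na(data$rate_W) & !is.na(data$mass_g)
  q_new <- rep(NA_real_, nrow(data))
  q_new[derivable] <- derive_mass_specific(data$rate_W[derivable],
                                           data$mass_g[derivable])
  both <- derivable & !is.na(data$q_W_per_g)
  rel <- abs(q_new[both] - data$q_W_per_g[both]) / data$q_W_per_g[both]
  if (any(rel > tolerance)) {
    conflicted <- data$species[both][rel > tolerance]
    warn(sprintf("Recomputed q conflicts with the recorded value for: %s",
                 paste(conflicted, collapse = ", ")))
  }
  fill <- derivable & is.na(data$q_W_per_g)
  data$q_W_per_g[fill] <- q_new[fill]
  data
}

GENUS_NUMERIC_COLS <- c("mass_g", "rate_W", "q_W_per_g", "temp_C",
                        "lifespan_y", "genome_bp")
GENUS_FLAG_COLS <- c("volant", "fossorial", "foraging_env", "daily_activity")

#' Average species-level traits within each genus
#'
#' Collapses a species-level trait table to one row per genus by averaging
#' the biological parameters (mass, metabolic rate, mass-specific rate,
#' temperature, lifespan) across the genus's species. A parameter missing
#' in some members is averaged over the members that have it, and is absent
#' at genus level only when absent in every member. `taxon_group` must be
#' uniform within a genus. Categorical mode-of-life flags are kept when
#' uniform and otherwise set to `NA` with a warning. Averaging is
#' arithmetic by default; `geometric = TRUE` switches to geometric means
#' for sensitivity analysis.
#'
#' Genome fields are not averaged here; use [select_representative()] /
#' [collapse_to_genus()] to attach one representative genome per genus.
#'
#' @param data Species-level trait tibble.
#' @param geometric Use geometric instead of arithmetic means.
#' @return A tibble with one row per genus (plus `n_species`).
#' @export
genus_average <- function(data, geometric = FALSE) {
  data <- validate_traits(data)
  avg <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      return(NA_real_)
    }
    if (isTRUE(geometric)) exp(mean(log(v))) else mean(v)
  }
  uniform_or_na <- function(v, genus, col) {
    u <- unique(v[!is.na(v)])
    if (length(u) == 1L) {
      return(u)
    }
    if (length(u) > 1L) {
      warn(sprintf("`%s` is not uniform within genus %s; set to NA.", col, genus))
    }
    v[NA_integer_]
  }
  data |>
    dplyr::group_by(.data$genus) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      taxa <- unique(g$taxon_group)
      if (length(taxa) != 1L) {
        abort(sprintf("Conflicting taxon_group within genus %s: %s",
                      g$genus[1], paste(taxa, collapse = ", ")))
      }
      row <- tibble(genus = g$genus[1], taxon_group = taxa,
                    n_species = nrow(g))
      for (col in intersect(GENUS_NUMERIC_COLS, names(g))) {
        row[[col]] <- avg(g[[col]])
      }
      for (col in intersect(GENUS_FLAG_COLS, names(g))) {
        row[[col]] <- uniform_or_na(g[[col]], g$genus[1], col)
      }
      row
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$genus)
}

#' Select the representative genome of a genus
#'
#' Among candidate genomes, picks the one whose genome was completely
#' determined earliest; ties on year are broken lexicographically by genome
#' code (reported via a message).
#'
#' @param candidates A data frame with columns `genome_code` and
#'   `genome_year` (one row per candidate species).
#' @return The selected genome code (length-1 character).
#' @export
select_representative <- function(candidates) {
  if (!all(c("genome_code", "genome_year") %in% names(candidates))) {
    abort("`candidates` must have columns genome_code and genome_year.")
  }
  cand <- candidates[!is.na(candidates$genome_year) &
                       !is.na(candidates$genome_code), , drop = FALSE]
  if (nrow(cand) == 0L) {
    abort("No candidate has a completion year; cannot select a representative genome.")
  }
  earliest <- cand[cand$genome_year == min(cand$genome_year), , drop = FALSE]
  codes <- sort(earliest$genome_code)
  if (length(codes) > 1L) {
    inform(sprintf("Year tie (%d) among %s; selected '%s' lexicographically.",
                   earliest$genome_year[1], paste(codes, collapse = ", "),
                   codes[1]))
  }
  codes[1]
}

#' Collapse a species-level trait table to analysis-ready genus rows
#'
#' Runs [genus_average()] and attaches, per genus, the representative
#' genome chosen by [select_representative()] (its `genome_code`,
#' `genome_bp`, `genome_year`, and the representative species name).
#' Genera without any dated genome get `NA` genome fields with a warning.
#'
#' @inheritParams genus_average
#' @return A genus-level trait tibble.
#' @export
collapse_to_genus <- function(data, geometric = FALSE) {
  data <- validate_traits(data)
  has_genome <- all(c("genome_code", "genome_year") %in% names(data))
  avg <- genus_average(
    dplyr::select(data, -dplyr::any_of(c("genome_bp"))),
    geometric = geometric
  )
  if (!has_genome) {
    return(avg)
  }
  reps <- data |>
    dplyr::group_by(.data$genus) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      ok <- !is.na(g$genome_year) & !is.na(g$genome_code)
      if (!any(ok)) {
        warn(sprintf("Genus %s has no dated genome; genome fields set to NA.",
                     g$genus[1]))
        return(tibble(genus = g$genus[1], species = NA_character_,
                      genome_code = NA_character_, genome_bp = NA_real_,
                      genome_year = NA_integer_))
      }
      code <- select_representative(g[ok, , drop = FALSE])
      rep_row <- g[which(g$genome_code == code)[1], , drop = FALSE]
      tibble(
        genus = g$genus[1],
        species = rep_row$species,
        genome_code = code,
        genome_bp = if ("genome_bp" %in% names(g)) rep_row$genome_bp else NA_real_,
        genome_year = as.integer(rep_row$genome_year)
      )
    }) |>
    dplyr::bind_rows()
  dplyr::left_join(avg, reps, by = "genus") |>
    dplyr::relocate("species", .after = "genus")
}
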