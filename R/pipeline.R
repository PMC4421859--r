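# End-to-end orchestration: ingest -> profile -> temperature-correct ->
# correlate -> report.

# One labelled correlation row (simple or one-controller partial) computed
# on the complete cases of the involved columns.
cor_row <- function(data, label, x, y, control = NULL) {
  cols <- c(x, y, control)
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  sub <- data[cc, , drop = FALSE]
  res <- tryCatch(
    if (is.null(control)) {
      spearman(sub[[x]], sub[[y]], p_method = "t")
    } else {
      partial_spearman(sub[[x]], sub[[y]], sub[[control]], p_method = "t")
    },
    error = function(e) {
      # degenerate at small n (e.g. a controller rank-identical to a
      # variable): report the comparison as unavailable rather than failing
      # the whole report
      warn(sprintf("Correlation '%s' unavailable: %s", label,
                   conditionMessage(e)))
      list(r = NA_real_, p = NA_real_, n = nrow(sub))
    }
  )
  tibble(
    comparison = label, x = x, y = y,
    controlled = control %||% NA_character_,
    r = res$r, p = res$p, n = res$n
  )
}

join_profiles <- function(traits, profiles, oxic_label = "Oxic metabolism") {
  wide <- if ("category" %in% names(profiles)) {
    profiles_wide(profiles)
  } else {
    profiles
  }
  if (!"organism" %in% names(wide)) {
    abort("`profiles` must identify organisms (an `organism` column).")
  }
  if (!oxic_label %in% names(wide)) {
    abort(sprintf("`profiles` lacks the '%s' pseudo-category.", oxic_label))
  }
  joined <- dplyr::inner_join(traits, wide,
                              by = c(genome_code = "organism"))
  list(
    data = joined,
    category_cols = setdiff(names(wide), "organism")
  )
}

#' Metabolic-rate analysis: genome size, oxic genes and the category screen
#'
#' Reproduces the metabolic-rate analysis plan on a joined trait + profile
#' table: simple and body-mass-controlled partial Spearman correlations of
#' mass-specific metabolic rate against genome size, body mass and the oxic
#' gene proportion; the full functional-category screen; and
#' temperature-corrected variants of the oxic and genome-size correlations
#' restricted to the temperature-eligible organisms (endotherm-referenced
#' targets exclude ectothermic vertebrates and organisms without a
#' measurement temperature).
#'
#' @param traits Genus- or species-level trait tibble with `q_W_per_g`,
#'   `mass_g`, `genome_bp`, `genome_code`, `taxon_group`, `temp_C`.
#' @param profiles Functional profiles: long (from [compute_profile()] /
#'   [generate_panel()]) or wide ([profiles_wide()]). Must include the
#'   `"Oxic metabolism"` pseudo-category.
#' @param alpha Screen retention threshold on the partial p-value.
#' @param target_temperatures Temperatures (deg C) at which to evaluate the
#'   corrected rates (default 25 and 10).
#' @param temperature_method `"q10_style"` (doubling per 10 deg C) or
#'   `"boltzmann"` (Boltzmann-Arrhenius with `activation_energy`).
#' @param activation_energy Activation energy in eV for the Boltzmann
#'   method.
#' @return A list with `n`, `core` (labelled correlation tibble), `screen`
#'   (all categories with `retained` flags) and `temperature` (a list per
#'   target temperature with its own `core` and `screen`).
#' @export
run_metabolic_analysis <- function(traits, profiles, alpha = 0.05,
                                   target_temperatures = c(25, 10),
                                   temperature_method = c("q10_style",
                                                          "boltzmann"),
                                   activation_energy = 0.65) {
  temperature_method <- match.arg(temperature_method)
  jp <- join_profiles(traits, profiles)
  data <- jp$data
  if (nrow(data) < 4L) {
    abort("Joined trait/profile table has fewer than 4 rows.")
  }
  data$oxic_proportion <- data[["Oxic metabolism"]]

  core <- dplyr::bind_rows(
    cor_row(data, "q_vs_genome_size", "q_W_per_g", "genome_bp"),
    cor_row(data, "q_vs_genome_size_given_mass", "q_W_per_g", "genome_bp",
            "mass_g"),
    cor_row(data, "q_vs_mass", "q_W_per_g", "mass_g"),
    cor_row(data, "q_vs_mass_given_genome_size", "q_W_per_g", "mass_g",
            "genome_bp"),
    cor_row(data, "mass_vs_genome_size", "mass_g", "genome_bp"),
    cor_row(data, "q_vs_oxic", "q_W_per_g", "oxic_proportion"),
    cor_row(data, "oxic_vs_mass", "oxic_proportion", "mass_g"),
    cor_row(data, "q_vs_oxic_given_mass", "q_W_per_g", "oxic_proportion",
            "mass_g"),
    cor_row(data, "q_vs_mass_given_oxic", "q_W_per_g", "mass_g",
            "oxic_proportion")
  )

  screen <- correlation_screen(
    data[, jp$category_cols, drop = FALSE],
    q = data$q_W_per_g, mass = data$mass_g, alpha = alpha, keep_all = TRUE
  )

  correct <- function(q, t, x) {
    if (temperature_method == "q10_style") {
      q10_style_correct(q, t, x)
    } else {
      boltzmann_correct(q, t, x, activation_energy = activation_energy)
    }
  }
  eligible <- filter_temperature_eligible(data)
  temperature <- lapply(target_temperatures, function(x_target) {
    sub <- eligible
    sub$q_corrected <- correct(sub$q_W_per_g, sub$temp_C, x_target)
    if (sum(stats::complete.cases(sub[, c("q_corrected", "mass_g")])) < 4L) {
      return(list(target = x_target, method = temperature_method,
                  n = nrow(sub), core = NULL, screen = NULL))
    }
    list(
      target = x_target,
      method = temperature_method,
      n = nrow(sub),
      core = dplyr::bind_rows(
        cor_row(sub, "q_corrected_vs_oxic", "q_corrected", "oxic_proportion"),
        cor_row(sub, "q_corrected_vs_oxic_given_mass", "q_corrected",
                "oxic_proportion", "mass_g"),
        cor_row(sub, "q_corrected_vs_genome_size", "q_corrected",
                "genome_bp"),
        cor_row(sub, "q_corrected_vs_genome_size_given_mass", "q_corrected",
                "genome_bp", "mass_g"),
        cor_row(sub, "q_corrected_vs_mass_given_oxic", "q_corrected",
                "mass_g", "oxic_proportion")
      ),
      screen = correlation_screen(
        sub[, jp$category_cols, drop = FALSE],
        q = sub$q_corrected, mass = sub$mass_g, alpha = alpha,
        keep_all = TRUE
      )
    )
  })
  names(temperature) <- paste0("T", target_temperatures)

  list(n = nrow(data), core = core, screen = screen,
       temperature = temperature)
}

#' Lifespan analysis: oxic genes, genome size and mode-of-life subgroups
#'
#' Body-mass-controlled partial Spearman correlations of maximal lifespan
#' against the oxic gene proportion, genome size, and every functional
#' category, plus the flight-capability (volant/non-volant) subgroup
#' analysis of the oxic-lifespan association.
#'
#' @inheritParams run_metabolic_analysis
#' @return A list with `n` (organisms with lifespan data), `core`,
#'   `screen` (categories against lifespan, mass-controlled) and
#'   `subgroups` (per volancy level).
#' @export
run_lifespan_analysis <- function(traits, profiles, alpha = 0.05) {
  jp <- join_profiles(traits, profiles)
  data <- jp$data[!is.na(jp$data$lifespan_y), , drop = FALSE]
  if (nrow(data) < 4L) {
    abort("Fewer than 4 organisms with lifespan data.")
  }
  data$oxic_proportion <- data[["Oxic metabolism"]]

  core <- dplyr::bind_rows(
    cor_row(data, "lifespan_vs_oxic", "lifespan_y", "oxic_proportion"),
    cor_row(data, "lifespan_vs_mass", "lifespan_y", "mass_g"),
    cor_row(data, "lifespan_vs_oxic_given_mass", "lifespan_y",
            "oxic_proportion", "mass_g"),
    cor_row(data, "lifespan_vs_mass_given_oxic", "lifespan_y", "mass_g",
            "oxic_proportion"),
    cor_row(data, "lifespan_vs_genome_size_given_mass", "lifespan_y",
            "genome_bp", "mass_g")
  )
  screen <- correlation_screen(
    data[, jp$category_cols, drop = FALSE],
    q = data$lifespan_y, mass = data$mass_g, alpha = alpha, keep_all = TRUE
  )
  subgroups <- if ("volant" %in% names(data)) {
    subgroup_partial(data, "oxic_proportion", "lifespan_y", "mass_g",
                     "volant", p_method = "t")
  } else {
    NULL
  }
  list(n = nrow(data), core = core, screen = screen, subgroups = subgroups)
}

#' Run the full comparative analysis pipeline
#'
#' Chains the stages of the comparative analysis: fill mass-specific rates,
#' collapse species to genus means with one representative genome per genus,
#' join the functional profiles, and run the metabolic-rate analysis
#' (including temperature-corrected variants), the lifespan analysis (when
#' at least four organisms carry lifespan data) and the allometric
#' power-law fit.
#'
#' @param traits Species-level trait tibble (see [read_trait_table()]).
#' @param profiles Functional profiles, long or wide, including the
#'   `"Oxic metabolism"` pseudo-category.
#' @param genus_level Collapse to genus-averaged rows with a representative
#'   genome before analysis (the default analysis plan); `FALSE` runs at
#'   species level for sensitivity.
#' @param geometric Use geometric genus means (sensitivity switch).
#' @inheritParams run_metabolic_analysis
#' @return An object of class `analysis_report`: a list with `metabolic`,
#'   `lifespan` (or `NULL`), `allometry` (an [fit_power_law()] object),
#'   and `provenance` (row counts at each filtering step, alpha, options).
#' @export
run_pipeline <- function(traits, profiles, alpha = 0.05, genus_level = TRUE,
                         geometric = FALSE,
                         target_temperatures = c(25, 10),
                         temperature_method = c("q10_style", "boltzmann"),
                         activation_energy = 0.65) {
  temperature_method <- match.arg(temperature_method)
  traits <- validate_traits(traits)
  n_input <- nrow(traits)
  traits <- add_mass_specific(traits)
  if (isTRUE(genus_level)) {
    n_direct_q <- sum(!is.na(traits$q_W_per_g))
    traits <- collapse_to_genus(traits, geometric = geometric)
    traits <- add_mass_specific(traits)
    inform(sprintf(
      "Genus averaging: %d species collapsed to %d genera (q averaged directly for %d species-level records).",
      n_input, nrow(traits), n_direct_q
    ))
  }
  n_analysis <- nrow(traits)

  metabolic <- run_metabolic_analysis(
    traits, profiles, alpha = alpha,
    target_temperatures = target_temperatures,
    temperature_method = temperature_method,
    activation_energy = activation_energy
  )
  lifespan <- tryCatch(
    run_lifespan_analysis(traits, profiles, alpha = alpha),
    error = function(e) {
      inform(sprintf("Lifespan analysis skipped: %s", conditionMessage(e)))
      NULL
    }
  )
  cc <- stats::complete.cases(traits[, c("mass_g", "q_W_per_g")])
  allometry <- fit_power_law(traits$mass_g[cc], traits$q_W_per_g[cc])

  provenance <- list(
    n_species_input = n_input,
    n_analysis_rows = n_analysis,
    n_joined = metabolic$n,
    n_lifespan = if (is.null(lifespan)) 0L else lifespan$n,
    n_allometry = allometry$n,
    alpha = alpha,
    genus_level = genus_level,
    temperature_method = temperature_method,
    target_temperatures = target_temperatures
  )
  structure(
    list(metabolic = metabolic, lifespan = lifespan, allometry = allometry,
         provenance = provenance),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("Comparative functional-genome analysis (%d organisms analysed)\n",
              pv$n_joined))
  cat(sprintf("  Allometry: q ~ M^(-%.3f +/- %.3f), n = %d\n",
              x$allometry$beta, x$allometry$standard_error, x$allometry$n))
  key <- x$metabolic$core
  show <- key[key$comparison %in%
                c("q_vs_oxic", "q_vs_oxic_given_mass",
                  "q_vs_genome_size", "q_vs_genome_size_given_mass"), ]
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  %-28s r = %+.3f  p = %.3g  (n = %d)\n",
                show$comparison[i], show$r[i], show$p[i], show$n[i]))
  }
  retained <- sum(x$metabolic$screen$retained)
  cat(sprintf("  Screen: %d of %d categories retained at alpha = %g; top: %s\n",
              retained, nrow(x$metabolic$screen), pv$alpha,
              x$metabolic$screen$category[1]))
  if (!is.null(x$lifespan)) {
    ls_row <- x$lifespan$core[
      x$lifespan$core$comparison == "lifespan_vs_oxic_given_mass", ]
    cat(sprintf("  Lifespan vs oxic | mass:     r = %+.3f  p = %.3g  (n = %d)\n",
                ls_row$r, ls_row$p, ls_row$n))
  }
  invisible(x)
}
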