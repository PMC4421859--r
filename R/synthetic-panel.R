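# Synthetic organism-panel generator: trait tables, functional profiles and
# on-disk KGML/.keg/FASTA fixtures with known (planted) effect structure.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Fixed synthetic oxic-reaction catalogue (60 reactions) and a disjoint
# non-oxic reaction pool. Schema-faithful to KEGG R numbers / EC numbers,
# not content-faithful.
synthetic_oxic_reactions <- function() {
  idx <- seq_len(60L)
  structure(
    list(
      r_numbers = sprintf("R%05d", 1000L + idx - 1L),
      ec_numbers = sprintf("1.%d.%d.%d", (idx - 1L) %% 14 + 1L,
                           (idx - 1L) %% 7 + 1L, idx)
    ),
    class = "oxic_reactions"
  )
}

non_oxic_reaction_pool <- function() {
  sprintf("R%05d", 2000:2199)
}

# BRITE-flavoured decoy category names; synthesised names fill in past the
# curated list.
decoy_category_names <- function(n) {
  base <- c(
    "Carbohydrate metabolism", "Energy metabolism", "Lipid metabolism",
    "Nucleotide metabolism", "Amino acid metabolism",
    "Metabolism of other amino acids", "Glycan biosynthesis and metabolism",
    "Metabolism of cofactors and vitamins",
    "Metabolism of terpenoids and polyketides",
    "Xenobiotics biodegradation and metabolism",
    "Biosynthesis of other secondary metabolites", "Transcription",
    "Translation", "Folding, sorting and degradation",
    "Replication and repair", "Membrane transport", "Signal transduction",
    "Signaling molecules and interaction", "Transport and catabolism",
    "Cell growth and death", "Cell motility", "Cellular community",
    "Immune system", "Endocrine system", "Circulatory system",
    "Digestive system", "Excretory system", "Nervous system",
    "Sensory system", "Development and regeneration"
  )
  if (n <= length(base)) {
    return(base[seq_len(n)])
  }
  c(base, sprintf("Functional category %02d", seq_len(n - length(base))))
}

#' Configuration for the synthetic organism panel
#'
#' Bundles every planted effect size, range, noise level and the seed for
#' [generate_panel()]. The defaults emulate the study conditions of the
#' comparative panel this package targets: ~101 genera spanning prokaryotes
#' to mammals (12 mammals, 6 birds, 4 ectothermic vertebrates, 5 insects,
#' 9 protozoa, the rest prokaryotes), body masses spanning `1e-13`-`1e6` g,
#' a shallow mass scaling of mass-specific rate (`beta_true = 0.035`), a
#' positive mass-genome-size link (rank correlation ~0.8), an oxic gene
#' proportion that rises with mass and raises the rate, and a lifespan
#' (mammals and birds only) that rises with mass and falls with the oxic
#' proportion. See the package vignette for the reasoning behind each
#' default.
#'
#' @param n_genera Number of genera in the panel.
#' @param species_per_genus Species per genus: a single count, or a
#'   `c(min, max)` range sampled per genus.
#' @param taxon_fracs Named fractions per taxon group (must sum to 1).
#' @param mass_log10_ranges Named list of `c(min, max)` log10-gram mass
#'   ranges per taxon group; jointly they span `[-13, 6]`.
#' @param beta_true Planted scaling exponent of `q ~ M^(-beta)`.
#' @param q_intercept Mass-specific rate (W/g) at the reference oxic
#'   proportion for a 1 g organism.
#' @param q_noise_sd Lognormal (natural-log) noise sd on the rate.
#' @param oxic_base,oxic_mass_slope Oxic proportion at the minimum mass and
#'   its increase per log10 gram.
#' @param oxic_noise_sd Gaussian noise sd on the oxic proportion.
#' @param oxic_effect_on_rate Coefficient on natural-log rate per unit oxic
#'   proportion (positive: more oxic genes, faster metabolism).
#' @param oxic_effect_on_lifespan Magnitude of the negative coefficient on
#'   natural-log lifespan per unit oxic proportion.
#' @param mass_lifespan_exponent Exponent of the mass-lifespan power law.
#' @param lifespan_intercept Lifespan (years) of a 1 g organism at oxic
#'   proportion zero.
#' @param lifespan_noise_sd Lognormal noise sd on lifespan.
#' @param genome_log10_at_min,genome_mass_slope,genome_noise_sd Genome size
#'   (log10 bp) at the minimum mass, its slope per log10 gram, and noise sd
#'   (these defaults target a mass-genome rank correlation around 0.8).
#' @param n_categories Number of decoy functional categories (pure noise).
#' @param category_mean_range Range of mean category proportions (log-uniform
#'   draw per category).
#' @param category_noise_sd Lognormal spread of per-organism category
#'   proportions around the category mean.
#' @param gene_count_range Genes per genome, scaled with log genome size.
#' @param species_jitter_sd Log-scale jitter of species around genus values.
#' @param volant_prob_mammal Probability that a mammal genus is volant
#'   (bats); birds are always volant.
#' @param temperature_ranges Named list of `c(min, max)` measurement
#'   temperatures (deg C) per taxon group; `NA` means temperature data are
#'   unavailable for that group (default: birds and insects, mirroring the
#'   availability pattern of endotherm respirometry compilations).
#' @param seed Default RNG seed for [generate_panel()].
#' @return A validated list of class `panel_config`.
#' @export
panel_config <- function(
    n_genera = 101L,
    species_per_genus = 1L,
    taxon_fracs = c(mammal = 12, bird = 6, ectothermic_vertebrate = 4,
                    insect = 5, protozoan = 9, prokaryote = 65) / 101,
    mass_log10_ranges = list(
      mammal = c(0.5, 6), bird = c(1, 4), ectothermic_vertebrate = c(0, 4),
      insect = c(-3, 0.5), protozoan = c(-9, -5), prokaryote = c(-13, -11)
    ),
    beta_true = 0.035,
    q_intercept = 0.01,
    q_noise_sd = 0.3,
    oxic_base = 0.08,
    oxic_mass_slope = 0.005,
    oxic_noise_sd = 0.05,
    oxic_effect_on_rate = 10,
    oxic_effect_on_lifespan = 8,
    mass_lifespan_exponent = 0.2,
    lifespan_intercept = 6,
    lifespan_noise_sd = 0.4,
    genome_log10_at_min = 6.5,
    genome_mass_slope = 0.16,
    genome_noise_sd = 0.45,
    n_categories = 30L,
    category_mean_range = c(0.005, 0.08),
    category_noise_sd = 0.4,
    gene_count_range = c(500L, 5000L),
    species_jitter_sd = 0.05,
    volant_prob_mammal = 0.13,
    temperature_ranges = list(
      mammal = c(36, 39), bird = c(NA, NA),
      ectothermic_vertebrate = c(15, 35), insect = c(NA, NA),
      protozoan = c(10, 30), prokaryote = c(5, 37)
    ),
    seed = 1L) {
  cfg <- list(
    n_genera = as.integer(n_genera), species_per_genus = species_per_genus,
    taxon_fracs = taxon_fracs, mass_log10_ranges = mass_log10_ranges,
    beta_true = beta_true, q_intercept = q_intercept, q_noise_sd = q_noise_sd,
    oxic_base = oxic_base, oxic_mass_slope = oxic_mass_slope,
    oxic_noise_sd = oxic_noise_sd,
    oxic_effect_on_rate = oxic_effect_on_rate,
    oxic_effect_on_lifespan = oxic_effect_on_lifespan,
    mass_lifespan_exponent = mass_lifespan_exponent,
    lifespan_intercept = lifespan_intercept,
    lifespan_noise_sd = lifespan_noise_sd,
    genome_log10_at_min = genome_log10_at_min,
    genome_mass_slope = genome_mass_slope,
    genome_noise_sd = genome_noise_sd,
    n_categories = as.integer(n_categories),
    category_mean_range = category_mean_range,
    category_noise_sd = category_noise_sd,
    gene_count_range = as.integer(gene_count_range),
    species_jitter_sd = species_jitter_sd,
    volant_prob_mammal = volant_prob_mammal,
    temperature_ranges = temperature_ranges,
    seed = as.integer(seed)
  )
  validate_panel_config(cfg)
}

validate_panel_config <- function(cfg) {
  if (is.na(cfg$n_genera) || cfg$n_genera < 0L) {
    abort("`n_genera` must be >= 0.")
  }
  if (abs(sum(cfg$taxon_fracs) - 1) > 1e-8 || any(cfg$taxon_fracs < 0)) {
    abort("`taxon_fracs` must be non-negative and sum to 1.")
  }
  if (!all(names(cfg$taxon_fracs) %in% TAXON_GROUPS)) {
    abort("`taxon_fracs` names must be taxon groups.")
  }
  for (rng_name in c("category_mean_range", "gene_count_range")) {
    rng <- cfg[[rng_name]]
    if (length(rng) != 2L || rng[1] > rng[2] || any(rng <= 0)) {
      abort(sprintf("`%s` must be an ordered positive pair.", rng_name))
    }
  }
  for (tx in names(cfg$mass_log10_ranges)) {
    rng <- cfg$mass_log10_ranges[[tx]]
    if (length(rng) != 2L || rng[1] > rng[2]) {
      abort(sprintf("Mass range for %s is not well-ordered.", tx))
    }
  }
  sds <- c(cfg$q_noise_sd, cfg$oxic_noise_sd, cfg$lifespan_noise_sd,
           cfg$genome_noise_sd, cfg$category_noise_sd, cfg$species_jitter_sd)
  if (any(sds < 0)) {
    abort("Noise standard deviations must be >= 0.")
  }
  mass_span <- range(unlist(cfg$mass_log10_ranges))
  max_oxic <- cfg$oxic_base +
    cfg$oxic_mass_slope * (mass_span[2] - mass_span[1])
  if (max_oxic > 1 || cfg$oxic_base <= 0) {
    abort("Infeasible oxic proportions: the planted mean leaves [0, 1].")
  }
  structure(cfg, class = "panel_config")
}

# Largest-remainder apportionment of n among the taxon fractions.
apportion_taxa <- function(fracs, n) {
  raw <- fracs * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  counts <- as.integer(counts)
  names(counts) <- names(fracs)
  counts[counts > 0]
}

#' Generate a synthetic organism panel with planted effects
#'
#' Draws a panel of genera (optionally with several species each) whose
#' traits follow the planted statistical structure described in
#' [panel_config()]: log-uniform body masses per taxon group, genome size
#' monotone-noisy in mass, an oxic gene proportion increasing with mass,
#' mass-specific metabolic rate
#' `q = c * M^(-beta) * exp(effect * (oxic - ref)) * lognormal noise`,
#' and -- for mammals and birds only -- a lifespan increasing with mass and
#' decreasing with the oxic proportion. Decoy category proportions are
#' independent noise. All proportions are realised as integer gene counts
#' over the genome's gene total, and the reported proportions are recomputed
#' from those counts, so fixture files written by [write_fixture_files()]
#' and re-read through the parsers reproduce them exactly.
#'
#' @param config A [panel_config()].
#' @param seed RNG seed (defaults to `config$seed`); the panel is fully
#'   deterministic given config and seed.
#' @param build_annotations Also materialise gene-level annotation maps
#'   (gene-reaction, category-gene, gene-length) for each representative
#'   genome. Trait draws are unaffected by this switch.
#' @return An object of class `synthetic_panel`: a list with `traits`
#'   (species-level trait tibble), `profiles` (long functional-profile
#'   tibble for the representative genomes, including the
#'   `"Oxic metabolism"` pseudo-category), `annotations` (named list per
#'   genome of `gene_reactions`, `categories`, `lengths` tibbles, or `NULL`),
#'   `oxic` (the synthetic oxic reaction set), `truth` (planted parameters
#'   and per-genus latent values) and `config`.
#' @export
generate_panel <- function(config = panel_config(), seed = config$seed,
                           build_annotations = TRUE) {
  withr::with_seed(as.integer(seed), {
    generate_panel_impl(config, build_annotations, as.integer(seed))
  })
}

empty_panel <- function(cfg, build_annotations, seed) {
  traits <- tibble(
    species = character(), genus = character(), taxon_group = character(),
    mass_g = double(), q_W_per_g = double(), rate_W = double(),
    temp_C = double(), lifespan_y = double(), volant = logical(),
    fossorial = logical(), foraging_env = character(),
    daily_activity = character(), genome_code = character(),
    genome_bp = double(), genome_year = integer()
  )
  profiles <- tibble(
    organism = character(), category = character(), gene_count = integer(),
    proportion = double(), nucleotides = double(), total_genes = integer()
  )
  annotations <- if (isTRUE(build_annotations)) {
    stats::setNames(list(), character())
  } else {
    NULL
  }
  structure(
    list(traits = traits, profiles = profiles, annotations = annotations,
         oxic = synthetic_oxic_reactions(),
         truth = list(planted_category = "Oxic metabolism",
                      genus_latent = tibble(genus = character())),
         config = cfg, seed = seed),
    class = "synthetic_panel"
  )
}

generate_panel_impl <- function(cfg, build_annotations, seed) {
  n <- cfg$n_genera
  if (n == 0L) {
    return(empty_panel(cfg, build_annotations, seed))
  }
  counts <- apportion_taxa(cfg$taxon_fracs, n)
  taxon <- rep(names(counts), counts)
  genus <- sprintf("Genus%03d", seq_len(n))

  # Panel-level: decoy category means (log-uniform over the configured range).
  cat_names <- decoy_category_names(cfg$n_categories)
  cat_mu <- exp(runif(cfg$n_categories, log(cfg$category_mean_range[1]),
                      log(cfg$category_mean_range[2])))

  # Genus-level latent draws.
  mass_rng <- do.call(rbind, cfg$mass_log10_ranges[taxon])
  m <- runif(n, mass_rng[, 1], mass_rng[, 2])
  mass_min <- min(unlist(cfg$mass_log10_ranges))
  mass_mid <- mean(range(unlist(cfg$mass_log10_ranges)))
  u_ref <- cfg$oxic_base + cfg$oxic_mass_slope * (mass_mid - mass_min)
  u_target <- clamp(
    cfg$oxic_base + cfg$oxic_mass_slope * (m - mass_min) +
      rnorm(n, 0, cfg$oxic_noise_sd),
    0.02, 0.95
  )
  g_log10 <- cfg$genome_log10_at_min +
    cfg$genome_mass_slope * (m - mass_min) + rnorm(n, 0, cfg$genome_noise_sd)
  ln_q <- log(cfg$q_intercept) - cfg$beta_true * log(10) * m +
    cfg$oxic_effect_on_rate * (u_target - u_ref) +
    rnorm(n, 0, cfg$q_noise_sd)

  temp_rng <- do.call(rbind, cfg$temperature_ranges[taxon])
  temp <- rep(NA_real_, n)
  has_temp <- !is.na(temp_rng[, 1])
  temp[has_temp] <- runif(sum(has_temp), temp_rng[has_temp, 1],
                          temp_rng[has_temp, 2])

  has_lifespan <- taxon %in% c("mammal", "bird")
  ln_L <- rep(NA_real_, n)
  ln_L[has_lifespan] <- log(cfg$lifespan_intercept) +
    cfg$mass_lifespan_exponent * log(10) * m[has_lifespan] -
    abs(cfg$oxic_effect_on_lifespan) * u_target[has_lifespan] +
    rnorm(sum(has_lifespan), 0, cfg$lifespan_noise_sd)

  volant <- taxon == "bird" |
    (taxon == "mammal" & runif(n) < cfg$volant_prob_mammal)
  fossorial <- taxon == "mammal" & runif(n) < 0.15
  foraging_env <- ifelse(
    taxon %in% c("mammal", "bird", "ectothermic_vertebrate", "insect"),
    ifelse(volant, "aerial",
           ifelse(runif(n) < 0.25, "aquatic", "terrestrial")),
    NA_character_
  )
  daily_activity <- ifelse(
    taxon %in% c("mammal", "bird", "ectothermic_vertebrate", "insect"),
    c("diurnal", "nocturnal", "crepuscular")[
      sample.int(3L, n, replace = TRUE)],
    NA_character_
  )

  # Integer realisation of the planted proportions over each genome's genes.
  g_rng <- cfg$gene_count_range
  span <- diff(range(c(6.5, 9.6)))
  n_genes <- as.integer(clamp(
    round(g_rng[1] + (g_log10 - 6.5) / span * (g_rng[2] - g_rng[1])),
    g_rng[1], g_rng[2]
  ))
  k_ox <- as.integer(clamp(round(u_target * n_genes), 1L, n_genes))
  u_real <- k_ox / n_genes

  p_cat_target <- matrix(
    clamp(rep(cat_mu, each = n) *
            exp(rnorm(n * cfg$n_categories, 0, cfg$category_noise_sd)),
          1e-4, 0.5),
    nrow = n
  )
  if (any(p_cat_target > 1)) {
    abort("Infeasible category proportions (> 1).")
  }
  # every category is realised by at least one gene so that the written
  # .keg hierarchy carries the full category set
  k_cat <- matrix(as.integer(clamp(round(p_cat_target * n_genes),
                                   1, max(n_genes))), nrow = n)
  k_cat <- pmin(k_cat, matrix(n_genes, nrow = n, ncol = ncol(k_cat)))
  p_cat_real <- k_cat / n_genes

  genome_bp <- round(10^g_log10)
  genome_year <- sample(1998:2014, n, replace = TRUE)
  genome_code <- sprintf("syn%03da", seq_len(n))

  # Species rows: jitter species around the genus latent values; the genus
  # mean of each parameter stays centred on the latent value.
  spg <- cfg$species_per_genus
  n_sp <- if (length(spg) == 2L) {
    sample(spg[1]:spg[2], n, replace = TRUE)
  } else {
    rep(as.integer(spg), n)
  }
  gi <- rep(seq_len(n), n_sp)
  sp_idx <- unlist(lapply(n_sp, seq_len))
  jit <- function(sd) rnorm(length(gi), 0, sd)
  m_sp <- m[gi] + jit(cfg$species_jitter_sd)
  q_sp <- exp(ln_q[gi] + jit(cfg$species_jitter_sd))
  L_sp <- exp(ln_L[gi] + jit(cfg$species_jitter_sd))
  temp_sp <- temp[gi]
  sp_code <- sprintf("syn%03d%s", gi, letters[sp_idx])
  sp_year <- ifelse(sp_idx == 1L, genome_year[gi],
                    sample(1998:2014, length(gi), replace = TRUE))

  traits <- tibble(
    species = sprintf("%s sp%d", genus[gi], sp_idx),
    genus = genus[gi],
    taxon_group = taxon[gi],
    mass_g = 10^m_sp,
    q_W_per_g = q_sp,
    rate_W = q_sp * 10^m_sp,
    temp_C = temp_sp,
    lifespan_y = L_sp,
    volant = volant[gi],
    fossorial = fossorial[gi],
    foraging_env = foraging_env[gi],
    daily_activity = daily_activity[gi],
    genome_code = sp_code,
    genome_bp = genome_bp[gi],
    genome_year = as.integer(sp_year)
  )

  # The representative genome of each genus (earliest year, lexicographic
  # tie-break over species codes) carries the annotation.
  rep_code <- vapply(seq_len(n), function(i) {
    rows <- which(gi == i)
    select_representative(tibble(genome_code = sp_code[rows],
                                 genome_year = sp_year[rows]))
  }, character(1))

  profiles <- tibble(
    organism = rep(rep_code, each = cfg$n_categories + 1L),
    category = rep(c(cat_names, "Oxic metabolism"), times = n),
    gene_count = as.integer(t(cbind(k_cat, k_ox))),
    total_genes = rep(n_genes, each = cfg$n_categories + 1L)
  ) |>
    dplyr::mutate(proportion = .data$gene_count / .data$total_genes,
                  .after = "gene_count")

  oxic <- synthetic_oxic_reactions()
  annotations <- NULL
  if (isTRUE(build_annotations)) {
    annotations <- lapply(seq_len(n), function(i) {
      build_annotation_one(
        organism = rep_code[i], n_genes = n_genes[i], k_ox = k_ox[i],
        k_cat = k_cat[i, ], cat_names = cat_names, oxic = oxic
      )
    })
    names(annotations) <- rep_code
    # Functional genome size (nucleotide totals) from the realised lengths.
    nt <- purrr::imap(annotations, function(ann, org) {
      len <- stats::setNames(ann$lengths$length, ann$lengths$gene)
      ann$categories |>
        dplyr::group_by(.data$category) |>
        dplyr::summarise(nucleotides = sum(len[unique(.data$gene)]),
                         .groups = "drop") |>
        dplyr::mutate(organism = org)
    }) |>
      dplyr::bind_rows()
    oxic_nt <- purrr::imap(annotations, function(ann, org) {
      len <- stats::setNames(ann$lengths$length, ann$lengths$gene)
      ox <- call_oxic_genes(ann$gene_reactions, oxic)
      tibble(organism = org, category = "Oxic metabolism",
             nucleotides = sum(len[ox]))
    }) |>
      dplyr::bind_rows()
    profiles <- profiles |>
      dplyr::left_join(dplyr::bind_rows(nt, oxic_nt),
                       by = c("organism", "category"))
  } else {
    profiles$nucleotides <- NA_real_
  }
  profiles <- dplyr::select(profiles, "organism", "category", "gene_count",
                            "proportion", "nucleotides", "total_genes")

  truth <- list(
    beta_true = cfg$beta_true,
    oxic_effect_on_rate = cfg$oxic_effect_on_rate,
    oxic_effect_on_lifespan = -abs(cfg$oxic_effect_on_lifespan),
    mass_lifespan_exponent = cfg$mass_lifespan_exponent,
    genome_mass_slope = cfg$genome_mass_slope,
    category_means = stats::setNames(cat_mu, cat_names),
    planted_category = "Oxic metabolism",
    genus_latent = tibble(
      genus = genus, organism = rep_code, taxon_group = taxon,
      mass_log10 = m, oxic_target = u_target, oxic_realized = u_real,
      genome_log10 = g_log10, ln_q = ln_q, ln_lifespan = ln_L,
      n_genes = n_genes, k_oxic = k_ox
    )
  )

  structure(
    list(traits = traits, profiles = profiles, annotations = annotations,
         oxic = oxic, truth = truth, config = cfg, seed = seed),
    class = "synthetic_panel"
  )
}

# Gene-level realisation for one genome: oxic genes get at least one oxic
# reaction; other genes get non-oxic reactions (or none); category members
# are sampled uniformly; genes in no category fall into "Unclassified" so
# the .keg file's gene universe equals the genome's gene total.
build_annotation_one <- function(organism, n_genes, k_ox, k_cat, cat_names,
                                 oxic) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  oxic_genes <- sample(genes, k_ox)
  other <- setdiff(genes, oxic_genes)

  rxn_rows <- list(
    tibble(gene = oxic_genes,
           reaction = sample(oxic$r_numbers, k_ox, replace = TRUE))
  )
  extra <- oxic_genes[runif(k_ox) < 0.3]
  if (length(extra) > 0L) {
    rxn_rows <- c(rxn_rows, list(tibble(
      gene = extra,
      reaction = sample(non_oxic_reaction_pool(), length(extra),
                        replace = TRUE)
    )))
  }
  with_rxn <- other[runif(length(other)) < 0.85]
  if (length(with_rxn) > 0L) {
    rxn_rows <- c(rxn_rows, list(tibble(
      gene = with_rxn,
      reaction = sample(non_oxic_reaction_pool(), length(with_rxn),
                        replace = TRUE)
    )))
  }
  no_rxn <- setdiff(other, with_rxn)
  if (length(no_rxn) > 0L) {
    rxn_rows <- c(rxn_rows, list(tibble(gene = no_rxn,
                                        reaction = NA_character_)))
  }
  gene_reactions <- dplyr::bind_rows(rxn_rows) |>
    dplyr::distinct() |>
    dplyr::mutate(organism = organism, .before = 1L) |>
    dplyr::arrange(.data$gene, .data$reaction)

  cat_rows <- purrr::map2(cat_names, k_cat, function(nm, k) {
    if (k == 0L) {
      return(NULL)
    }
    tibble(category = nm, gene = sample(genes, k))
  })
  categories <- dplyr::bind_rows(cat_rows)
  covered <- unique(categories$gene)
  leftover <- setdiff(genes, covered)
  if (length(leftover) > 0L) {
    categories <- dplyr::bind_rows(
      categories, tibble(category = "Unclassified", gene = leftover)
    )
  }
  categories <- categories |>
    dplyr::mutate(organism = organism, .before = 1L) |>
    dplyr::arrange(.data$category, .data$gene)

  lengths <- tibble(
    organism = organism, gene = genes,
    length = 3L * sample(100:800, n_genes, replace = TRUE)
  )
  list(gene_reactions = gene_reactions, categories = categories,
       lengths = lengths)
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(
    "<synthetic_panel> %d genera / %d species, %d decoy categories, seed %d%s\n",
    nrow(x$truth$genus_latent), nrow(x$traits),
    x$config$n_categories, x$seed,
    if (is.null(x$annotations)) " (no gene-level annotations)" else ""
  ))
  invisible(x)
}
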