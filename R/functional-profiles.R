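#' Identify oxic genes from gene-reaction relations
#'
#' A gene is called oxic when it is associated with at least one reaction in
#' the oxic reaction list (matching on KEGG R numbers). Optionally, genes
#' can also be matched on EC numbers when the annotation provides an `ec`
#' column; this is off by default because the primary operational rule uses
#' R numbers from pathway XML.
#'
#' @param gene_reactions Tibble from [parse_kgml()] (columns `gene`,
#'   `reaction`, optionally `ec`).
#' @param oxic An `oxic_reactions` object from [load_oxic_reactions()], or a
#'   character vector of R numbers.
#' @param match_ec Also match on EC numbers when available (default FALSE).
#'
#' @return Sorted character vector of oxic gene identifiers.
#' @export
call_oxic_genes <- function(gene_reactions, oxic, match_ec = FALSE) {
  if (is.character(oxic)) {
    oxic <- structure(list(r_numbers = unique(oxic), ec_numbers = character()),
                      class = "oxic_reactions")
  }
  if (!inherits(oxic, "oxic_reactions")) {
    abort("`oxic` must be an `oxic_reactions` object or a character vector of R numbers.")
  }
  rset <- oxic$r_numbers
  eset <- if (isTRUE(match_ec)) oxic$ec_numbers else character()
  if (length(rset) == 0L && length(eset) == 0L) {
    abort("The oxic reaction set is empty; calling oxic genes is meaningless.")
  }
  hits <- gene_reactions$gene[!is.na(gene_reactions$reaction) &
                                gene_reactions$reaction %in% rset]
  if (length(eset) > 0L && "ec" %in% names(gene_reactions)) {
    hits <- c(hits, gene_reactions$gene[!is.na(gene_reactions$ec) &
                                          gene_reactions$ec %in% eset])
  }
  sort(unique(hits))
}

#' Compute a per-organism functional profile
#'
#' For every functional category, counts member genes and expresses them as
#' a proportion of the organism's total gene count; when gene lengths are
#' supplied, also totals the nucleotides of each category's genes (the
#' "functional genome size"). The oxic gene set is appended as a
#' pseudo-category (default label `"Oxic metabolism"`) so that screens can
#' rank it alongside ordinary categories.
#'
#' The denominator defaults to the number of distinct genes in the category
#' annotation; pass `universe` (a character vector of all annotated genes,
#' e.g. from the genome-wide gene list) to use a broader denominator.
#'
#' @param categories Tibble from [parse_brite_keg()] (columns `organism`,
#'   `category`, `gene`).
#' @param oxic_genes Optional character vector from [call_oxic_genes()].
#' @param lengths Optional tibble from [read_gene_lengths()].
#' @param universe Optional character vector defining the gene universe.
#' @param oxic_label Label for the oxic pseudo-category.
#'
#' @return A tibble with one row per (organism, category): `organism`,
#'   `category`, `gene_count`, `proportion`, `nucleotides` (`NA` when
#'   lengths are unavailable or incomplete), `total_genes`.
#' @export
compute_profile <- function(categories, oxic_genes = NULL, lengths = NULL,
                            universe = NULL, oxic_label = "Oxic metabolism") {
  if (!all(c("organism", "category", "gene") %in% names(categories))) {
    abort("`categories` must have columns organism, category, gene.")
  }
  org <- unique(categories$organism)
  if (length(org) != 1L) {
    abort("`compute_profile()` profiles one organism at a time.")
  }
  universe <- unique(universe %||% categories$gene)
  total <- length(universe)
  if (total == 0L) {
    abort("Gene universe is empty: total_genes must be positive.")
  }

  len_lookup <- NULL
  if (!is.null(lengths)) {
    len_lookup <- stats::setNames(lengths$length, lengths$gene)
  }
  sum_nt <- function(genes) {
    if (is.null(len_lookup)) {
      return(NA_integer_)
    }
    found <- genes %in% names(len_lookup)
    if (!all(found)) {
      warn(sprintf("%d gene(s) missing from the length map; nucleotide total marked incomplete.",
                   sum(!found)))
      return(NA_integer_)
    }
    as.integer(sum(len_lookup[genes]))
  }

  per_cat <- categories |>
    dplyr::distinct(.data$category, .data$gene) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      gene_count = dplyr::n_distinct(.data$gene),
      nucleotides = sum_nt(unique(.data$gene)),
      .groups = "drop"
    )

  out <- per_cat
  if (!is.null(oxic_genes)) {
    oxic_genes <- unique(oxic_genes)
    outside <- setdiff(oxic_genes, universe)
    if (length(outside) > 0L) {
      warn(sprintf("%d oxic gene(s) outside the gene universe were dropped from the profile.",
                   length(outside)))
      oxic_genes <- intersect(oxic_genes, universe)
    }
    out <- dplyr::bind_rows(out, tibble(
      category = oxic_label,
      gene_count = length(oxic_genes),
      nucleotides = sum_nt(oxic_genes)
    ))
  }
  out |>
    dplyr::mutate(
      organism = org,
      proportion = .data$gene_count / total,
      total_genes = total
    ) |>
    dplyr::select("organism", "category", "gene_count", "proportion",
                  "nucleotides", "total_genes") |>
    dplyr::arrange(.data$category)
}

#' Pivot long functional profiles to a wide organisms-by-categories table
#'
#' @param profiles Long profile tibble (rows are organism-category pairs),
#'   e.g. from [compute_profile()] or a [generate_panel()] result's
#'   `profiles` element.
#' @param value Which value to spread: `"proportion"` (default),
#'   `"gene_count"` or `"nucleotides"`.
#'
#' @return A wide tibble with one row per organism and one column per
#'   category.
#' @export
profiles_wide <- function(profiles, value = "proportion") {
  value <- match.arg(value, c("proportion", "gene_count", "nucleotides"))
  tidyr::pivot_wider(
    dplyr::select(profiles, "organism", "category", dplyr::all_of(value)),
    names_from = "category", values_from = dplyr::all_of(value)
  )
}

#' Write functional profiles to TSV
#'
#' @param profiles Long profile tibble from [compute_profile()].
#' @param path Output file path.
#' @param wide Write the organisms-by-categories proportion matrix instead
#'   of the long per-(organism, category) table.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, wide = FALSE) {
  out <- if (isTRUE(wide)) profiles_wide(profiles) else profiles
  readr::write_tsv(out, path, na = "")
  invisible(path)
}
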