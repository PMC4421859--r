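# On-disk fixture writing for synthetic panels, and re-reading fixture
# directories back into functional profiles.

# Deterministic filler sequence of a given length (no RNG: file contents
# are a pure function of the panel object).
filler_sequence <- function(len) {
  s <- strrep("ACGT", ceiling(len / 4))
  substr(s, 1L, len)
}

wrap_fasta <- function(seq, width = 60L) {
  gsub(sprintf("(.{%d})", width), "\\1\n", seq)
}

kgml_text <- function(ann, organism) {
  by_gene <- ann$gene_reactions |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      rxn = paste(stats::na.omit(.data$reaction), collapse = " "),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene)
  entries <- vapply(seq_len(nrow(by_gene)), function(i) {
    rxn <- by_gene$rxn[i]
    rxn_attr <- if (nzchar(rxn)) {
      sprintf(' reaction="%s"',
              paste(sprintf("rn:%s", strsplit(rxn, " ")[[1]]), collapse = " "))
    } else {
      ""
    }
    sprintf('  <entry id="%d" name="%s:%s" type="gene"%s/>',
            i, organism, by_gene$gene[i], rxn_attr)
  }, character(1))
  c(
    '<?xml version="1.0"?>',
    sprintf('<pathway name="path:%s00001" org="%s" number="00001" title="Synthetic metabolic map">',
            organism, organism),
    entries,
    "</pathway>"
  )
}

keg_text <- function(ann, organism) {
  cats <- ann$categories |> dplyr::arrange(.data$category, .data$gene)
  lines <- c(
    "+D\tGene",
    sprintf("#DEFINITION  Synthetic functional hierarchy for %s", organism),
    "!",
    "A<b>Synthetic functional categories</b>"
  )
  for (cat in unique(cats$category)) {
    genes <- cats$gene[cats$category == cat]
    lines <- c(
      lines,
      sprintf("B  <b>%s</b>", cat),
      sprintf("C    00001 Synthetic pathway [PATH:%s00001]", organism),
      sprintf("D      %s:%s  %s; synthetic protein", organism, genes, genes)
    )
  }
  c(lines, "!", "#Generated fixture")
}

fasta_text <- function(ann, organism) {
  unlist(lapply(seq_len(nrow(ann$lengths)), function(i) {
    c(sprintf(">%s:%s synthetic gene", organism, ann$lengths$gene[i]),
      strsplit(wrap_fasta(filler_sequence(ann$lengths$length[i])),
               "\n", fixed = TRUE)[[1]])
  }))
}

#' Write a synthetic panel to on-disk fixture files
#'
#' Writes, for every annotated genome in the panel, one KGML pathway XML
#' file (`<organism>.xml`), one BRITE `.keg` hierarchy (`<organism>.keg`)
#' and one nucleotide FASTA (`<organism>.fna`), plus two panel-level files:
#' the trait table (`traits.tsv`) and the oxic reaction list
#' (`oxic_reactions.tsv`). Re-reading these files through [parse_kgml()],
#' [parse_brite_keg()], [read_gene_lengths()] and [compute_profile()]
#' reproduces the panel's annotation maps and planted proportions exactly.
#' File contents are a pure function of the panel object (no randomness at
#' write time).
#'
#' @param panel A `synthetic_panel` generated with
#'   `build_annotations = TRUE`.
#' @param dir Output directory (created if needed).
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return A manifest tibble with one row per file written: `file`
#'   (relative path), `bytes`, `checksum`, `algorithm` (`"md5"`).
#' @export
write_fixture_files <- function(panel, dir, overwrite = FALSE) {
  if (!inherits(panel, "synthetic_panel")) {
    abort("`panel` must be a synthetic_panel.")
  }
  if (is.null(panel$annotations)) {
    abort("Panel has no gene-level annotations; regenerate with `build_annotations = TRUE`.")
  }
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !isTRUE(overwrite)) {
    abort(sprintf("Directory '%s' is non-empty; pass `overwrite = TRUE` to write anyway.",
                  dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  files <- character(0)
  for (org in names(panel$annotations)) {
    ann <- panel$annotations[[org]]
    xml_path <- file.path(dir, paste0(org, ".xml"))
    keg_path <- file.path(dir, paste0(org, ".keg"))
    fna_path <- file.path(dir, paste0(org, ".fna"))
    writeLines(kgml_text(ann, org), xml_path)
    writeLines(keg_text(ann, org), keg_path)
    writeLines(fasta_text(ann, org), fna_path)
    files <- c(files, xml_path, keg_path, fna_path)
  }
  traits_path <- file.path(dir, "traits.tsv")
  write_trait_table(panel$traits, traits_path)
  oxic_path <- file.path(dir, "oxic_reactions.tsv")
  n_ox <- max(length(panel$oxic$r_numbers), length(panel$oxic$ec_numbers))
  readr::write_tsv(tibble(
    r_number = rep_len(panel$oxic$r_numbers, n_ox),
    ec_number = rep_len(panel$oxic$ec_numbers, n_ox)
  ), oxic_path)
  files <- c(files, traits_path, oxic_path)

  tibble(
    file = basename(files),
    bytes = unname(file.size(files)),
    checksum = unname(tools::md5sum(files)),
    algorithm = "md5"
  )
}

#' Rebuild functional profiles from a fixture directory
#'
#' Scans a directory written by [write_fixture_files()] (one `.xml`, `.keg`
#' and `.fna` file per organism plus `oxic_reactions.tsv`), parses each
#' organism's files, calls its oxic genes and recomputes the functional
#' profile.
#'
#' @param dir Directory of fixture files.
#' @param oxic Optional `oxic_reactions` object; defaults to the
#'   `oxic_reactions.tsv` in `dir`.
#' @return A long profile tibble (see [compute_profile()]) covering all
#'   organisms found.
#' @export
read_fixture_profiles <- function(dir, oxic = NULL) {
  keg_files <- list.files(dir, pattern = "\\.keg$", full.names = TRUE)
  if (length(keg_files) == 0L) {
    abort(sprintf("No .keg files found in '%s'.", dir))
  }
  if (is.null(oxic)) {
    oxic_path <- file.path(dir, "oxic_reactions.tsv")
    if (!file.exists(oxic_path)) {
      abort("No `oxic` given and no oxic_reactions.tsv in the directory.")
    }
    oxic <- load_oxic_reactions(oxic_path)
  }
  purrr::map(keg_files, function(keg) {
    org <- sub("\\.keg$", "", basename(keg))
    grm <- parse_kgml(file.path(dir, paste0(org, ".xml")), org)
    cgm <- parse_brite_keg(keg, org)
    fna <- file.path(dir, paste0(org, ".fna"))
    lens <- if (file.exists(fna)) read_gene_lengths(fna, org) else NULL
    compute_profile(cgm, oxic_genes = call_oxic_genes(grm, oxic),
                    lengths = lens)
  }) |>
    dplyr::bind_rows()
}
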