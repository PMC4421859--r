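# Shared fixtures: toy annotation texts and downsized panel configurations.

toy_kgml <- function(entries, org = "toy") {
  paste0(
    sprintf('<pathway name="path:%s00010" org="%s" number="00010">', org, org),
    paste(entries, collapse = ""),
    "</pathway>"
  )
}

gene_entry <- function(id, genes, reactions = NULL, org = "toy") {
  rxn <- if (is.null(reactions)) {
    ""
  } else {
    sprintf(' reaction="%s"',
            paste(sprintf("rn:%s", reactions), collapse = " "))
  }
  sprintf('<entry id="%d" name="%s" type="gene"%s/>', id,
          paste(sprintf("%s:%s", org, genes), collapse = " "), rxn)
}

toy_keg <- function(categories, org = "toy") {
  lines <- c("+C\tGene", "#Toy hierarchy", "!", "A<b>Toy</b>")
  for (nm in names(categories)) {
    lines <- c(lines, sprintf("B  <b>%s</b>", nm),
               sprintf("C      %s:%s  toy protein", org, categories[[nm]]))
  }
  paste(c(lines, "!"), collapse = "\n")
}

# A panel small enough that gene-level annotation and file writing are fast.
small_panel_config <- function(n_genera = 6L, ...) {
  panel_config(n_genera = n_genera, gene_count_range = c(60L, 200L),
               n_categories = 6L, ...)
}

# The lifespan study subset: 30 genera, 23 mammals and 7 birds.
lifespan_panel_config <- function(...) {
  panel_config(n_genera = 30L,
               taxon_fracs = c(mammal = 23, bird = 7) / 30, ...)
}

panel_join <- function(panel) {
  w <- profiles_wide(panel$profiles)
  dplyr::inner_join(panel$traits, w, by = c(genome_code = "organism"))
}

# Pipeline runs on downsized panels emit expected bookkeeping messages and
# small-subgroup warnings; keep test output clean.
quiet_pipeline <- function(...) {
  suppressMessages(suppressWarnings(run_pipeline(...)))
}
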