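#' Parse KGML pathway XML into a gene-reaction table
#'
#' Reads one or more KGML (KEGG Markup Language) pathway files and extracts
#' the gene-to-reaction ("R number") relations. Two KGML dialects are
#' supported: `reaction="rn:R00010"` attributes carried directly on gene
#' `<entry>` elements, and separate `<reaction>` elements linked to entries
#' by their `id` attribute. Results from multiple pathway files are merged
#' by taking the union of reaction sets per gene, so the result is invariant
#' under file order.
#'
#' Gene identifiers keep their case but lose any `org:` qualifier; reaction
#' identifiers lose the `rn:` qualifier and must then match `R` followed by
#' five digits -- tokens that do not are skipped with a warning. Genes that
#' appear in a pathway with no reaction at all are retained with an `NA`
#' reaction so that the annotation universe is not silently truncated.
#'
#' @param x Character vector of file paths and/or literal KGML XML strings.
#' @param organism_code Short organism identifier recorded in the output.
#'
#' @return A tibble with columns `organism`, `gene`, `reaction` (one row per
#'   gene-reaction pair; `reaction` is `NA` for genes with no reaction).
#' @export
#' @examples
#' kgml <- paste0(
#'   '<pathway name="path:toy00010" org="toy" number="00010">',
#'   '<entry id="1" name="toy:g1 toy:g2" type="gene" reaction="rn:R00010"/>',
#'   "</pathway>"
#' )
#' parse_kgml(kgml, "toy")
parse_kgml <- function(x, organism_code) {
  assert_scalar_string(organism_code, "organism_code")
  if (!is.character(x) || length(x) < 1L) {
    abort("`x` must be one or more KGML file paths or XML strings.")
  }
  maps <- lapply(x, parse_kgml_one, organism_code = organism_code)
  out <- dplyr::bind_rows(maps)
  if (nrow(out) == 0L) {
    return(tibble(organism = character(), gene = character(),
                  reaction = character()))
  }
  out <- dplyr::distinct(out)
  # A gene seen with reactions in one file and without in another keeps only
  # its informative rows.
  has_rxn <- unique(out$gene[!is.na(out$reaction)])
  out <- out[!(is.na(out$reaction) & out$gene %in% has_rxn), , drop = FALSE]
  dplyr::arrange(as_tibble(out), .data$gene, .data$reaction)
}

parse_kgml_one <- function(src, organism_code) {
  doc <- tryCatch(
    xml2::read_xml(src),
    error = function(e) {
      lab <- if (looks_like_path(src)) src else "<inline KGML text>"
      abort(sprintf("Malformed KGML XML in %s: %s", lab, conditionMessage(e)))
    }
  )
  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene']")
  if (length(entries) == 0L) {
    return(tibble(organism = character(), gene = character(),
                  reaction = character()))
  }
  # Dialect 2: standalone <reaction> elements are linked by entry id.
  rxn_nodes <- xml2::xml_find_all(doc, ".//reaction[@id and @name]")
  rxn_by_id <- stats::setNames(
    xml2::xml_attr(rxn_nodes, "name"),
    xml2::xml_attr(rxn_nodes, "id")
  )

  rows <- lapply(entries, function(entry) {
    genes <- strsplit(xml2::xml_attr(entry, "name"), "\\s+")[[1]]
    genes <- strip_prefix(genes[nzchar(genes)])
    if (length(genes) == 0L) {
      return(NULL)
    }
    rxn_attr <- xml2::xml_attr(entry, "reaction")
    rxn_linked <- unname(rxn_by_id[xml2::xml_attr(entry, "id")])
    tokens <- unlist(strsplit(stats::na.omit(c(rxn_attr, rxn_linked)), "\\s+"))
    tokens <- strip_prefix(tokens[nzchar(tokens)])
    ok <- grepl("^R[0-9]{5}$", tokens)
    if (any(!ok)) {
      warn(sprintf("Skipping unparseable reaction token(s): %s",
                   paste(tokens[!ok], collapse = ", ")))
      tokens <- tokens[ok]
    }
    if (length(tokens) == 0L) {
      return(tibble(gene = genes, reaction = NA_character_))
    }
    tidyr::expand_grid(gene = genes, reaction = unique(tokens))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(organism = character(), gene = character(),
                  reaction = character()))
  }
  dplyr::mutate(out, organism = organism_code, .before = 1L)
}

#' Parse a BRITE `.keg` hierarchy into a category-gene table
#'
#' Reads a KEGG BRITE flat-file hierarchy, in which the first character of
#' each line (`A`, `B`, `C`, `D`, ...) encodes its depth. Genes are taken
#' from the deepest level present in the file and are assigned to the
#' heading at `level` (default 2, the `B` lines -- the broad functional
#' category tier such as "Energy metabolism"). A gene listed under several
#' level-`level` headings is a member of each. HTML markup in headings
#' (e.g. `<b>...</b>`) is stripped.
#'
#' @param x A file path or the `.keg` text itself.
#' @param organism_code Short organism identifier recorded in the output.
#' @param level Hierarchy depth of the category headings (1 = `A` lines,
#'   2 = `B` lines, ...).
#'
#' @return A tibble with columns `organism`, `category`, `gene`. The number
#'   of distinct genes in the file is the default denominator for
#'   proportions downstream (see [compute_profile()]).
#' @export
parse_brite_keg <- function(x, organism_code, level = 2L) {
  assert_scalar_string(organism_code, "organism_code")
  if (!is.numeric(level) || length(level) != 1L || level < 1L) {
    abort("`level` must be a single positive integer.")
  }
  level <- as.integer(level)
  lines <- as_text_lines(x)
  lines <- lines[!grepl("^[#!+%]", lines) & nzchar(trimws(lines))]
  letter <- substr(lines, 1L, 1L)
  depth <- match(letter, LETTERS)
  body <- trimws(gsub("<[^>]*>", "", substr(lines, 2L, nchar(lines))))
  keep <- !is.na(depth) & nzchar(body)
  lines <- lines[keep]; depth <- depth[keep]; body <- body[keep]

  if (!any(depth == level)) {
    abort(sprintf(
      "No level-%d ('%s') headings found: not a valid .keg hierarchy for this level.",
      level, LETTERS[level]
    ))
  }
  gene_depth <- max(depth)
  if (gene_depth <= level) {
    abort("No gene lines below the category level: total gene count would be zero.")
  }

  current <- NA_character_
  cat_out <- character(0)
  gene_out <- character(0)
  n_orphan <- 0L
  for (i in seq_along(depth)) {
    if (depth[i] == level) {
      current <- body[i]
    } else if (depth[i] == gene_depth) {
      if (is.na(current)) {
        n_orphan <- n_orphan + 1L
        next
      }
      gene <- strip_prefix(strsplit(body[i], "\\s+")[[1]][1])
      cat_out <- c(cat_out, current)
      gene_out <- c(gene_out, gene)
    } else if (depth[i] < level) {
      current <- NA_character_
    }
  }
  if (n_orphan > 0L) {
    warn(sprintf("Skipped %d gene line(s) outside any level-%d heading.",
                 n_orphan, level))
  }
  if (length(gene_out) == 0L) {
    abort("No gene lines found under any category heading: total gene count would be zero.")
  }
  dplyr::distinct(tibble(
    organism = organism_code, category = cat_out, gene = gene_out
  ))
}

#' Load a list of oxic reactions
#'
#' Reads a delimited table of oxygen-requiring ("oxic") metabolic reactions,
#' identified by KEGG reaction numbers (`R00010`-style) and/or Enzyme
#' Commission numbers. `rn:`/`ec:` qualifiers are stripped and entries are
#' deduplicated; rows carrying neither identifier are skipped with a
#' warning.
#'
#' @param x A file path or the table text itself. Tab- or comma-delimited
#'   with a header; the identifier columns are recognised by name
#'   (`r_number`/`reaction`/`rn` and `ec_number`/`ec`).
#'
#' @return An object of class `oxic_reactions`: a list with character
#'   vectors `r_numbers` and `ec_numbers`.
#' @export
load_oxic_reactions <- function(x) {
  txt <- paste(as_text_lines(x), collapse = "\n")
  delim <- if (grepl("\t", txt)) "\t" else ","
  tab <- readr::read_delim(I(txt), delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  names(tab) <- tolower(names(tab))
  r_col <- intersect(c("r_number", "reaction", "rn", "r"), names(tab))[1]
  ec_col <- intersect(c("ec_number", "ec"), names(tab))[1]
  if (is.na(r_col) && is.na(ec_col)) {
    abort("No reaction-number or EC-number column found in the oxic list.")
  }
  norm <- function(v) {
    v <- strip_prefix(trimws(v))
    v[!nzchar(v)] <- NA_character_
    v
  }
  r_raw <- if (!is.na(r_col)) norm(tab[[r_col]]) else rep(NA_character_, nrow(tab))
  ec_raw <- if (!is.na(ec_col)) norm(tab[[ec_col]]) else rep(NA_character_, nrow(tab))
  bad_r <- !is.na(r_raw) & !grepl("^R[0-9]{5}$", r_raw)
  if (any(bad_r)) {
    warn(sprintf("Skipped malformed R number(s): %s",
                 paste(unique(r_raw[bad_r]), collapse = ", ")))
    r_raw[bad_r] <- NA_character_
  }
  empty <- is.na(r_raw) & is.na(ec_raw)
  if (any(empty)) {
    warn(sprintf("Skipped %d oxic-list row(s) with neither a valid R number nor an EC number.",
                 sum(empty)))
  }
  out <- list(
    r_numbers = sort(unique(r_raw[!is.na(r_raw)])),
    ec_numbers = sort(unique(ec_raw[!is.na(ec_raw)]))
  )
  if (length(out$r_numbers) == 0L && length(out$ec_numbers) == 0L) {
    abort("The oxic reaction list is empty after normalization.")
  }
  structure(out, class = "oxic_reactions")
}

#' @export
print.oxic_reactions <- function(x, ...) {
  cat(sprintf("<oxic_reactions> %d R numbers, %d EC numbers\n",
              length(x$r_numbers), length(x$ec_numbers)))
  invisible(x)
}

#' Read gene nucleotide lengths from a FASTA file
#'
#' Computes the length in nucleotides of every gene in a (possibly
#' line-wrapped) nucleotide FASTA file. The gene identifier is the first
#' whitespace-delimited token of each header, with any `org:` qualifier
#' stripped.
#'
#' @param x A file path or the FASTA text itself.
#' @param organism_code Short organism identifier recorded in the output.
#'
#' @return A tibble with columns `organism`, `gene`, `length` (nt).
#' @export
read_gene_lengths <- function(x, organism_code) {
  assert_scalar_string(organism_code, "organism_code")
  path <- if (looks_like_path(x)) {
    x
  } else {
    tf <- tempfile(fileext = ".fna")
    writeLines(as_text_lines(x), tf)
    tf
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    abort("No sequences found in the FASTA input.")
  }
  ids <- strip_prefix(vapply(
    strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L
  ))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate gene identifier(s) in FASTA: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  len <- Biostrings::width(seqs)
  if (any(len < 1L)) {
    abort(sprintf("Empty sequence(s) for gene(s): %s",
                  paste(ids[len < 1L], collapse = ", ")))
  }
  tibble(organism = organism_code, gene = ids, length = as.integer(len))
}
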