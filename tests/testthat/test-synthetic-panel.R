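test_that("the panel is byte-identical for a fixed config and seed", {
  cfg <- small_panel_config()
  p1 <- generate_panel(cfg, seed = 5)
  p2 <- generate_panel(cfg, seed = 5)
  expect_identical(p1, p2)
  p3 <- generate_panel(cfg, seed = 6)
  expect_false(identical(p1$traits, p3$traits))
})

test_that("trait draws are unaffected by the annotation-building switch", {
  cfg <- small_panel_config()
  with_ann <- generate_panel(cfg, seed = 9)
  without <- generate_panel(cfg, seed = 9, build_annotations = FALSE)
  expect_identical(with_ann$traits, without$traits)
  expect_identical(
    dplyr::select(with_ann$profiles, -nucleotides),
    dplyr::select(without$profiles, -nucleotides)
  )
})

test_that("the noiseless limit yields an exact power law", {
  cfg <- panel_config(
    n_genera = 24L, q_noise_sd = 0, oxic_noise_sd = 0,
    genome_noise_sd = 0, lifespan_noise_sd = 0, category_noise_sd = 0,
    species_jitter_sd = 0, oxic_effect_on_rate = 0,
    oxic_effect_on_lifespan = 0
  )
  p <- generate_panel(cfg, seed = 1, build_annotations = FALSE)
  fit <- fit_power_law(p$traits$mass_g, p$traits$q_W_per_g)
  expect_equal(fit$beta, cfg$beta_true, tolerance = 1e-10)
})

test_that("taxon apportionment reproduces the configured panel mix", {
  p <- generate_panel(seed = 2, build_annotations = FALSE)
  counts <- table(p$traits$taxon_group)
  expect_equal(nrow(p$traits), 101L)
  expect_equal(unname(counts[["mammal"]]), 12L)
  expect_equal(unname(counts[["bird"]]), 6L)
  expect_equal(unname(counts[["ectothermic_vertebrate"]]), 4L)
  expect_equal(unname(counts[["prokaryote"]]), 65L)
  # lifespan only for mammals and birds; temperature absent for birds/insects
  expect_true(all(is.na(p$traits$lifespan_y[
    !p$traits$taxon_group %in% c("mammal", "bird")])))
  expect_true(all(!is.na(p$traits$lifespan_y[
    p$traits$taxon_group %in% c("mammal", "bird")])))
  expect_true(all(is.na(p$traits$temp_C[p$traits$taxon_group == "bird"])))
})

test_that("reported proportions are exactly the realised integer counts", {
  p <- generate_panel(small_panel_config(), seed = 3)
  expect_identical(p$profiles$proportion,
                   p$profiles$gene_count / p$profiles$total_genes)
  # and agree with a recomputation from the in-memory annotation maps
  for (org in names(p$annotations)[1:3]) {
    ann <- p$annotations[[org]]
    prof <- compute_profile(
      ann$categories,
      oxic_genes = call_oxic_genes(ann$gene_reactions, p$oxic),
      lengths = ann$lengths
    )
    gen <- p$profiles[p$profiles$organism == org, ]
    cmp <- dplyr::inner_join(gen, prof, by = "category",
                             suffix = c(".gen", ".re"))
    expect_equal(nrow(cmp), nrow(gen))
    expect_identical(cmp$proportion.gen, cmp$proportion.re)
    expect_identical(cmp$gene_count.gen, cmp$gene_count.re)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(panel_config(taxon_fracs = c(mammal = 0.7, bird = 0.7)),
               "sum to 1")
  expect_error(panel_config(oxic_base = 0.9, oxic_mass_slope = 0.05),
               "Infeasible")
  expect_error(panel_config(q_noise_sd = -1), ">= 0")
  expect_error(panel_config(gene_count_range = c(100L, 10L)), "ordered")
})

test_that("write_fixture_files emits 3 files per organism plus 2 panel files", {
  p <- generate_panel(small_panel_config(n_genera = 3L), seed = 8)
  dir <- withr::local_tempdir()
  manifest <- write_fixture_files(p, dir, overwrite = TRUE)
  expect_equal(nrow(manifest), 3 * 3 + 2)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_true(all(c("traits.tsv", "oxic_reactions.tsv") %in% manifest$file))
  # refuse to clobber a non-empty directory without consent
  expect_error(write_fixture_files(p, dir), "non-empty")
})

test_that("an empty panel writes only the two panel-level files", {
  p <- generate_panel(small_panel_config(n_genera = 0L), seed = 1)
  expect_equal(nrow(p$traits), 0L)
  dir <- withr::local_tempdir()
  manifest <- write_fixture_files(p, dir, overwrite = TRUE)
  expect_setequal(manifest$file, c("traits.tsv", "oxic_reactions.tsv"))
})

test_that("fixture files are a pure function of the panel", {
  p <- generate_panel(small_panel_config(n_genera = 2L), seed = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_fixture_files(p, d1, overwrite = TRUE)
  m2 <- write_fixture_files(p, d2, overwrite = TRUE)
  expect_identical(m1$checksum, m2$checksum)
})

test_that("profiles recomputed from fixture files equal the planted profiles", {
  p <- generate_panel(small_panel_config(), seed = 12)
  dir <- withr::local_tempdir()
  write_fixture_files(p, dir, overwrite = TRUE)
  reread <- read_fixture_profiles(dir)
  cmp <- dplyr::inner_join(p$profiles, reread,
                           by = c("organism", "category"),
                           suffix = c(".gen", ".read"))
  expect_equal(nrow(cmp), nrow(p$profiles))
  expect_identical(cmp$proportion.gen, cmp$proportion.read)
  expect_identical(cmp$gene_count.gen, cmp$gene_count.read)
  expect_equal(cmp$nucleotides.gen, as.numeric(cmp$nucleotides.read))
})

test_that("planted mass-genome and oxic-rate associations are positive", {
  ok <- vapply(1:20, function(s) {
    p <- generate_panel(seed = 6000 + s, build_annotations = FALSE)
    g <- p$truth$genus_latent
    spearman(g$mass_log10, g$genome_log10, p_method = "t")$r > 0 &&
      spearman(g$oxic_realized, exp(g$ln_q), p_method = "t")$r > 0
  }, logical(1))
  expect_true(all(ok))
})
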