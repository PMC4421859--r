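test_that("unit conversions reach canonical units", {
  expect_equal(convert_mass(2, "kg"), 2000)
  expect_equal(convert_rate(500, "mW"), 0.5)
  expect_equal(convert_temperature(298.15, "K"), 25)
  expect_error(convert_mass(1, "stone"), "Unknown mass unit")
})

test_that("unit conversion composed with its inverse is the identity", {
  x <- c(0.004, 1, 250, 9.81e6)
  for (u in c("kg", "mg", "ug", "pg")) {
    factor <- convert_mass(1, u)
    expect_equal(convert_mass(x, u) / factor, x, tolerance = 1e-12)
  }
  # the affine Kelvin conversion loses a few digits to cancellation at
  # small magnitudes; the multiplicative conversions above hold to 1e-12
  expect_equal(convert_temperature(convert_temperature(x, "C") + 273.15, "K"),
               x)
})

test_that("convert_units maps value/unit column pairs", {
  raw <- tibble::tibble(
    species = "A b", genus = "A", taxon_group = "mammal",
    mass = 2, mass_unit = "kg", rate = 500, rate_unit = "mW",
    temp = 310.15, temp_unit = "K"
  )
  out <- convert_units(raw)
  expect_equal(out$mass_g, 2000)
  expect_equal(out$rate_W, 0.5)
  expect_equal(out$temp_C, 37)
})

test_that("derive_mass_specific is the guarded quotient", {
  expect_equal(derive_mass_specific(1, 1000), 0.001)
  expect_equal(derive_mass_specific(7.3, 7.3), 1)
  set.seed(8)
  b <- runif(20, 0.01, 100); m <- runif(20, 0.1, 1e5)
  expect_equal(derive_mass_specific(b, m), b / m)
  expect_error(derive_mass_specific(1, 0), "positive")
})

test_that("add_mass_specific fills gaps and flags conflicts", {
  d <- tibble::tibble(
    species = c("A a", "B b"), genus = c("A", "B"),
    taxon_group = "mammal", mass_g = c(100, 100),
    rate_W = c(1, 1), q_W_per_g = c(NA, 0.5)
  )
  expect_warning(out <- add_mass_specific(d), "conflicts.*B b")
  expect_equal(out$q_W_per_g[1], 0.01)
})

test_that("genus averaging means present members and preserves singletons", {
  d <- tibble::tibble(
    species = c("A a", "A b", "A c", "B b"),
    genus = c("A", "A", "A", "B"),
    taxon_group = c(rep("mammal", 3), "bird"),
    mass_g = c(2, 4, 3, 7),
    lifespan_y = c(10, NA, 14, 3),
    temp_C = c(37, 38, NA, NA)
  )
  out <- genus_average(d)
  a <- out[out$genus == "A", ]
  expect_equal(a$mass_g, 3)
  expect_equal(a$lifespan_y, 12)
  expect_equal(a$temp_C, 37.5)
  b <- out[out$genus == "B", ]
  expect_equal(b$mass_g, 7)
  expect_equal(b$n_species, 1L)
})

test_that("genus averaging is permutation-invariant and idempotent", {
  set.seed(21)
  d <- tibble::tibble(
    species = sprintf("G%d s%d", rep(1:4, each = 3), 1:3),
    genus = sprintf("G%d", rep(1:4, each = 3)),
    taxon_group = rep(c("mammal", "prokaryote", "bird", "insect"), each = 3),
    mass_g = runif(12, 1, 100),
    q_W_per_g = runif(12, 0.001, 0.1)
  )
  out <- genus_average(d)
  out_perm <- genus_average(d[sample(nrow(d)), ])
  expect_equal(out, out_perm)
  again <- genus_average(
    dplyr::mutate(out, species = genus)[, c("species", "genus", "taxon_group",
                                            "mass_g", "q_W_per_g")]
  )
  expect_equal(again$mass_g, out$mass_g)
  expect_equal(again$q_W_per_g, out$q_W_per_g)
})

test_that("conflicting taxon_group within a genus is an error", {
  d <- tibble::tibble(
    species = c("A a", "A b"), genus = "A",
    taxon_group = c("mammal", "bird"), mass_g = c(1, 2)
  )
  expect_error(genus_average(d), "Conflicting taxon_group")
})

test_that("representative genome selection prefers the earliest year", {
  expect_equal(select_representative(tibble::tibble(
    genome_code = c("xb", "xa"), genome_year = c(2003, 2008)
  )), "xb")
  expect_equal(select_representative(tibble::tibble(
    genome_code = "only", genome_year = 2011
  )), "only")
  expect_message(
    code <- select_representative(tibble::tibble(
      genome_code = c("b", "a"), genome_year = c(2005, 2005)
    )),
    "tie"
  )
  expect_equal(code, "a")
  expect_error(select_representative(tibble::tibble(
    genome_code = "x", genome_year = NA_integer_
  )), "year")
})

test_that("collapse_to_genus attaches the representative genome", {
  d <- tibble::tibble(
    species = c("A a", "A b"), genus = "A", taxon_group = "mammal",
    mass_g = c(10, 20), q_W_per_g = c(0.01, 0.02),
    genome_code = c("ga", "gb"), genome_bp = c(3e9, 2e9),
    genome_year = c(2010, 2001)
  )
  out <- collapse_to_genus(d)
  expect_equal(out$genome_code, "gb")
  expect_equal(out$genome_bp, 2e9)
  expect_equal(out$mass_g, 15)
})

test_that("trait tables survive a TSV round trip", {
  panel <- generate_panel(small_panel_config(), seed = 4,
                          build_annotations = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trait_table(panel$traits, path)
  back <- read_trait_table(path)
  expect_equal(back$mass_g, panel$traits$mass_g, tolerance = 1e-12)
  expect_equal(back$taxon_group, panel$traits$taxon_group)
  expect_equal(back$volant, panel$traits$volant)
})
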