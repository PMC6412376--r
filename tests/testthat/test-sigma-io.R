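test_that("COSMO files parse segment blocks and metadata", {
  f <- write_tmp(cosmo_text(c(1, 2, 3), c(0.001, -0.002, 0.001),
                            compound = "tri"))
  s <- read_cosmo_file(f)
  expect_s3_class(s, "sigma_surface")
  expect_equal(s$total_area, 6)
  expect_equal(s$compound_id, "tri")
  expect_equal(s$area, c(1, 2, 3))
  expect_equal(s$charge_density, c(0.001, -0.002, 0.001))
})

test_that("anion sign convention: screening charge mirrors formal charge", {
  # area-weighted screening charge about +1 e for a -1 anion
  f <- write_tmp(cosmo_text(c(40, 40), c(0.0125, 0.0125),
                            compound = "an", charge = -1L))
  s <- read_cosmo_file(f)
  expect_equal(s$formal_charge, -1L)
  expect_equal(sum(s$area * s$charge_density), 1, tolerance = 0.05)
})

test_that("COSMO parse failures are specific", {
  f <- write_tmp(c("$info", "compound = x", "no segments here"))
  expect_error(read_cosmo_file(f), "segment_information")
  f2 <- write_tmp(c("$segment_information",
                    "1 1 0 0 0 0.1 1.0 0.001 0",
                    "2 1 0 0 0 0.1 oops 0.001 0"))
  expect_error(read_cosmo_file(f2), "line 3")
  expect_error(read_cosmo_file(tempfile()), "not found")
})

test_that("COSMO write/read round trip is the identity", {
  for (seed in 1:5) {
    s <- random_surface(50, seed = seed)
    f <- tempfile(fileext = ".cosmo")
    write_cosmo_file(s, f)
    s2 <- read_cosmo_file(f)
    expect_equal(s2$area, s$area, tolerance = 1e-12)
    expect_equal(s2$charge_density, s$charge_density, tolerance = 1e-12)
    expect_equal(s2$total_area, s$total_area, tolerance = 1e-12)
    expect_equal(s2$formal_charge, s$formal_charge)
    expect_equal(s2$position, s$position, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # large synthetic surface
  big <- generate_surface(
    profile_spec(500, -1L, data.frame(center = 0.002, width = 0.004,
                                      weight = 1), seed = 42),
    n_segments = 10000L)
  f <- tempfile(fileext = ".cosmo")
  write_cosmo_file(big, f)
  big2 <- read_cosmo_file(f, charge_tol = 1e-4)
  expect_equal(big2$charge_density, big$charge_density, tolerance = 1e-12)
  expect_equal(big2$total_area, big$total_area, tolerance = 1e-12)
})

test_that("invalid surfaces are refused", {
  expect_error(sigma_surface("x", numeric(0), numeric(0)), "non-empty")
  expect_error(sigma_surface("x", c(1, -1), c(0, 0)), "area must be > 0")
  # inconsistent net charge vs declared formal charge
  expect_error(sigma_surface("x", c(10, 10), c(0.05, 0.05),
                             formal_charge = 0L), "inconsistent")
})

test_that("sigma-profile tables read verbatim on a matching grid", {
  pr <- bump_profile(grid51, 0, 0.004, 120, id = "b")
  f <- tempfile(fileext = ".sigma")
  write_sigma_profile(pr, f)
  pr2 <- read_sigma_profile(f, grid51)
  expect_equal(pr2$p, pr$p, tolerance = 1e-12)
  expect_equal(sum(pr2$p), 120, tolerance = 1e-9)
})

test_that("re-binning from a finer grid conserves total area", {
  fine <- sigma_grid(-0.025, 0.025, 101L)
  pr <- bump_profile(fine, 0.003, 0.005, 77)
  f <- tempfile(fileext = ".sigma")
  write_sigma_profile(pr, f)
  pr2 <- read_sigma_profile(f, grid51)
  expect_equal(sum(pr2$p), sum(pr$p), tolerance = 1e-9 * 77)
  # and the first moment is conserved by the linear split
  expect_equal(sum(grid51$centers * pr2$p), sum(fine$centers * pr$p),
               tolerance = 1e-9)
})

test_that("malformed profile tables are rejected", {
  expect_error(
    read_sigma_profile(write_tmp(c("0.001 1.0", "0.000 2.0"), ".sigma")),
    "strictly increasing")
  expect_error(
    read_sigma_profile(write_tmp(c("0.000 1.0", "0.001 -2.0"), ".sigma")),
    "negative")
  expect_error(
    read_sigma_profile(write_tmp(c("# only comments"), ".sigma")),
    "no data rows")
})

test_that("the packaged default manifest defines the 352-combination screen", {
  m <- read_manifest(default_manifest_path())
  expect_equal(nrow(m$cations), 16L)
  expect_equal(nrow(m$anions), 22L)
  expect_equal(m$n_combinations, 352L)
  expect_equal(m$temperature, 298.15)
  expect_equal(m$solute_id, "EPA")
  expect_equal(m$anions$charge[m$anions$id == "SO4"], -2L)
  expect_true(all(m$anions$charge[m$anions$id != "SO4"] == -1L))
})

test_that("manifest validation catches duplicates and defaults temperature", {
  f <- write_tmp(manifest_text("A", c("X", "Y")), ".yaml")
  m <- read_manifest(f)
  expect_equal(m$n_combinations, 2L)

  f1 <- write_tmp(manifest_text("A", "X", temperature = NULL), ".yaml")
  expect_message(m1 <- read_manifest(f1), "298.15")
  expect_equal(m1$temperature, 298.15)
  expect_equal(m1$n_combinations, 1L)

  fdup <- write_tmp(manifest_text("A", c("X", "X")), ".yaml")
  expect_error(read_manifest(fdup), "duplicate")
})
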