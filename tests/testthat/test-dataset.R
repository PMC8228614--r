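test_that("packaged dataset matches the published tables and splits", {
  ds <- load_pae_dataset()
  expect_equal(nrow(ds$registry), 14L)
  expect_false(anyDuplicated(ds$registry$abbrev) > 0)

  ld50 <- ds$endpoints$LD50
  ic50 <- ds$endpoints$IC50_72h
  nrf2 <- ds$endpoints$Nrf2
  expect_equal(nrow(ld50), 13L)
  expect_equal(nrow(ic50), 7L)
  expect_equal(nrow(nrf2), 7L)
  expect_equal(sum(ld50$role == "train"), 10L)
  expect_setequal(ld50$abbrev[ld50$role == "test"],
                  c("DMEP", "DEP", "DIDP"))
  expect_setequal(ic50$abbrev[ic50$role == "test"], c("DPHP", "DHXP"))
  expect_setequal(nrf2$abbrev[nrf2$role == "test"], c("DEP", "DHXP"))
  expect_equal(ld50$raw_value[ld50$abbrev == "DIDP"], 64000)

  # Nrf2 is modeled untransformed
  expect_equal(nrf2$transformed_value, nrf2$raw_value)
})

test_that("lg transform reproduces printed Exp. columns to 4 decimals", {
  expect_equal(round(lg_transform(6800), 4), 3.8325)
  expect_equal(round(lg_transform(1160), 4), 3.0645)
  expect_equal(lg_transform(1), 0)
  expect_error(lg_transform(0), "positive")
  expect_error(lg_transform(-3), "positive")

  for (ep in c("LD50", "IC50_72h")) {
    tab <- load_endpoint_table(ep)
    # agreement at each entry's own printed precision (two IC50 rows,
    # DNP and DNOP, are printed at 3 decimals)
    expect_true(all(matches_printed(lg_transform(tab$raw_value),
                                    tab$transformed_value)),
                info = ep)
  }
  ld50 <- load_endpoint_table("LD50")
  expect_true(all(abs(lg_transform(ld50$raw_value) -
                        ld50$transformed_value) <= 5e-5))
})

test_that("residual arithmetic matches printed tables, anomalies flagged", {
  expect_equal(residual(3.8325, 3.791), 0.0415)
  expect_equal(round(residual(0.6449, 0.646), 4), -0.0011)
  expect_equal(residual(2.5, 2.5), 0)
  expect_error(residual(NA, 1), "finite")

  # the IC50 CoMSIA column is internally inconsistent for five rows
  # (Exp - Pred != printed Res; values appear row-shifted)
  ic <- flag_residual_anomalies(load_reference_predictions("IC50_72h"))
  bad <- ic[ic$res_inconsistent, ]
  expect_setequal(paste(bad$abbrev, bad$model),
                  paste(c("DNP", "DIDP", "DHXP", "DNOP", "DPHP"), "CoMSIA"))

  # every other printed (Exp, Pred, Res) triple is consistent to 1e-4
  for (ep in PAE_ENDPOINTS) {
    tab <- flag_residual_anomalies(load_reference_predictions(ep))
    ok <- tab[!tab$res_inconsistent, ]
    expect_true(all(abs(residual(ok$exp, ok$pred) - ok$res) <= 1e-4),
                info = ep)
    if (ep != "IC50_72h") expect_false(any(tab$res_inconsistent), info = ep)
  }
})

test_that("endpoint tables round-trip through CSV exactly", {
  for (ep in PAE_ENDPOINTS) {
    tab <- load_endpoint_table(ep)
    path <- withr::local_tempfile(fileext = ".csv")
    write_endpoint_csv(tab, path)
    back <- read_endpoint_csv(path)
    expect_identical(back$abbrev, tab$abbrev)
    expect_identical(back$raw_value, tab$raw_value)
    expect_identical(back$transformed_value, tab$transformed_value)
    expect_identical(back$role, tab$role)
    expect_identical(attr(back, "endpoint"), ep)
  }
})

test_that("JSON export carries the full dataset", {
  path <- withr::local_tempfile(fileext = ".json")
  export_dataset_json(path)
  back <- jsonlite::fromJSON(path)
  expect_equal(nrow(back$registry), 14L)
  expect_equal(nrow(back$endpoints$LD50), 13L)
  expect_equal(back$endpoints$Nrf2$transformed_value,
               load_endpoint_table("Nrf2")$transformed_value)
})
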