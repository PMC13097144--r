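test_that("FCS write/read round-trips values and metadata", {
  tb <- tiny_table(500)
  f <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tb, f)
  back <- read_fcs(f)
  expect_identical(channels(back), channels(tb))
  expect_equal(back$exprs, tb$exprs)   # doubles stored exactly
  expect_identical(n_events(back), 500L)

  # with a time channel: seconds survive the $TIMESTEP scaling
  tb2 <- event_table(tb$exprs, time = sort(runif(500, 0, 30)))
  f2 <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tb2, f2, timestep = 0.01)
  back2 <- read_fcs(f2)
  expect_equal(back2$time, tb2$time, tolerance = 1e-12)
  expect_true("Time" %in% channels(back2))
})

test_that("FCS reader enforces format and required keywords", {
  f <- withr::local_tempfile(fileext = ".fcs")
  writeBin(charToRaw(sprintf("%-58s", "FCS9.9")), f)
  expect_error(read_fcs(f), "FCS 3.0/3.1")

  # strip a required keyword from a valid file
  g <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tiny_table(10), g)
  raw <- readBin(g, "raw", file.size(g))
  pat <- charToRaw("$DATATYPE")
  hit <- which(raw == pat[1])
  hit <- hit[vapply(hit, function(i)
    identical(raw[i:(i + length(pat) - 1L)], pat), logical(1))][1]
  raw[hit + 1L] <- charToRaw("X")  # $DATATYPE -> $XATATYPE
  writeBin(raw, g)
  expect_error(read_fcs(g), "\\$DATATYPE")
})

test_that("compensation inverts a constructed spillover exactly", {
  set.seed(7)
  n <- 400
  truth <- cbind(`VL1-A` = rlnorm(n, 5, 1), `BL5-A` = rlnorm(n, 6, 1))
  sp <- spillover_matrix(matrix(c(1, 0.1, 0.1, 1), 2, 2,
                                dimnames = list(c("VL1-A", "BL5-A"),
                                                c("VL1-A", "BL5-A"))))
  tb <- event_table(cbind(`FSC-A` = runif(n), truth))
  mixed <- mix_spillover(tb, sp)
  expect_false(isTRUE(all.equal(mixed$exprs[, "VL1-A"], truth[, "VL1-A"])))
  comp <- apply_compensation(mixed, sp)
  expect_equal(comp$exprs[, c("VL1-A", "BL5-A")], truth, tolerance = 1e-12)
  # scatter untouched
  expect_identical(comp$exprs[, "FSC-A"], tb$exprs[, "FSC-A"])
})

test_that("compensation validates its inputs", {
  tb <- tiny_table(50)
  sp_id <- spillover_matrix(diag(2) |>
    `dimnames<-`(list(c("VL1-A", "BL5-A"), c("VL1-A", "BL5-A"))))
  expect_equal(apply_compensation(tb, sp_id)$exprs, tb$exprs)
  sp_absent <- spillover_matrix(diag(2) |>
    `dimnames<-`(list(c("YL9-A", "BL5-A"), c("YL9-A", "BL5-A"))))
  expect_error(apply_compensation(tb, sp_absent), "absent")
  m <- matrix(c(1, 1, 1, 1), 2, 2,
              dimnames = list(c("VL1-A", "BL5-A"), c("VL1-A", "BL5-A")))
  expect_error(spillover_matrix(m), "singular")
})

test_that("spillover matrix round-trips through CSV", {
  sp <- spillover_matrix(matrix(c(1, 0.07, 0.02, 1), 2, 2,
                                dimnames = list(c("VL1-A", "BL5-A"),
                                                c("VL1-A", "BL5-A"))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spillover(sp, f)
  expect_equal(unclass(read_spillover(f)), unclass(sp))
})

test_that("plate layout builds, validates, and round-trips CSV", {
  lay <- plate_layout_default()
  expect_identical(nrow(lay), 384L)
  expect_identical(sum(lay$role == "dmso_positive"), 8L)
  expect_identical(sum(lay$role == "cd4_only_negative"), 4L)
  expect_identical(sum(lay$role == "unstained"), 4L)
  expect_true(all(lay$concentration_um[lay$role == "compound"] == 10))
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_layout(lay, f)
  expect_equal(as.data.frame(read_plate_layout(f)), as.data.frame(lay))

  bad <- as.data.frame(lay); bad$role[1] <- "mystery"
  expect_error(validate_plate_layout(bad), "unknown well role")
  bad2 <- as.data.frame(lay); bad2$well[1] <- "Q1"
  expect_error(validate_plate_layout(bad2), "invalid 384-well")
  serp <- well_names_384("serpentine")
  expect_identical(serp[25], "B24")
})
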