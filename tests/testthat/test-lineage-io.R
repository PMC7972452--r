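test_that("native format round-trips through write/read", {
  # identity case: one cell, three frames
  tmp <- withr::local_tempfile(fileext = ".tsv")
  d <- data.frame(embryo_id = "e1", cell_name = "AB", frame = 1:3,
                  time_min = c(0, 2.5, 5), x = 1:3, y = 0, z = 0,
                  diameter = 5, parent_name = NA)
  write.table(d, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  embs <- read_native(tmp)
  expect_length(embs, 1)
  expect_equal(nrow(embs[["e1"]]$data), 3)
  expect_equal(unique(embs[["e1"]]$data$cell), "AB")

  # round trip on a simulated embryo
  e <- simulate_embryo(fx_sim_config(), "wild_type", 31)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_native(e, f)
  back <- read_native(f)[[1]]
  expect_equal(back$data$cell, e$data$cell)
  expect_equal(back$data$x, e$data$x, tolerance = 1e-10)
  expect_equal(back$data$parent, e$data$parent)
  # writing again reproduces the same bytes
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_native(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("structural validation rejects malformed tables", {
  base <- data.frame(embryo_id = "e1",
                     cell_name = c("AB", "ABa", "ABp"),
                     frame = c(1, 2, 2), time_min = c(0, 2.5, 2.5),
                     x = 0, y = 0, z = 0, diameter = 5,
                     parent_name = c(NA, "AB", "AB"))
  write_tab <- function(d) {
    f <- tempfile(fileext = ".tsv")
    write.table(d, f, sep = "\t", row.names = FALSE, quote = FALSE)
    f
  }
  expect_length(read_native(write_tab(base)), 1)
  # missing mandatory column
  expect_error(read_native(write_tab(base[, -3])), "format error")
  # parent referring to a nonexistent cell
  bad <- base; bad$parent_name[2] <- "ABx"
  expect_error(read_native(write_tab(bad)), "structure error")
  # one daughter only
  expect_error(read_native(write_tab(base[1:2, ])), "daughter")
  # duplicate (cell, frame)
  dup <- rbind(base, base[2, ])
  expect_error(read_native(write_tab(dup)), "duplication error")
  # daughters overlapping the mother's track
  ovl <- base; ovl$frame[2:3] <- 1
  expect_error(read_native(write_tab(ovl)), "overlap")
})

# writes a minimal AceTree-dialect nuclei directory; positions in pixels
# (x, y) and planes (z). Layout per timepoint row:
# index, valid, pred, succ1, succ2, x, y, z, diameter, name
write_starrynite_fixture <- function(dir, invalid_all = FALSE,
                                     break_chain = FALSE) {
  dir.create(dir, showWarnings = FALSE)
  v <- if (invalid_all) 0 else 1
  lines <- list(
    t001 = sprintf("1,%d,-1,1,2,100,50,10,40,AB", v),
    t002 = c(sprintf("1,%d,1,-1,-1,110,52,10,38,ABa", v),
             sprintf("2,%d,1,-1,-1,130,60,12,38,ABp", v)))
  if (break_chain)
    lines$t002[1] <- sub(",1,-1,-1,110", ",7,-1,-1,110", lines$t002[1])
  for (nm in names(lines))
    writeLines(lines[[nm]], file.path(dir, paste0(nm, "-nuclei")))
  dir
}

test_that("StarryNite reader reconstructs divisions and calibrates", {
  dir <- write_starrynite_fixture(tempfile("sn"))
  e <- read_starrynite(dir, xy_res = 0.14, z_res = 0.75)
  expect_setequal(unique(e$data$cell), c("AB", "ABa", "ABp"))
  tr <- cell_tracks(e)
  expect_equal(tr$n_daughters[tr$cell == "AB"], 2)
  expect_equal(tr$parent[tr$cell == "ABa"], "AB")
  # pixel/plane coordinates scale by the supplied calibration
  aba <- e$data[e$data$cell == "ABa", ]
  expect_equal(aba$x, 110 * 0.14)
  expect_equal(aba$z, 10 * 0.75)
  expect_equal(aba$time_min, (2 - 1) * 2.5)
})

test_that("StarryNite reader handles degenerate inputs", {
  expect_error(read_starrynite(tempfile("none")), "xy_res")
  dir <- write_starrynite_fixture(tempfile("sn"), invalid_all = TRUE)
  expect_warning(e <- read_starrynite(dir, xy_res = 0.14, z_res = 0.75),
                 "invalid")
  expect_equal(nrow(e$data), 0)
  dir2 <- write_starrynite_fixture(tempfile("sn"), break_chain = TRUE)
  expect_error(read_starrynite(dir2, xy_res = 0.14, z_res = 0.75),
               "predecessor chain")
})

test_that("metadata table round-trips and attaches to embryos", {
  md <- data.frame(embryo_id = "e1", group = "control",
                   relative_AB_size = 60.2, compression_um = 22,
                   outcome = "alive", frame_interval_min = 2.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_metadata(md, f)
  back <- read_metadata(f)
  expect_equal(back$relative_AB_size, 60.2)
  d <- data.frame(embryo_id = "e1", cell_name = "AB", frame = 1:3,
                  time_min = c(0, 2.5, 5), x = 1:3, y = 0, z = 0,
                  diameter = 5, parent_name = NA)
  ftab <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, ftab, sep = "\t", row.names = FALSE, quote = FALSE)
  e <- read_native(ftab, metadata = back)[[1]]
  expect_equal(e$metadata$group, "control")
  expect_equal(e$metadata$outcome, "alive")
})
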