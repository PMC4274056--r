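test_that("a batch combines every dendrite of every image", {
  dir <- tempfile("batch"); dir.create(dir)
  for (i in 1:2) write_batch_image(dir, paste0("img", i), seed = i)
  cfg <- quiet_batch_config(images = file.path(dir, "*.tif"),
                            out_dir = file.path(dir, "out"),
                            channel = "GRAY", t_min = 70, timestamp = FALSE)
  res <- run_batch(cfg)
  expect_identical(res$status, 0L)
  tab <- read.delim(file.path(dir, "out", "dendrites.tsv"))
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$image, c("img1", "img2"))
  expect_true(all(tab$puncta_count == 6L)) # planted blobs per image
  expect_identical(nrow(read.delim(file.path(dir, "out", "spines.tsv"))), 6L)
  # puncta conservation across tables
  pt <- read.delim(file.path(dir, "out", "puncta.tsv"))
  expect_identical(nrow(pt), sum(tab$puncta_count))
})

test_that("identical runs are byte-identical when the timestamp is disabled", {
  dir <- tempfile("repro"); dir.create(dir)
  for (i in 1:2) write_batch_image(dir, paste0("img", i), seed = 10 + i)
  cfg <- quiet_batch_config(images = file.path(dir, "*.tif"),
                            out_dir = file.path(dir, "o1"),
                            channel = "GRAY", t_min = 70, timestamp = FALSE)
  run_batch(cfg)
  run_batch(cfg, out_dir = file.path(dir, "o2"))
  for (f in c("dendrites.tsv", "puncta.tsv", "spines.tsv", "groups.tsv",
              "run_metadata.json")) {
    a <- readBin(file.path(dir, "o1", f), "raw", file.size(file.path(dir, "o1", f)))
    b <- readBin(file.path(dir, "o2", f), "raw", file.size(file.path(dir, "o2", f)))
    expect_identical(a, b)
  }
})

test_that("threshold overrides carry forward to subsequent images", {
  dir <- tempfile("ovr"); dir.create(dir)
  for (i in 1:4) write_batch_image(dir, sprintf("img%02d", i), seed = 20 + i)
  cfg <- quiet_batch_config(images = file.path(dir, "*.tif"),
                            out_dir = file.path(dir, "out"),
                            channel = "GRAY", t_min = 70, timestamp = FALSE)
  cfg <- override_threshold(cfg, "img02", 90)
  res <- run_batch(cfg)
  th <- unlist(res$per_image_thresholds)
  expect_identical(th[["img01"]], 70L)
  expect_identical(th[["img02"]], 90L)
  expect_identical(th[["img03"]], 90L)
  expect_identical(th[["img04"]], 90L)
  # the audit trail is in the metadata JSON too
  meta <- jsonlite::read_json(file.path(dir, "out", "run_metadata.json"))
  expect_identical(meta$per_image_thresholds$img03, 90L)
  expect_error(override_threshold(cfg, "img01", 300), "\\[0, 255\\]")
})

test_that("per-image failures skip the image without aborting the batch", {
  dir <- tempfile("fail"); dir.create(dir)
  for (i in 1:2) write_batch_image(dir, paste0("ok", i), seed = 30 + i)
  writeLines("corrupt", file.path(dir, "bad.tif")) # no sidecar, unreadable
  cfg <- quiet_batch_config(images = file.path(dir, "*.tif"),
                            out_dir = file.path(dir, "out"),
                            channel = "GRAY", t_min = 70, timestamp = FALSE)
  expect_warning(res <- run_batch(cfg), "skipped")
  expect_identical(res$status, 0L)
  expect_identical(sort(names(res$per_image_thresholds)), c("ok1", "ok2"))
  expect_error(run_batch(quiet_batch_config(
    images = file.path(dir, "none-*.tif"), out_dir = dir, channel = "GRAY",
    t_min = 70)), "no images match")
})

test_that("images without an ROI sidecar are skipped with a warning", {
  dir <- tempfile("noroi"); dir.create(dir)
  write_batch_image(dir, "has", seed = 41)
  fx <- generate_fixture(random_fixture_spec(3, shape = c(48L, 48L), seed = 42))
  save_image(fx$frame, file.path(dir, "lacks.tif"))
  cfg <- quiet_batch_config(images = file.path(dir, "*.tif"),
                            out_dir = file.path(dir, "out"),
                            channel = "GRAY", t_min = 70, timestamp = FALSE)
  expect_warning(res <- run_batch(cfg), "no ROI sidecar")
  expect_identical(names(res$per_image_thresholds), "has")
})

test_that("batch configs round-trip through JSON with nested sections", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    images = "x/*.tif", out_dir = "out", channel = "G",
    marker_channel = "R", marker_threshold = 50, pixel_size = 0.2,
    detection = list(t_min = 80, step = 2, min_size = 5),
    spine_rules = list(mushroom_head_neck_ratio = 1.8),
    overrides = list(img2 = 95), timestamp = FALSE
  ), path, auto_unbox = TRUE)
  cfg <- read_batch_config(path)
  expect_identical(cfg$params$t_min, 80L)
  expect_identical(cfg$params$step, 2L)
  expect_identical(cfg$params$min_size, 5L)
  expect_identical(cfg$marker_channel, "R")
  expect_equal(cfg$spine_rules$mushroom_head_neck_ratio, 1.8)
  expect_identical(cfg$overrides$img2, 95L)
  expect_error(quiet_batch_config(images = "x", out_dir = "o", channel = "G",
                                  marker_channel = "G"), "differ")
})

test_that("marker filtering removes puncta outside the transfection fill", {
  dir <- tempfile("marker"); dir.create(dir)
  # blobs on one row; marker band covers only the left half of the image
  blobs <- lapply(c(20, 40, 60, 80), function(cc)
    list(center = c(24, cc), amp = 220, sigma = 1.8))
  spec <- fixture_spec(c(48L, 100L), blobs, seed = 60,
                       marker = list(centerline = rbind(c(24, 0), c(24, 40)),
                                     half_width = 10))
  fx <- generate_fixture(spec)
  expect_identical(fx$frame$channels, c("R", "G", "B"))
  save_image(fx$frame, file.path(dir, "m1.tif"))
  jsonlite::write_json(list(regions = list(list(
    id = "d1", kind = "dendrite", mode = "fixed_width",
    centerline = list(c(24, 2), c(24, 97)), half_width_um = 12,
    group = "transfected"))),
    file.path(dir, "m1.rois.json"), auto_unbox = TRUE, digits = NA)
  base <- quiet_batch_config(images = file.path(dir, "m1.tif"),
                             out_dir = file.path(dir, "o_nofilter"),
                             channel = "G", t_min = 70, timestamp = FALSE)
  res_all <- run_batch(base)
  expect_identical(res_all$dendrites$puncta_count, 4L)
  filt <- quiet_batch_config(images = file.path(dir, "m1.tif"),
                             out_dir = file.path(dir, "o_filter"),
                             channel = "G", marker_channel = "R",
                             marker_threshold = 50, t_min = 70,
                             timestamp = FALSE)
  res_f <- run_batch(filt)
  # only the two blobs under the marker band survive
  expect_identical(res_f$dendrites$puncta_count, 2L)
})

test_that("the command-line driver analyses a single image end to end", {
  dir <- tempfile("cli"); dir.create(dir)
  write_batch_image(dir, "img1", seed = 50, with_spines = FALSE)
  exe <- system.file("exec", "punctanal", package = "punctanal")
  out <- file.path(dir, "cliout")
  st <- system2("Rscript", c(exe, "detect", "--image",
                             file.path(dir, "img1.tif"), "--rois",
                             file.path(dir, "img1.rois.json"), "--tmin", "70",
                             "--channel", "GRAY", "--out", out),
                stdout = TRUE, stderr = TRUE)
  expect_identical(attr(st, "status"), NULL) # exit 0
  tab <- read.delim(file.path(out, "dendrites.tsv"))
  expect_identical(tab$puncta_count, 6L)
})
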