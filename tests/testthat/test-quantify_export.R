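# build a dendrite region with k well-separated bright blocks inside the band
make_dendrite_with_puncta <- function(k, length_px = 120, pixel_size = 1,
                                      group = "default", id = "d1",
                                      image_shape = c(40L, 140L)) {
  d <- suppressWarnings(dendrite_region(
    id, rbind(c(20, 5), c(20, 5 + length_px)), half_width_um = 8 * pixel_size,
    group = group, pixel_size = pixel_size, image_shape = image_shape))
  ch <- matrix(0L, image_shape[1], image_shape[2])
  if (k > 0) {
    at <- round(seq(10, 5 + length_px - 5, length.out = k))
    for (c0 in at) ch[20:21, c0:(c0 + 1)] <- 200L
  }
  det <- detect_puncta(ch, d$mask, detection_params(70), pixel_size)
  stopifnot(nrow(det$puncta) == k)
  attach_puncta(d, det)
}

test_that("per-dendrite statistics follow the density and intensity definitions", {
  d <- make_dendrite_with_puncta(5, length_px = 50)
  st <- dendrite_stats(d, image = "img1")
  expect_identical(st$puncta_count, 5L)
  expect_equal(st$length_um, 50)
  expect_equal(st$puncta_density_per_um, 0.1)
  expect_equal(st$puncta_density_per_10um, 1.0)
  expect_equal(st$puncta_density_per_um * st$length_um, st$puncta_count)
  # each punctum: 4 px of 200 -> integrated 800, average 200
  expect_equal(st$mean_avg_intensity, 200)
  expect_equal(st$mean_integrated_intensity, 800)
  expect_equal(st$total_puncta_intensity_per_um, 5 * 800 / 50)
  expect_true(is.na(st$puncta_per_spine)) # no spines attached
})

test_that("puncta per spine and spine densities are joined per dendrite", {
  d <- make_dendrite_with_puncta(6, length_px = 60)
  recs <- lapply(1:3, function(i) list(id = paste0("s", i), dendrite = "d1",
    landmarks = list(base = c(20, 10 * i), tip = c(23, 10 * i),
                     head = rbind(c(22, 10 * i - 1), c(22, 10 * i + 1)),
                     neck = rbind(c(21, 10 * i - 0.2), c(21, 10 * i + 0.2)))))
  d <- attach_spines(d, classify_spines(recs))
  st <- dendrite_stats(d)
  expect_identical(st$spine_count, 3L)
  expect_equal(st$puncta_per_spine, 2.0)
  expect_equal(st$spine_density_per_um, 0.05)
  expect_equal(st$mushroom_density_per_um + st$thin_density_per_um +
               st$stubby_density_per_um + st$filopodia_density_per_um,
               st$spine_density_per_um)
})

test_that("group statistics average per dendrite, not pooled over puncta", {
  d1 <- dendrite_stats(make_dendrite_with_puncta(2, 20, id = "a", group = "g"))
  d2 <- dendrite_stats(make_dendrite_with_puncta(6, 40, id = "b", group = "g"))
  dd <- rbind(d1, d2)
  g <- group_stats(dd)
  expect_identical(g$n_dendrites, 2L)
  per_dendrite_mean <- mean(c(2 / 20, 6 / 40))
  pooled <- (2 + 6) / (20 + 40)
  expect_equal(g$mean_puncta_density_per_um, per_dendrite_mean)
  expect_equal(g$pooled_puncta_density_per_um, pooled)
  expect_false(isTRUE(all.equal(per_dendrite_mean, pooled)))
  expect_equal(g$sd_puncta_density_per_um, sd(c(0.1, 0.15)))
  # single-dendrite group: mean equals the value, sd 0
  g1 <- group_stats(d1)
  expect_equal(g1$mean_puncta_density_per_um, 0.1)
  expect_equal(g1$sd_puncta_density_per_um, 0)
  expect_warning(group_stats(dd[0, ]), "no dendrites")
})

test_that("region intensities sum and average over the rasterized mask", {
  sq <- rbind(c(0.5, 0.5), c(0.5, 3.5), c(3.5, 3.5), c(3.5, 0.5))
  reg <- generic_region("soma", sq, image_shape = c(8L, 8L))
  ch <- matrix(100L, 8, 8)
  ri <- region_intensity(reg, ch)
  expect_identical(ri$area_px, 9L)
  expect_equal(ri$integrated_intensity, 900)
  expect_equal(ri$average_intensity, 100)
  expect_equal(region_intensity(reg, matrix(0L, 8, 8))$integrated_intensity, 0)
  # checkerboard averages to half amplitude over an even region
  cb <- matrix(c(0L, 200L), 8, 8)
  sq2 <- rbind(c(0.5, 0.5), c(0.5, 4.5), c(4.5, 4.5), c(4.5, 0.5))
  reg2 <- generic_region("r2", sq2, image_shape = c(8L, 8L))
  expect_equal(region_intensity(reg2, cb)$average_intensity, 100)
  expect_error(region_intensity(reg, matrix(0L, 4, 4)), "shape")
})

test_that("exports round-trip exactly and keep the object hierarchy consistent", {
  out <- tempfile("export")
  d1 <- dendrite_stats(make_dendrite_with_puncta(3, 30, id = "a", group = "g1"),
                       image = "img1")
  d2 <- dendrite_stats(make_dendrite_with_puncta(5, 25, id = "b", group = "g1"),
                       image = "img1")
  d3 <- dendrite_stats(make_dendrite_with_puncta(4, 40, id = "c", group = "g2"),
                       image = "img2")
  dd <- rbind(d1, d2, d3)
  gg <- group_stats(dd)
  files <- export_results(gg, dd, data.frame(), data.frame(), out,
                          config = list(t_min = 70), timestamp = FALSE)
  dback <- read.delim(file.path(out, "dendrites.tsv"))
  expect_identical(nrow(dback), 3L)
  expect_identical(nrow(read.delim(file.path(out, "groups.tsv"))), 2L)
  # numeric columns re-parse to the exact in-memory values (integer-valued
  # doubles may come back as integers)
  for (cn in c("length_um", "puncta_density_per_um", "mean_avg_intensity",
               "total_puncta_intensity_per_um"))
    expect_identical(as.numeric(dback[[cn]]), dd[[cn]])
  # group means recompute from the dendrite table
  gback <- read.delim(file.path(out, "groups.tsv"))
  for (grp in c("g1", "g2")) {
    expect_equal(gback$mean_puncta_density_per_um[gback$group == grp],
                 mean(dback$puncta_density_per_um[dback$group == grp]))
  }
  meta <- jsonlite::read_json(file.path(out, "run_metadata.json"))
  expect_identical(meta$schema_version, "1.0")
  expect_identical(meta$config$t_min, 70L)
  expect_null(meta$timestamp)
})

test_that("an empty analysis exports header-only tables", {
  out <- tempfile("empty")
  files <- export_results(data.frame(group = character()),
                          punctanal:::dendrite_stats_schema(),
                          punctanal:::puncta_table_schema(),
                          punctanal:::spine_table_schema(), out,
                          timestamp = FALSE)
  dd <- read.delim(file.path(out, "dendrites.tsv"))
  expect_identical(nrow(dd), 0L)
  expect_true("puncta_density_per_um" %in% names(dd))
  expect_true(file.exists(file.path(out, "puncta.tsv")))
})
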