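test_that("open_slide synthesizes a pyramid for single-resolution files", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "slide.png")
  img <- withr::with_seed(1, array(runif(512 * 512 * 3), c(512, 512, 3)))
  png::writePNG(img, path)

  slide <- open_slide(path, pixel_size_um = 0.5)
  expect_identical(slide$downsamples, c(1L, 4L))
  expect_identical(dim(slide$levels[[2]]), c(128L, 128L, 3L))
  expect_equal(slide$width_px, 512)

  expect_error(open_slide(path), "pixel size")
  expect_error(open_slide(file.path(dir, "nope.png"), 0.5), "not found")

  bad <- file.path(dir, "corrupt.png")
  writeLines("not a png", bad)
  expect_error(open_slide(bad, pixel_size_um = 0.5), "failed to read")
})

test_that("multi-page pyramid TIFFs keep their stored downsamples", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pyramid.tiff")
  base <- withr::with_seed(2, array(runif(64 * 64 * 3), c(64, 64, 3)))
  tiff::writeTIFF(list(base, base[seq(1, 64, 2), seq(1, 64, 2), ],
                       base[seq(1, 64, 4), seq(1, 64, 4), ]),
                  path, bits.per.sample = 8L)
  slide <- open_slide(path, pixel_size_um = 0.5)
  expect_identical(slide$downsamples, c(1L, 2L, 4L))
  expect_identical(dim(slide$levels[[3]])[1:2], c(16L, 16L))
})

test_that("tile size scales to match the reference physical area", {
  expect_identical(tile_size_for_area(0.5, 600, 0.5), 600L)
  expect_identical(tile_size_for_area(0.25, 600, 0.5), 1200L)
  expect_identical(tile_size_for_area(1.0, 600, 0.5), 300L)
  expect_error(tile_size_for_area(-1, 600, 0.5), "positive")
})

test_that("tile grids are disjoint, in-bounds, and drop partial tiles", {
  slide <- flat_slide(1800, 1200)
  grid <- build_tile_grid(slide, 600)
  expect_equal(nrow(grid$tiles), 6)
  expect_setequal(unique(grid$tiles$x), c(0, 600, 1200))
  expect_setequal(unique(grid$tiles$y), c(0, 600))

  one <- build_tile_grid(flat_slide(600, 600), 600)
  expect_equal(nrow(one$tiles), 1)
  expect_equal(c(one$tiles$x, one$tiles$y), c(0, 0))

  expect_error(build_tile_grid(flat_slide(599, 600), 600), "exceeds")

  # area bookkeeping: disjoint cover never exceeds the slide area
  for (tile_px in c(7, 50, 128)) {
    s <- flat_slide(301, 260)
    g <- build_tile_grid(s, tile_px)
    keys <- paste(g$tiles$x, g$tiles$y)
    expect_false(anyDuplicated(keys) > 0)
    expect_lte(nrow(g$tiles) * tile_px^2, s$width_px * s$height_px)
    expect_true(all(g$tiles$x + tile_px <= s$width_px))
    expect_true(all(g$tiles$y + tile_px <= s$height_px))
  }
})

test_that("ImageScope XML parses, maps labels, and rejects unknown classes", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.xml")
  writeLines(c(
    "<Annotations><Annotation Id=\"1\"><Regions>",
    "<Region Id=\"1\" Text=\"solid\"><Vertices>",
    "<Vertex X=\"0\" Y=\"0\"/><Vertex X=\"30\" Y=\"0\"/>",
    "<Vertex X=\"0\" Y=\"30\"/>",
    "</Vertices></Region>",
    "<Region Id=\"2\" Text=\"non-tumor\"><Vertices>",
    "<Vertex X=\"40\" Y=\"40\"/><Vertex X=\"60\" Y=\"40\"/>",
    "<Vertex X=\"60\" Y=\"60\"/><Vertex X=\"40\" Y=\"60\"/>",
    "</Vertices></Region>",
    "</Regions></Annotation></Annotations>"), path)
  ann <- parse_imagescope_xml(path)
  expect_length(ann$regions, 2)
  expect_identical(vapply(ann$regions, `[[`, character(1), "label"),
                   c("SO", "NT"))
  expect_equal(ann$regions[[1]]$vertices[2, ], c(x = 30, y = 0))

  bad <- file.path(dir, "bad.xml")
  writeLines(gsub("solid", "lepidic", readLines(path)), bad)
  expect_error(parse_imagescope_xml(bad), "lepidic")
})

test_that("XML round-trip preserves labels and coordinates", {
  gen <- generate_slide(random_slide_layout(seed = 3, tile_px = 32,
                                            region_tiles = 2),
                        seed = 3, id = "rt")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rt.xml")
  write_imagescope_xml(gen$annotations, path)
  back <- parse_imagescope_xml(path)
  expect_length(back$regions, length(gen$annotations$regions))
  for (i in seq_along(back$regions)) {
    expect_identical(back$regions[[i]]$label,
                     gen$annotations$regions[[i]]$label)
    expect_equal(back$regions[[i]]$vertices,
                 gen$annotations$regions[[i]]$vertices,
                 ignore_attr = TRUE)
  }
  # second round trip is byte-stable on the parsed representation
  path2 <- file.path(dir, "rt2.xml")
  write_imagescope_xml(back, path2)
  expect_identical(parse_imagescope_xml(path2), back)
})

test_that("rasterization matches the per-pixel even-odd oracle", {
  slide <- flat_slide(20, 20)
  sq <- function(x0, y0, s, label) {
    list(vertices = cbind(x = x0 + c(0, s, s, 0), y = y0 + c(0, 0, s, s)),
         label = label)
  }
  ann <- structure(list(regions = list(sq(2, 3, 10, "AC"))),
                   class = "gp_annotations")
  gt <- rasterize_annotations(ann, slide, downsample = 1)
  expect_equal(sum(gt$raster == 1L), 100)
  expect_equal(gt$raster, oracle_rasterize(ann, 20, 20))

  ann2 <- structure(list(regions = list(sq(0, 0, 8, "AC"),
                                        sq(10, 10, 6, "NT"))),
                    class = "gp_annotations")
  gt2 <- rasterize_annotations(ann2, slide, downsample = 1)
  expect_equal(sum(gt2$raster == 1L), 64)
  expect_equal(sum(gt2$raster == 5L), 36)

  empty <- structure(list(regions = list()), class = "gp_annotations")
  expect_true(all(rasterize_annotations(empty, slide)$raster == 0L))

  # random triangles vs the brute-force oracle, including downsampling
  for (seed in 1:5) {
    verts <- withr::with_seed(seed, cbind(x = runif(3, 0, 40),
                                          y = runif(3, 0, 40)))
    annr <- structure(list(regions = list(list(vertices = verts,
                                               label = "MP"))),
                      class = "gp_annotations")
    s40 <- flat_slide(40, 40)
    for (d in c(1, 2)) {
      expect_equal(rasterize_annotations(annr, s40, downsample = d)$raster,
                   oracle_rasterize(annr, 40, 40, downsample = d),
                   info = sprintf("seed %d downsample %d", seed, d))
    }
  }
})

test_that("overlapping classes error by default but last-wins on request", {
  slide <- flat_slide(20, 20)
  sq <- function(x0, s, label) {
    list(vertices = cbind(x = x0 + c(0, s, s, 0), y = c(0, 0, s, s)),
         label = label)
  }
  ann <- structure(list(regions = list(sq(0, 10, "AC"), sq(5, 10, "SO"))),
                   class = "gp_annotations")
  expect_error(rasterize_annotations(ann, slide), "overlap")
  gt <- rasterize_annotations(ann, slide, overlap = "last-wins")
  expect_equal(gt$raster[3, 8], 3L)  # overlap zone takes the later label
  expect_equal(gt$raster[3, 3], 1L)
})
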