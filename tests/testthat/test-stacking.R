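layout10 <- stackLayout(c("bNa", "to", "pK", "bCa", "CaL"),
                        c("pCa", "K1", "Ks", "Na", "Kr"))

test_that("stack coordinates implement the nested mixed radix", {
  z <- setNames(rep(0L, 10), channelIds())
  co <- stackCoordinates(z, layout10)
  expect_equal(co$x, 0)
  expect_equal(co$y, 0)

  z[["bNa"]] <- 3L     # outermost x channel is the most significant digit
  co <- stackCoordinates(z, layout10)
  expect_equal(co$x, 3 * 4^4)
  expect_equal(co$y, 0)

  lay2 <- stackLayout("CaL", "Ks")
  grid <- as.matrix(expand.grid(CaL = 0:3, Ks = 0:3))
  co2 <- stackCoordinates(grid, lay2)
  expect_equal(nrow(unique(cbind(co2$x, co2$y))), 16L)
})

test_that("stack coordinates are bijective over random layouts", {
  set.seed(11)
  chans <- c("CaL", "Kr", "Ks", "K1")
  grid <- as.matrix(expand.grid(CaL = 0:3, Kr = 0:3, Ks = 0:3, K1 = 0:3))
  for (i in 1:20) {
    ord <- sample(chans)
    lay <- stackLayout(ord[1:2], ord[3:4])
    co <- stackCoordinates(grid, lay)
    key <- co$y * 16 + co$x
    expect_equal(sort(key), 0:255)
  }
})

test_that("maps place every case at its coordinates with sentinels for gaps", {
  tab <- surrogateTable4()
  lay <- stackLayout(c("CaL", "Kr"), c("Ks", "K1"))
  m <- buildMap(tab, "apd90_ms", lay, bcl = 600)
  expect_equal(dim(unclass(m)), c(16L, 16L))
  # definition unwinding: each cell equals the surrogate at its levels
  for (case in c(0, 37, 200, 255)) {
    lv <- decodeIndex(case, channels = attr(tab, "channels"))
    co <- stackCoordinates(lv, lay)
    expect_equal(m[co$y + 1, co$x + 1],
                 tab$apd90_ms[tab$case_id == case])
  }

  # constant table -> constant map
  tab2 <- tab; tab2$apd90_ms <- 5
  m2 <- buildMap(tab2, "apd90_ms", lay, bcl = 600)
  expect_true(all(m2 == 5))

  # a single missing biomarker -> exactly one sentinel cell, at its coords
  tab3 <- tab; tab3$apd90_ms[tab3$case_id == 37] <- NA
  m3 <- buildMap(tab3, "apd90_ms", lay, bcl = 600)
  expect_equal(sum(is.na(m3)), 1L)
  co <- stackCoordinates(decodeIndex(37, attr(tab, "channels")), lay)
  expect_true(is.na(m3[co$y + 1, co$x + 1]))

  # incomplete factorial is refused with the missing indices
  expect_error(buildMap(tab[tab$case_id != 3, ], "apd90_ms", lay, 600),
               "missing case indices 3")
})

test_that("roughness cost counts each adjacent pair once and skips sentinels", {
  m <- matrix(c(0, 2, 1, 3), nrow = 2)   # [[0,1],[2,3]] row-wise
  expect_equal(roughnessCost(m), 6)
  expect_equal(roughnessCost(matrix(7, 5, 5)), 0)

  mna <- matrix(c(0, NA, 1, 3), nrow = 2) # [[0,1],[NA,3]]
  expect_equal(roughnessCost(mna), abs(0 - 1) + abs(1 - 3))

  set.seed(3)
  for (i in 1:10) {
    r <- matrix(runif(64), 8, 8)
    r[sample(64, 5)] <- NA
    expect_equal(roughnessCost(t(r)), roughnessCost(r))
  }
})

test_that("exhaustive layout search is globally optimal and the heuristic matches it", {
  tab <- surrogateTable4(noise = 0.5, seed = 5)
  ex <- optimizeLayout(tab, "apd90_ms", bcl = 600, mode = "exhaustive")
  expect_equal(ex$n_evaluated, 12L)   # 4!/2 layout classes

  for (seed in 1:20) {
    h <- optimizeLayout(tab, "apd90_ms", bcl = 600, mode = "heuristic",
                        seed = seed, restarts = 4)
    expect_equal(h$cost, ex$cost, tolerance = 1e-12)
  }
})

test_that("a two-channel problem has a single layout class", {
  tab <- generateSurrogateSweep(c("CaL", "Ks"), bcls = 600)
  ex <- optimizeLayout(tab, "max_cai_mM", bcl = 600, mode = "exhaustive")
  expect_equal(ex$n_evaluated, 1L)
  m <- buildMap(tab, "max_cai_mM", ex$layout, 600)
  expect_equal(roughnessCost(m), ex$cost)
})

test_that("equal-cost layouts resolve to the lexicographic tie-break", {
  tab <- surrogateTable4()
  tab$apd90_ms <- 1  # constant: every layout costs 0
  ex <- optimizeLayout(tab, "apd90_ms", bcl = 600, mode = "exhaustive")
  expect_equal(ex$cost, 0)
  chans <- attr(tab, "channels")
  keys <- character(0)
  for (xs in combn(chans, 2, simplify = FALSE)) {
    ys <- setdiff(chans, xs)
    for (px in cardioEMD:::permutations(xs))
      for (py in cardioEMD:::permutations(ys))
        keys <- c(keys, cardioEMD:::layoutKey(px, py))
  }
  expect_equal(cardioEMD:::layoutKey(ex$layout$x_order, ex$layout$y_order),
               min(keys))
})

test_that("the exhaustive search refuses oversized problems", {
  tab <- surrogateTable4()
  expect_error(optimizeLayout(tab, "apd90_ms", bcl = 600,
                              mode = "exhaustive", cap = 5),
               "refused")
})

test_that("optimized layouts dominate random ones", {
  tab <- surrogateTable4(noise = 0.3, seed = 9)
  opt <- optimizeLayout(tab, "emd_ms", bcl = 600, mode = "heuristic",
                        seed = 1)
  chans <- attr(tab, "channels")
  lev <- t(vapply(tab$case_id[tab$bcl_ms == 600], decodeIndex,
                  integer(4), channels = chans))
  colnames(lev) <- chans
  vals <- tab$emd_ms[tab$bcl_ms == 600]
  set.seed(99)
  for (i in 1:100) {
    ord <- sample(chans)
    rc <- cardioEMD:::layoutCost(vals, lev, ord[1:2], ord[3:4])
    expect_lte(opt$cost, rc + 1e-12)
  }
})

test_that("the dominant channel earns an outermost axis slot", {
  # surrogate EMD response is dominated by CaL (bump over its levels)
  tab <- surrogateTable4()
  ex <- optimizeLayout(tab, "emd_ms", bcl = 600, mode = "exhaustive")
  expect_true(ex$layout$x_order[1] == "CaL" || ex$layout$y_order[1] == "CaL")
})

test_that("rendering writes the grid and a pixel-exact raster", {
  tab <- surrogateTable4()
  lay <- stackLayout(c("CaL", "Kr"), c("Ks", "K1"))
  m <- buildMap(tab, "emd_ms", lay, bcl = 600)
  gf <- tempfile(fileext = ".tsv")
  rf <- tempfile(fileext = ".png")
  pf <- tempfile(fileext = ".png")
  renderMap(m, file_grid = gf, file_image = pf, file_raster = rf)
  grid <- as.matrix(read.delim(gf, header = FALSE))
  expect_equal(dim(grid), c(16L, 16L))
  expect_equal(sum(is.na(grid)), sum(is.na(m)))

  skip_if_not_installed("png")
  img <- png::readPNG(rf)
  sent <- grDevices::col2rgb("#00008B") / 255
  hits <- abs(img[, , 1] - sent[1]) < 1e-3 &
    abs(img[, , 2] - sent[2]) < 1e-3 &
    abs(img[, , 3] - sent[3]) < 1e-3
  expect_equal(sum(hits), sum(is.na(m)))

  # constant map -> single-color raster
  mc <- m; mc[] <- 1
  renderMap(mc, file_grid = gf, file_raster = rf)
  img2 <- png::readPNG(rf)
  expect_equal(length(unique(round(as.numeric(img2), 6))), 3L)
  unlink(c(gf, rf, pf))
})
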