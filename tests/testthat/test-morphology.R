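test_that("SWC parsing collapses soma and sums Euclidean path lengths", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 1 -1", "2 3 3 0 0 0.2 1",
               "3 3 3 4 0 0.2 2"), f)
  m <- parse_swc(f)
  expect_length(m$neurites, 1L)
  expect_equal(total_neurite_length(m), 7)

  # orphan parent
  writeLines(c("1 1 0 0 0 1 -1", "2 3 1 0 0 0.2 9"), f)
  expect_error(parse_swc(f), "parent id 9 is undefined")
  # malformed column count, with line number
  writeLines(c("1 1 0 0 0 1 -1", "2 3 1 0 0 0.2"), f)
  expect_error(parse_swc(f), "line 2")
  # cyclic parent chain among non-soma nodes
  writeLines(c("1 1 0 0 0 1 -1", "2 3 1 0 0 0.2 3", "3 3 2 0 0 0.2 2"), f)
  expect_error(parse_swc(f), "cyclic")
})

test_that("generator truth matches reparsed reconstructions", {
  for (s in 1:10) {
    g <- generate_morphology(morph_gen_params(branch_prob = 0.5), day = 14,
                             seed = s)
    f <- withr::local_tempfile(fileext = ".swc")
    write_swc(g$morphology, f)
    m <- parse_swc(f)
    expect_length(m$neurites, g$truth$n_neurites)
    expect_equal(sum(vapply(m$neurites, nrow, 0L)), g$truth$n_nodes)
    expect_equal(total_neurite_length(m), g$truth$total_length,
                 tolerance = 1e-5)  # 6-decimal serialization
    expect_equal(total_neurite_length(g$morphology), g$truth$total_length,
                 tolerance = 1e-9)
  }
})

test_that("total neurite length: 3-4-5 segment and rigid-transform invariance", {
  m <- line_morphology(matrix(c(3, 4, 0), 1))
  expect_equal(total_neurite_length(m), 5)
  for (s in 1:10) {
    g <- generate_morphology(morph_gen_params(), day = 21, seed = 100 + s)
    m0 <- g$morphology
    m1 <- rigid_transform_morphology(m0, angles = stats::runif(2, -pi, pi),
                                     shift = stats::rnorm(3, 0, 20))
    expect_equal(total_neurite_length(m1), total_neurite_length(m0),
                 tolerance = 1e-9)
    expect_equal(identify_axon(m1)$length, identify_axon(m0)$length,
                 tolerance = 1e-9)
    expect_identical(sholl_profile(m1)$counts, sholl_profile(m0)$counts)
  }
  expect_error(total_neurite_length(neuron_morphology("x", c(0, 0, 0))),
               "zero neurites")
})

test_that("axon is the longest neurite, ties to the lowest index", {
  two <- neuron_morphology("t", c(0, 0, 0), list(
    data.frame(x = 5, y = 0, z = 0, radius = 0.2, parent = 0L),
    data.frame(x = 0, y = 10, z = 0, radius = 0.2, parent = 0L)))
  ax <- identify_axon(two)
  expect_equal(ax$index, 2L)
  expect_equal(ax$length, 10)

  tie <- neuron_morphology("tie", c(0, 0, 0), list(
    data.frame(x = 10, y = 0, z = 0, radius = 0.2, parent = 0L),
    data.frame(x = 0, y = 10, z = 0, radius = 0.2, parent = 0L)))
  expect_equal(identify_axon(tie)$index, 1L)

  # argmax agrees with an exhaustive per-neurite scan on random trees
  for (s in 1:10) {
    g <- generate_morphology(morph_gen_params(n_primary = 4), seed = 200 + s)
    m <- g$morphology
    lens <- vapply(seq_along(m$neurites), function(i)
      total_neurite_length(neuron_morphology("one", m$soma, m$neurites[i])), 0)
    expect_equal(identify_axon(m)$index, which.max(lens))
  }
})

test_that("polarity classes count primary neurites above the length floor", {
  mk <- function(lens) neuron_morphology("p", c(0, 0, 0), lapply(lens, function(L)
    data.frame(x = L, y = 0, z = 0, radius = 0.2, parent = 0L)))
  expect_equal(classify_polarity(mk(20)), "unipolar")
  expect_equal(classify_polarity(mk(c(30, 30, 30, 30))), "multipolar")
  expect_equal(classify_polarity(mk(c(30, 30, 2))), "bipolar")
  expect_warning(cl <- classify_polarity(mk(c(1, 2)), min_primary_length = 5),
                 "unclassifiable")
  expect_true(is.na(cl))
})

test_that("Sholl counts cross concentric spheres per segment crossing", {
  straight <- line_morphology(cbind(seq(5, 25, by = 5), 0, 0))
  sp <- sholl_profile(straight, step = 10)
  expect_equal(sp$radii, c(10, 20))
  expect_equal(sp$counts, c(1L, 1L))
  expect_equal(sp$total_intersections, 2L)

  # Y-tree: 15 um trunk, two 15 um daughters laid out radially
  y <- neuron_morphology("y", c(0, 0, 0), list(data.frame(
    x = c(7.5, 15, 22.5, 30, 22.5, 30),
    y = 0, z = 0, radius = 0.2,
    parent = c(0L, 1L, 2L, 3L, 2L, 5L))))
  sy <- sholl_profile(y, step = 10)
  expect_equal(sy$counts, c(1L, 2L, 2L))

  expect_error(sholl_profile(straight, step = 0), "positive")
})

test_that("Sholl profile agrees exactly with the dense-resampling oracle", {
  for (s in 1:15) {
    g <- generate_morphology(morph_gen_params(branch_prob = 0.5), day = 14,
                             seed = 300 + s)
    a <- sholl_profile(g$morphology, step = 10)
    b <- sholl_profile_dense(g$morphology, step = 10)
    expect_identical(as.integer(a$counts), as.integer(b$counts))
    expect_identical(a$total_intersections, as.integer(b$total_intersections))
  }
})

test_that("morphometry record is internally consistent", {
  g <- generate_morphology(morph_gen_params(n_primary = 3), seed = 11)
  rec <- morphometry(g$morphology)
  expect_equal(rec$total_neurite_length,
               rec$axon_length + rec$dendrite_length, tolerance = 1e-9)
  expect_equal(rec$sholl$total_intersections, sum(rec$sholl$counts))
  expect_gte(rec$dendrite_length, 0)
  tab <- morphometry_table(list(rec))
  expect_equal(nrow(tab$cells), 1L)
  expect_equal(tab$cells$sholl_total, rec$sholl$total_intersections)
})

test_that("batch normalization divides by the per-batch reference mean", {
  df <- data.frame(group = c("ape", "ape", "human"),
                   batch = "b1", value = c(2, 4, 6))
  out <- batch_normalize(df)
  expect_equal(out$normalized, c(2 / 3, 4 / 3, 2))
  expect_equal(mean(out$normalized[out$group == "ape"]), 1, tolerance = 1e-12)

  one <- batch_normalize(data.frame(group = "ape", batch = "b", value = 7))
  expect_equal(one$normalized, 1)

  # two batches normalize independently; pooled reference mean is 1
  df2 <- data.frame(group = rep(c("ape", "human"), each = 4),
                    batch = rep(c("b1", "b2"), 4),
                    value = c(2, 4, 4, 8, 3, 9, 1, 5))
  out2 <- batch_normalize(df2)
  ape1 <- df2$value[df2$group == "ape" & df2$batch == "b1"]
  expect_equal(out2$normalized[1], df2$value[1] / mean(ape1))
  expect_equal(mean(out2$normalized[out2$group == "ape"]), 1,
               tolerance = 1e-12)
  for (b in c("b1", "b2"))
    expect_equal(mean(out2$normalized[out2$group == "ape" & out2$batch == b]),
                 1, tolerance = 1e-12)

  expect_error(batch_normalize(data.frame(group = "human", batch = "bX",
                                          value = 1)),
               "batch 'bX' has no ape values")
})

test_that("hand-written HOC geometry parses with additive lengths", {
  f <- withr::local_tempfile(fileext = ".hoc")
  writeLines(c("create soma",
               "soma { pt3dclear() pt3dadd(0, 0, 0, 2) }",
               "create trunk",
               "connect trunk(0), soma(1)",
               "trunk {",
               "  pt3dadd(0, 0, 0, 0.4)",
               "  pt3dadd(5, 0, 0, 0.4)",
               "  pt3dadd(10, 0, 0, 0.4)",
               "}",
               "create tip",
               "connect tip(0), trunk(1)",
               "tip { pt3dadd(10, 0, 0, 0.4) pt3dadd(15, 0, 0, 0.4) }"), f)
  m <- parse_hoc(f)
  expect_length(m$neurites, 1L)
  expect_equal(total_neurite_length(m), 15)

  writeLines(c("create soma", "soma { pt3dadd(0,0,0,2) }",
               "connect ghost(0), soma(1)"), f)
  expect_error(parse_hoc(f), "undeclared section 'ghost'")

  writeLines(c("create soma", "soma { pt3dadd(0,0,0,2) }",
               "create empty", "connect empty(0), soma(1)"), f)
  expect_error(parse_hoc(f), "no 3-D points")

  writeLines(c("create soma", "soma { pt3dadd(0,0,0,2) }",
               "access soma"), f)
  expect_warning(parse_hoc(f), "ignored")
})

test_that("SWC and HOC serializations yield identical morphometry records", {
  for (s in 1:10) {
    g <- generate_morphology(morph_gen_params(branch_prob = 0.5), day = 21,
                             seed = 400 + s)
    f1 <- withr::local_tempfile(fileext = ".swc")
    f2 <- withr::local_tempfile(fileext = ".hoc")
    write_swc(g$morphology, f1)
    write_hoc(g$morphology, f2)
    r1 <- morphometry(parse_swc(f1))
    r2 <- morphometry(parse_hoc(f2))
    expect_equal(r1$total_neurite_length, r2$total_neurite_length,
                 tolerance = 1e-6)
    expect_equal(r1$axon_length, r2$axon_length, tolerance = 1e-6)
    expect_equal(r1$dendrite_length, r2$dendrite_length, tolerance = 1e-6)
    expect_identical(r1$polarity_class, r2$polarity_class)
    expect_identical(r1$sholl$counts, r2$sholl$counts)
    expect_identical(r1$n_neurites, r2$n_neurites)
  }
})
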