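# rise/twist geometry, stack construction, screw-symmetry estimation,
# contacts

test_that("pitch and cross-over follow from rise and twist", {
  g <- pitch_and_crossover(helical_symmetry(4.8, -0.58))
  expect_equal(g$pitch, 4.8 * 360 / 0.58, tolerance = 1e-12)
  expect_equal(g$crossover, g$pitch / 2)
  expect_equal(g$handedness, "left")
  # pitch * |twist| / 360 = rise exactly
  expect_equal(g$pitch * 0.58 / 360, 4.8, tolerance = 1e-12)
  expect_equal(pitch_and_crossover(helical_symmetry(4.8, 360))$pitch, 4.8)
  expect_equal(pitch_and_crossover(helical_symmetry(4.8, -1))$pitch, 1728)
  expect_equal(pitch_and_crossover(helical_symmetry(4.8, 1))$handedness,
               "right")
  expect_error(helical_symmetry(0, 1), "rise")
  expect_error(helical_symmetry(4.8, 0), "twist")
})

test_that("build_stack applies a rigid screw operation", {
  lay <- generate_beta_arch_layer(24)
  sym <- helical_symmetry(4.8, -0.58)
  stk <- build_stack(lay, sym, 5)
  expect_equal(length(unique(stk$chain)), 5)
  expect_equal(sort(unique(stk$layer)), 0:4)
  # intra-layer pairwise distances preserved to tight relative tolerance
  d0 <- dist(as.matrix(stk[stk$layer == 0, c("x", "y", "z")]))
  d4 <- dist(as.matrix(stk[stk$layer == 4, c("x", "y", "z")]))
  expect_lt(max(abs(d4 - d0) / pmax(d0, 1e-9)), 1e-9)
  # layer k+1 is layer k's image under the screw operation
  l1 <- as.matrix(stk[stk$layer == 1, c("x", "y", "z")])
  th <- -0.58 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  l0img <- as.matrix(stk[stk$layer == 0, c("x", "y", "z")]) %*% t(R)
  l0img[, 3] <- l0img[, 3] + 4.8
  expect_lt(sqrt(mean((l1 - l0img)^2)), 1e-9)
  # a full-turn twist degenerates to pure translation
  stk2 <- build_stack(lay, helical_symmetry(4.8, 360), 3)
  expect_equal(stk2$x[stk2$layer == 2], stk2$x[stk2$layer == 0],
               tolerance = 1e-9)
  expect_error(build_stack(lay, sym, 0), "n_layers")
})

test_that("estimate_symmetry inverts build_stack across a parameter grid", {
  lay <- generate_beta_arch_layer(20)
  for (rise in c(2, 4.8, 10)) {
    for (twist in c(-5, -0.58, -0.3, 0.3, 0.58, 5)) {
      stk <- build_stack(lay, helical_symmetry(rise, twist), 4)
      est <- estimate_symmetry(stk)
      expect_equal(est$rise, rise, tolerance = 1e-6)
      expect_equal(est$twist, twist, tolerance = 1e-6)
      expect_lt(est$rmsd, 1e-6)
    }
  }
})

test_that("estimate_symmetry rejects degenerate input", {
  lay <- generate_beta_arch_layer(10)
  expect_error(estimate_symmetry(lay), ">= 2 chains")
  stk <- build_stack(lay, helical_symmetry(4.8, -0.58), 2)
  stk_bad <- stk[!(stk$layer == 1 & stk$resno > 5), ]
  class(stk_bad) <- c("atomic_model", "data.frame")
  expect_error(estimate_symmetry(stk_bad), "unmatched")
})

test_that("axial height span measures CA extent along the axis", {
  lay <- generate_beta_arch_layer(10)
  expect_equal(axial_height_span(lay, "A"), 0)
  tilted <- lay
  ca <- tilted$elety == "CA"
  tilted$z[ca] <- seq(-2.5, 2.5, length.out = sum(ca))
  expect_equal(axial_height_span(tilted, "A"), 5.0)
  expect_error(axial_height_span(lay, "Z"), "no CA")
})

test_that("width is the cross-sectional extent, optionally with vdW", {
  ang <- seq(0, 2 * pi, length.out = 37)[-37]
  ring <- atomic_model(data.frame(
    elety = "CA", resid = "GLY", resno = seq_along(ang), chain = "A",
    x = 50 * cos(ang), y = 50 * sin(ang), z = runif(length(ang), 0, 100)))
  expect_equal(measure_width(ring), 100, tolerance = 1e-9)
  expect_equal(measure_width(ring, mode = "surface"), 100 + 2 * 1.70,
               tolerance = 1e-9)
  single <- atomic_model(data.frame(elety = "CA", resid = "GLY", resno = 1,
                                    chain = "A", x = 1, y = 2, z = 3))
  expect_equal(measure_width(single), 0)
})

test_that("interlayer contacts are found at the right offsets", {
  lay <- generate_beta_arch_layer(8)
  stk <- build_stack(lay, helical_symmetry(4.8, 360), 3)
  cm5 <- interlayer_contacts(stk, cutoff = 5)
  off1 <- cm5[cm5$offset == 1, ]
  # vertically aligned layers 4.8 A apart: every residue contacts its own
  # image in the next layer
  expect_true(all(1:8 %in% off1$resno_a[off1$resno_a == off1$resno_b]))
  expect_true(all(off1$min_dist <= 5))
  cm3 <- interlayer_contacts(stk, cutoff = 3)
  expect_equal(nrow(cm3[cm3$offset >= 1, ]), 0)
  expect_error(interlayer_contacts(lay, 4.5), ">= 2 layers")
})

test_that("opposed charges across layers are flagged as salt bridges", {
  base <- data.frame(
    elety = c("CA", "NH1", "CA", "OE1"),
    resid = c("ARG", "ARG", "GLU", "GLU"),
    resno = c(25, 25, 84, 84),
    chain = "A",
    x = c(0, 0, 10, 10), y = c(0, 0, 0, 0), z = c(0, 1, 0, 1),
    stringsAsFactors = FALSE)
  upper <- base
  upper$chain <- "B"
  upper$z <- upper$z + 4.8
  # bring Arg25 (layer 0) side chain near Glu84 (layer 1)
  upper$x[upper$resno == 84] <- 0
  upper$z[upper$elety == "OE1"] <- 1 + 3.0
  mdl <- atomic_model(rbind(base, upper))
  cm <- interlayer_contacts(mdl, cutoff = 4.5)
  sb <- cm[cm$offset == 1 & cm$salt_bridge, ]
  expect_true(any(sb$resno_a == 25 & sb$resno_b == 84 |
                  sb$resno_a == 84 & sb$resno_b == 25))
})
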