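# generators: worm-like-chain traces, protomer layers, cavity phantoms,
# sequence pairs

test_that("wlc_params enforces its invariants", {
  expect_error(wlc_params(-1, 0.02, 5), "persistence_length")
  expect_error(wlc_params(6.7, 0, 5), "step")
  expect_error(wlc_params(6.7, 6, 5), "step")
  expect_error(wlc_params(1, 0.03, 5), "discretization")
})

test_that("wlc trace has exact segment geometry and is seed-deterministic", {
  p <- wlc_params(6.7, 0.02, 3.0, seed = 11)
  tr <- generate_wlc_trace(p)
  m <- measure_trace(tr)
  n_seg <- round(3.0 / 0.02)
  expect_equal(nrow(tr), n_seg + 1)
  # contour length equals n_segments * step exactly (in nm)
  expect_equal(unname(m["L_nm"]), n_seg * 0.02 * 1000, tolerance = 1e-12)
  seg <- sqrt(diff(tr$x_nm)^2 + diff(tr$y_nm)^2)
  expect_true(all(abs(seg - 20) < 1e-9))
  tr2 <- generate_wlc_trace(p)
  expect_identical(tr$x_nm, tr2$x_nm)
  expect_identical(tr$y_nm, tr2$y_nm)
  tr3 <- generate_wlc_trace(wlc_params(6.7, 0.02, 3.0, seed = 12))
  expect_false(isTRUE(all.equal(tr$x_nm, tr3$x_nm)))
})

test_that("stiff-limit trace is essentially straight", {
  # huge P: tangent variance ~ 0, end-to-end ~ contour length
  tr <- generate_wlc_trace(wlc_params(1e9, 0.02, 2, seed = 3))
  m <- measure_trace(tr)
  expect_equal(unname(m["D_nm"]), unname(m["L_nm"]), tolerance = 1e-6)
})

test_that("ensemble mean squared end-to-end follows the WLC relation", {
  # L/P in {0.1, 1, 5} at P = 1 um; sample mean within 3 standard errors.
  # Fine discretization (step = P/200): a polyline of straight segments
  # slightly overestimates the continuum D^2 (no intra-segment bending),
  # an O(step/P) effect that must stay below the Monte-Carlo resolution.
  for (L in c(0.1, 1, 5)) {
    traces <- generate_trace_ensemble(1, 10000, c(L, L), step = 0.005,
                                      seed = 1000 + L * 10)
    d2 <- measure_traces(traces)$D_um^2
    expected <- wlc_expected_sq_end_to_end(L, 1)
    se <- sd(d2) / sqrt(length(d2))
    expect_lt(abs(mean(d2) - expected), 3 * se)
  }
})

test_that("trace ensembles honor n, length range and seeding", {
  expect_error(generate_trace_ensemble(6.7, 1), "n must be >= 2")
  expect_error(generate_trace_ensemble(6.7, 10, c(3, 1)), "ordered")
  ens <- generate_trace_ensemble(6.7, 124, c(1, 8), 0.02, seed = 42)
  expect_length(ens, 124)
  ls <- measure_traces(ens)$L_um
  expect_true(all(ls >= 1 - 0.011 & ls <= 8 + 0.011))
  # degenerate range
  ens2 <- generate_trace_ensemble(6.7, 2, c(2, 2), 0.02, seed = 1)
  expect_equal(measure_traces(ens2)$L_um, c(2, 2), tolerance = 1e-12)
  # seeding
  a <- generate_trace_ensemble(6.7, 5, c(1, 2), 0.02, seed = 7)
  b <- generate_trace_ensemble(6.7, 5, c(1, 2), 0.02, seed = 7)
  c <- generate_trace_ensemble(6.7, 5, c(1, 2), 0.02, seed = 8)
  expect_identical(measure_traces(a), measure_traces(b))
  expect_false(isTRUE(all.equal(measure_traces(a)$D_um,
                                measure_traces(c)$D_um)))
})

test_that("beta-arch layer is flat with near-uniform CA spacing", {
  lay <- generate_beta_arch_layer(91, spacing = 3.8)
  expect_equal(sum(lay$elety == "CA"), 91)
  expect_equal(max(lay$z) - min(lay$z), 0)
  ca <- lay[lay$elety == "CA", ]
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2)
  expect_true(all(d > 0.9 * 3.8 & d < 1.1 * 3.8))
  expect_error(generate_beta_arch_layer(3), "n_residues")
})

test_that("cavity phantom encloses a sealed void of the designed size", {
  ph <- generate_cavity_phantom(phantom_spec(3))
  cavs <- find_cavities(ph, spacing = 0.5)
  expect_length(cavs, 1)
  expect_lt(abs(cavs[[1]]$volume - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.15)
  # solid ball: no interior void
  solid <- generate_cavity_phantom(phantom_spec(0, shell_thickness = 5))
  expect_length(find_cavities(solid, spacing = 0.5), 0)
  # bored channel: void connected to the exterior, no sealed cavity.
  # The bore must clear the occupancy radius (vdW 1.7 + probe 1.4) so a
  # free path to the outside actually exists.
  open <- generate_cavity_phantom(phantom_spec(3), channel_radius = 5)
  expect_length(find_cavities(open, spacing = 0.5), 0)
})

test_that("phantom spec rejects unsealable constructions", {
  expect_error(phantom_spec(3, atom_spacing = 2), "seal")
  expect_error(phantom_spec(3, shell_thickness = 1), "shell_thickness")
  expect_error(phantom_spec(-1), "void_radius")
})

test_that("mutations apply with a numbering guard and invert cleanly", {
  g <- germline_template()
  expect_identical(apply_mutations(g, data.frame(from = character(),
                                                 pos = integer(),
                                                 to = character())), g)
  p <- apply_mutations(g, patient_mutations())
  diffs <- which(strsplit(p, "")[[1]] != strsplit(g, "")[[1]])
  expect_length(diffs, 10)
  # self-substitution is a no-op
  expect_identical(apply_mutations(g, data.frame(from = "G", pos = 15,
                                                 to = "G")), g)
  # wrong `from` residue trips the consistency guard
  expect_error(apply_mutations(g, data.frame(from = "W", pos = 15, to = "A")),
               "mismatch")
  # invertible by the reversed substitutions
  m <- patient_mutations()
  back <- data.frame(from = m$to, pos = m$pos, to = m$from)
  expect_identical(apply_mutations(p, back), g)
})

test_that("mutation shorthand parses three- and one-letter forms", {
  m <- parse_mutations(c("Ser25Arg", "D94A"))
  expect_equal(m$from, c("S", "D"))
  expect_equal(m$pos, c(25L, 94L))
  expect_equal(m$to, c("R", "A"))
  expect_error(parse_mutations("notamutation"), "unparseable")
})
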