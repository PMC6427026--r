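# hydropathy, predictor ingestion, consensus scoring, mutation records

test_that("hydropathy profile follows the Kyte-Doolittle scale", {
  expect_equal(hydropathy_profile("III", window = 1), c(4.5, 4.5, 4.5))
  expect_equal(hydropathy_profile("R", window = 1), -4.5)
  # windowing smooths but preserves the overall range and, for a
  # homopolymer, the exact per-residue value at every window size
  expect_equal(hydropathy_profile(strrep("L", 9), 5), rep(3.8, 9))
  s <- patient_sequence()
  p1 <- hydropathy_profile(s, 1)
  p9 <- hydropathy_profile(s, 9)
  expect_true(all(p9 >= min(p1) & p9 <= max(p1)))
  expect_lt(sd(p9), sd(p1))
  expect_error(hydropathy_profile("AXA"), "unknown residue")
  expect_error(hydropathy_profile("AAAA", window = 2), "odd")
})

test_that("scale_scan enforces run length and thresholds", {
  # per-position values: 4 consecutive above threshold, min_run 5 -> none
  v <- c(0, 30, 30, 30, 30, 0, 0, 0, 0, 0)
  s <- strrep("A", 10)
  expect_length(scale_scan(s, v, 21.4, min_run = 5)$positions, 0)
  v5 <- c(0, 30, 30, 30, 30, 30, 0, 0, 0, 0)
  expect_equal(scale_scan(s, v5, 21.4, min_run = 5)$positions, 2:6)
  expect_length(scale_scan(s, rep(-1, 10), 0)$positions, 0)
  # named-scale route with mode below
  expect_equal(scale_scan("IRI", kyte_doolittle(), 0, mode = "below")$positions,
               2L)
  # degenerate thresholds mark all / none
  expect_equal(scale_scan(s, v, -Inf, min_run = 1)$positions, 1:10)
  expect_length(scale_scan(s, v, Inf, min_run = 1)$positions, 0)
})

test_that("predictor files are parsed with the published hit rules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tvalue", "1\t-0.1", "2\t0.0", "3\t0.2"), f)
  hits <- parse_predictor_output(f, "WALTZ", seq_length = 5)
  expect_equal(hits$positions, 3L)  # strictly above 0.00
  # FoldAmyloid needs runs of five above 21.4
  writeLines(c(paste(1:4, 25, sep = "\t"), paste(5:10, 10, sep = "\t")), f)
  expect_length(parse_predictor_output(f, "FoldAmyloid", 10)$positions, 0)
  writeLines(paste(1:5, 25, sep = "\t"), f)
  expect_equal(parse_predictor_output(f, "FoldAmyloid", 10)$positions, 1:5)
  # Aggrescan hot spots are values above -0.02
  writeLines(c("1\t-0.05", "2\t-0.01", "3\t1.2"), f)
  expect_equal(parse_predictor_output(f, "Aggrescan", 3)$positions, 2:3)
  # AmylPred rows carry a 0/1 consensus flag
  writeLines(c("1\t0", "2\t1", "3\t1"), f)
  expect_equal(parse_predictor_output(f, "AmylPred", 3)$positions, 2:3)
  # empty file -> no hits
  writeLines(character(0), f)
  expect_length(parse_predictor_output(f, "TANGO", 5)$positions, 0)
  # positions beyond the sequence and malformed rows are rejected
  writeLines("9\t1.0", f)
  expect_error(parse_predictor_output(f, "WALTZ", 5), "beyond")
  writeLines(c("1\t0.5", "oops"), f)
  expect_error(parse_predictor_output(f, "WALTZ", 5), "line 2")
  expect_error(parse_predictor_output(f, "NotAPredictor", 5), "unknown")
})

test_that("consensus score counts predictor indicators per residue", {
  s <- strrep("A", 6)
  hs <- list(
    predictor_hits("WALTZ", c(1, 2, 3), 6),
    predictor_hits("TANGO", c(1, 2), 6),
    predictor_hits("FoldAmyloid", c(1, 2, 3), 6),
    predictor_hits("Aggrescan", c(1, 4), 6),
    predictor_hits("AmylPred", 1, 6))
  prof <- consensus_amyloid_score(hs, s)
  expect_equal(prof$score, c(5, 3, 2, 1, 0, 0))
  expect_equal(prof$predictors[1],
               "Aggrescan,AmylPred,FoldAmyloid,TANGO,WALTZ")
  # exactly the five named predictors, once each
  expect_error(consensus_amyloid_score(hs[1:4], s), "five predictors")
  expect_error(consensus_amyloid_score(c(hs[1:4], hs[1]), s),
               "five predictors")
})

test_that("consensus equals the indicator sum on random hit sets", {
  n <- 40
  for (rep in 1:25) {
    hs <- random_hit_sets(n, seed = rep)
    prof <- consensus_amyloid_score(hs, strrep("G", n))
    manual <- integer(n)
    for (h in hs) manual[h$positions] <- manual[h$positions] + 1L
    expect_identical(prof$score, manual)
  }
})

test_that("mutation listing recovers the designed substitutions", {
  g <- germline_template()
  expect_equal(nrow(list_mutations(g, g)), 0)
  muts <- list_mutations(patient_sequence(), g)
  expect_equal(muts$pos, c(25, 31, 33, 35, 40, 53, 76, 94, 95, 98))
  expect_equal(muts$germline[muts$pos == 25], "S")
  expect_equal(muts$patient[muts$pos == 25], "R")
  one <- list_mutations(apply_mutations(g, "Gly15Ala"), g)
  expect_equal(nrow(one), 1)
  expect_equal(one$germline, "G")
  expect_equal(one$patient, "A")
  expect_error(list_mutations("AAA", "AAAA"), "equal length")
})

test_that("mutation count is stable under non-overlapping mutation sets", {
  g <- germline_template()
  set.seed(4)
  for (k in c(1, 5, 12)) {
    pos <- sample(nchar(g), k)
    chars <- strsplit(g, "")[[1]]
    to <- ifelse(chars[pos] == "W", "A", "W")
    mutated <- apply_mutations(g, data.frame(from = chars[pos], pos = pos,
                                             to = to))
    expect_equal(nrow(list_mutations(mutated, g)), k)
  }
})

test_that("the ordered core spans 91 residues from Gly15 to Thr105", {
  core <- ordered_core(germline_template())
  expect_equal(core$length, 91L)
  expect_equal(substr(core$sequence, 1, 1), "G")
  expect_equal(substr(core$sequence, core$length, core$length), "T")
  expect_error(ordered_core("SHORT"), "outside")
})

test_that("mutation classification annotates charge, burial, CDR, cavity", {
  muts <- list_mutations(patient_sequence(), germline_template())
  n53d <- classify_mutation(muts[muts$pos == 53, ])
  expect_equal(n53d$charge_change, -1)  # charge added (0 -> -1)
  d94a <- classify_mutation(muts[muts$pos == 94, ])
  expect_equal(d94a$charge_germline, -1)
  expect_equal(d94a$charge_patient, 0)  # buried charge removed
  s25r <- classify_mutation(muts[muts$pos == 25, ],
                            cdr_ranges = list(c(24, 34)),
                            cavity_linings = list(B = c(25, 84, 86)))
  expect_true(s25r$cdr)
  expect_equal(s25r$cavities, "B")
  # a lone exposed residue has few neighbours -> surface
  lone <- atomic_model(data.frame(
    elety = c("N", "CA", "CB", "C"), resid = "ALA", resno = 7, chain = "A",
    x = c(0, 1.4, 2, 2.4), y = c(0, 0, 1, -1), z = 0))
  a7v <- classify_mutation(data.frame(pos = 7, germline = "A",
                                      patient = "V"), structure = lone)
  expect_equal(a7v$charge_change, 0)
  expect_false(a7v$buried)
  # a residue at the centre of a dense cluster is buried
  cloud <- expand.grid(x = seq(-6, 6, 3), y = seq(-6, 6, 3),
                       z = seq(-6, 6, 3))
  dense <- atomic_model(data.frame(
    elety = c("CB", rep("CA", nrow(cloud))),
    resid = "ALA",
    resno = c(7L, seq_len(nrow(cloud)) + 100L),
    chain = "A",
    x = c(0, cloud$x), y = c(0, cloud$y), z = c(0, cloud$z)))
  b <- classify_mutation(data.frame(pos = 7, germline = "A", patient = "V"),
                         structure = dense)
  expect_true(b$buried)
  # residue absent from the structure: warning, burial NA
  expect_warning(
    miss <- classify_mutation(data.frame(pos = 99, germline = "G",
                                         patient = "A"), structure = lone),
    "missing")
  expect_true(is.na(miss$buried))
})
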