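test_that("config validation", {
  expect_error(simulation_config(10, peptide_length = 15))
  expect_error(simulation_config(40, epitopes = list(list(start = 5, end = 50))))
  expect_error(simulation_config(40, epitopes = list(list(start = 5, end = 9, effect = 1.2))))
  expect_s3_class(simulation_config(40), "simulation_config")
})

test_that("peptide count follows the design formula (P-L+1)(R + 19L)", {
  cfg <- simulation_config(protein_length = 30, peptide_length = 15,
                           native_copies = 2, seed = 2)
  sim <- generate_dataset(cfg)
  expect_equal(nrow(sim$peptides), 16L * (2L + 19L * 15L))  # 4592
})

test_that("identical config and seed give byte-identical tables", {
  cfg <- simulation_config(protein_length = 40, peptide_length = 10,
                           native_copies = 3,
                           epitopes = list(list(start = 12, end = 17)), seed = 9)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1$protein, s2$protein)
  expect_identical(s1$peptides, s2$peptides)
  cfg2 <- simulation_config(protein_length = 40, peptide_length = 10,
                            native_copies = 3,
                            epitopes = list(list(start = 12, end = 17)), seed = 10)
  expect_false(identical(generate_dataset(cfg2)$peptides, s1$peptides))
})

test_that("noise-free construction: null gives all values 1; effects are exact", {
  cfg <- simulation_config(protein_length = 30, peptide_length = 10,
                           native_copies = 2, noise_cv = 0, seed = 4)
  sim <- generate_dataset(cfg)
  m <- map_peptides(sim$peptides, sim$protein, length = 10)
  g <- native_groups(m)
  s <- substitution_records(m, g)
  expect_true(all(s$value == 1))

  cfg2 <- simulation_config(protein_length = 30, peptide_length = 10,
                            native_copies = 2, noise_cv = 0,
                            epitopes = list(list(start = 15, end = 18, effect = 0.1)),
                            heteroclitic = list(list(pos = 5, aa = "W", factor = 2)),
                            seed = 4)
  sim2 <- generate_dataset(cfg2)
  m2 <- map_peptides(sim2$peptides, sim2$protein, length = 10)
  s2 <- substitution_records(m2, native_groups(m2))
  pos <- s2$offset + s2$frame_pos - 1L
  expect_true(all(s2$value[pos %in% 15:18] == 0.1))
  het <- pos == 5L & s2$replacing_aa == "W"
  if (any(het)) expect_true(all(s2$value[het] == 2))
  expect_true(all(s2$value[!(pos %in% 15:18) & !het] == 1))
})

test_that("tolerated amino acids escape the epitope effect", {
  cfg <- simulation_config(protein_length = 30, peptide_length = 10,
                           native_copies = 2, noise_cv = 0,
                           epitopes = list(list(start = 15, end = 16,
                                                tolerated = c("S", "T"),
                                                effect = 0.2)),
                           seed = 8)
  sim <- generate_dataset(cfg)
  m <- map_peptides(sim$peptides, sim$protein, length = 10)
  s <- substitution_records(m, native_groups(m))
  pos <- s$offset + s$frame_pos - 1L
  on_epi <- pos %in% 15:16
  expect_true(all(s$value[on_epi & s$replacing_aa %in% c("S", "T")] == 1))
  expect_true(all(s$value[on_epi & !(s$replacing_aa %in% c("S", "T"))] == 0.2))
})

test_that("alanine-only coverage emits exactly one variant per non-alanine position", {
  cfg <- simulation_config(protein_length = 25, peptide_length = 10,
                           native_copies = 2, coverage = "alanine_only", seed = 12)
  sim <- generate_dataset(cfg)
  chars <- strsplit(sim$protein$sequence, "")[[1]]
  n_windows <- 25L - 10L + 1L
  expected_subs <- sum(vapply(seq_len(n_windows), function(o)
    sum(chars[o:(o + 9L)] != "A"), integer(1)))
  expect_equal(nrow(sim$peptides), n_windows * 2L + expected_subs)
  m <- map_peptides(sim$peptides, sim$protein, length = 10)
  expect_true(all(m$replacing_aa[m$variant_kind == "substitution"] == "A"))
})

test_that("truth_comparison counts residues and regions as defined", {
  cfg <- simulation_config(protein_length = 40,
                           epitopes = list(list(start = 20, end = 27)), seed = 1)
  truth <- generate_dataset(cfg)$truth
  perfect <- seq_len(40) %in% 20:27
  regions <- call_epitope_regions(perfect)
  tc <- truth_comparison(perfect, regions, truth)
  expect_equal(tc$sensitivity, 1)
  expect_equal(tc$fp, 0L)
  expect_equal(tc$region_matches, 1L)

  none <- truth_comparison(logical(40), call_epitope_regions(logical(40)), truth)
  expect_equal(none$fn, 8L)
  expect_equal(none$region_matches, 0L)

  ## a region shifted by one still matches under the +/-1 tolerance
  shifted <- seq_len(40) %in% 19:26
  tcs <- truth_comparison(shifted, call_epitope_regions(shifted), truth)
  expect_equal(tcs$region_matches, 1L)
  expect_equal(tcs$fp_beyond_1, 0L)
  ## a far-away false call is counted beyond the tolerance
  far <- seq_len(40) %in% c(20:27, 35)
  expect_equal(truth_comparison(far, call_epitope_regions(far), truth)$fp_beyond_1, 1L)
})
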