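test_that("build_pssm: complete scan has 285 cells, native cells absent, duplicates averaged", {
  native <- "DHVKLVNEVTEFAKT"
  recs <- full_scan_records(native, function(pos, aa) 1)
  pssm <- build_pssm(recs, native)
  expect_equal(sum(pssm$n), 285L)            # 15 columns x 19 cells
  expect_true(all(pssm$n == 19L))
  chars <- strsplit(native, "")[[1]]
  expect_true(all(is.na(pssm$values[cbind(chars, seq_len(15))])))

  dup <- rbind(recs, data.frame(frame_pos = 1, replacing_aa = "A", value = 3))
  pssm2 <- build_pssm(dup, native)
  expect_equal(pssm2$values["A", 1], 2)      # mean of 1 and 3
  expect_equal(sum(pssm2$n), 285L)

  bad <- data.frame(frame_pos = 1, replacing_aa = "D", value = 1)
  expect_error(build_pssm(bad, native), "mapping bug")
})

test_that("build_pssm: alanine scan and missing spots decrement n_i", {
  native <- "ACDEF"
  ala <- data.frame(frame_pos = c(2, 3, 4, 5), replacing_aa = "A",
                    value = c(0.9, 1, 1.1, 1))
  pssm <- build_pssm(ala, native)
  expect_equal(unname(pssm$n), c(0L, 1L, 1L, 1L, 1L))

  recs <- full_scan_records(native, function(pos, aa) 1)
  recs <- recs[!(recs$frame_pos == 3 & recs$replacing_aa == "W"), ]
  pssm2 <- build_pssm(recs, native)
  expect_equal(unname(pssm2$n), c(19L, 19L, 18L, 19L, 19L))
})

test_that("pooled_variance: hand-computed toy and degenerate cases", {
  ## 2-column toy {col1: 0.9, 1.1; col2: 0.4, 0.6} -> (0.02+0.02)/(4-2) = 0.02
  recs <- data.frame(frame_pos = c(1, 1, 2, 2),
                     replacing_aa = c("A", "C", "A", "C"),
                     value = c(0.9, 1.1, 0.4, 0.6))
  pssm <- build_pssm(recs, "DE")
  expect_equal(pooled_variance(pssm), 0.02)

  const <- full_scan_records("ACDEF", function(pos, aa) 0.7)
  expect_equal(pooled_variance(build_pssm(const, "ACDEF")), 0)

  ala <- data.frame(frame_pos = 2:5, replacing_aa = "A", value = 1)
  expect_error(pooled_variance(build_pssm(ala, "CDEFG")), "insufficient data")
})

test_that("complete scans give identical SE (hence LSD) at every position", {
  set.seed(41)
  recs <- full_scan_records("DHVKLVNEVTEFAKT",
                            function(pos, aa) rnorm(1, 1, 0.05))
  call <- call_epitope_positions(build_pssm(recs, "DHVKLVNEVTEFAKT"))
  expect_equal(length(unique(round(call$lsd, 12))), 1L)
})

test_that("call_epitope_positions: null, planted, heteroclitic one-tailedness", {
  set.seed(42)
  native <- "DHVKLVNEVTEFAKT"
  null_recs <- full_scan_records(native, function(pos, aa) rnorm(1, 1, 0.05))
  expect_false(any(call_epitope_positions(build_pssm(null_recs, native))$flags))

  planted <- full_scan_records(native, function(pos, aa)
    rnorm(1, if (pos %in% 5:12) 0.2 else 1, 0.05))
  pssm <- build_pssm(planted, native)
  call <- call_epitope_positions(pssm, alpha = 1e-4)
  expect_equal(which(call$flags), 5:12)
  expect_equal(call$flags, brute_force_epitope_flags(pssm$values, 1e-4))

  ## a strong heteroclitic position (mu = 1.8) must never be flagged
  het <- full_scan_records(native, function(pos, aa)
    rnorm(1, if (pos == 4) 1.8 else 1, 0.05))
  expect_false(call_epitope_positions(build_pssm(het, native))$flags[4])
  expect_error(call_epitope_positions(pssm, alpha = 2), "alpha")
})

test_that("flag rule equals the brute-force oracle on random small PSSMs", {
  set.seed(99)
  for (rep in 1:25) {
    L <- sample(3:6, 1)
    native <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    chars <- strsplit(native, "")[[1]]
    recs <- do.call(rbind, lapply(seq_len(L), function(j) {
      n_j <- sample(2:4, 1)
      data.frame(frame_pos = j,
                 replacing_aa = sample(setdiff(AA_ALPHABET, chars[j]), n_j),
                 value = pmax(rnorm(n_j, runif(1, 0.2, 1.2), 0.15), 0))
    }))
    pssm <- build_pssm(recs, native)
    alpha <- sample(c(0.05, 0.01, 1e-3), 1)
    call <- call_epitope_positions(pssm, alpha = alpha)
    expect_equal(call$flags, brute_force_epitope_flags(pssm$values, alpha))
  }
})

test_that("monotonicity: lowering a column mean never un-flags it", {
  set.seed(13)
  native <- "ACDEFGHIKL"
  recs <- full_scan_records(native, function(pos, aa)
    rnorm(1, if (pos == 5) 0.55 else 1, 0.1))
  call1 <- call_epitope_positions(build_pssm(recs, native), alpha = 0.01)
  recs2 <- recs
  recs2$value[recs2$frame_pos == 5] <- recs2$value[recs2$frame_pos == 5] - 0.3
  call2 <- call_epitope_positions(build_pssm(recs2, native), alpha = 0.01)
  expect_true(all(which(call1$flags) %in% which(call2$flags) |
                    !(seq_along(call1$flags) %in% 5)))
  expect_true(call2$flags[5] >= call1$flags[5])
})

test_that("format_epitope_string reproduces the dashed reporting dialect", {
  flags <- seq_len(15) %in% 5:12
  expect_equal(format_epitope_string("DHVKLVNEVTEFAKT", flags),
               "----LVNEVTEF---")
  expect_equal(format_epitope_string("QQCPFEDHVKLVNEV", rep(FALSE, 15)),
               "---------------")
  expect_equal(format_epitope_string("ACDEF", rep(TRUE, 5)), "ACDEF")
  expect_equal(format_epitope_string("ACDEF", c(TRUE, NA, FALSE, NA, TRUE)),
               "A---F")
})
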