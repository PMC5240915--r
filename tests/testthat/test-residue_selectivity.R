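test_that("residues flagged in no peptide yield empty, non-selective matrices", {
  rsm <- make_rsm(list(E = c(1, 1.1), A = c(0.2, 0.3)), "E")
  rsm$data <- rsm$data[0L]  # simulate: nothing included
  prof <- selectivity_stats(rsm)
  expect_false(prof$selective)
  expect_equal(nrow(prof$stats), 0L)

  ## via the inclusion rule itself: no TRUE flags anywhere
  subs <- data.table::data.table(protein_id = "p", offset = 10L, frame_pos = 1L,
                                 native_aa = "E", replacing_aa = "A", value = 0.2)
  ratios <- data.table::data.table(protein_id = "p", offset = 10L, ratio = 1)
  calls <- data.table::data.table(offset = 10L, frame_pos = 1L, flag = FALSE)
  rsm2 <- build_residue_matrix(10L, subs, ratios, calls)
  expect_equal(nrow(rsm2$data), 0L)
  expect_false(selectivity_stats(rsm2)$selective)
})

test_that("degenerate variance (all values identical) is non-selective with p = 1", {
  rsm <- make_rsm(list(E = rep(1, 4), A = rep(1, 5), K = rep(1, 3)), "E")
  prof <- selectivity_stats(rsm)
  expect_false(prof$selective)
  expect_true(all(prof$stats$p == 1))
  expect_equal(prof$mu_g, 1)
})

test_that("complete native selectivity: native t large positive, p << 1", {
  set.seed(6)
  cols <- setNames(lapply(AA_ALPHABET, function(a)
    pmax(rnorm(8, 0.05, 0.02), 0)), AA_ALPHABET)
  cols$E <- rnorm(8, 1, 0.05)
  prof <- selectivity_stats(make_rsm(cols, "E"))
  st <- prof$stats
  expect_gt(st[st$aa == "E", ]$t, 10)
  expect_lt(st[st$aa == "E", ]$p, 1e-10)
  expect_true(prof$selective)
})

test_that("two-column (alanine-only) matrices condense exactly to a Student t-test", {
  set.seed(77)
  for (rep in 1:20) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    nat <- rnorm(n1, 1, 0.1)
    ala <- rnorm(n2, runif(1, 0.1, 1.1), 0.1)
    prof <- selectivity_stats(make_rsm(list(E = nat, A = ala), "E"))
    tt <- t.test(ala, nat, var.equal = TRUE)
    expect_equal(prof$stats[aa == "A", t], unname(tt$statistic),
                 tolerance = 1e-12)
    p_oracle <- pt(abs(tt$statistic), df = n1 + n2 - 2, lower.tail = FALSE)
    expect_lt(abs(prof$stats[aa == "A", p] - p_oracle), 1e-9)
    expect_equal(prof$df, n1 + n2 - 2)
  }
})

test_that("logo scores: normalization, degenerate zero case, hand computation", {
  set.seed(15)
  cols <- setNames(lapply(AA_ALPHABET, function(a) rnorm(6, 0.3, 0.1)), AA_ALPHABET)
  cols$D <- rnorm(6, 1, 0.05)
  prof <- selectivity_stats(make_rsm(cols, "D"))
  s <- logo_scores(prof)
  expect_lt(abs(sum(abs(s)) - (1 - prof$mu_g)), 1e-12)
  expect_gt(s["D"], 0)

  flat <- selectivity_stats(make_rsm(list(E = rep(1, 4), A = rep(1, 4)), "E"))
  expect_true(all(logo_scores(flat) == 0))

  ## two-amino-acid toy, hand-calculated through the Student-t identity
  nat <- c(0.95, 1.00, 1.05, 1.00)
  ala <- c(0.55, 0.60, 0.65, 0.60)
  prof2 <- selectivity_stats(make_rsm(list(E = nat, A = ala), "E"))
  tt <- t.test(ala, nat, var.equal = TRUE)
  p_hand <- pt(abs(tt$statistic), 6, lower.tail = FALSE)
  raw <- c(A = log10(p_hand), E = -log10(p_hand))  # sign(t_A) < 0 < sign(t_E)
  s_hand <- raw * (1 - prof2$mu_g) / sum(abs(raw))
  s2 <- logo_scores(prof2)
  expect_equal(unname(s2[c("A", "E")]), unname(s_hand), tolerance = 1e-9)
})

test_that("antisymmetry: reflecting values about mu_g flips every t and s", {
  set.seed(30)
  cols <- setNames(lapply(c("E", "A", "K", "W"), function(a)
    rnorm(5, runif(1, 0.2, 1), 0.1)), c("E", "A", "K", "W"))
  rsm <- make_rsm(cols, "E")
  prof <- selectivity_stats(rsm)
  mu_g <- prof$mu_g
  refl <- lapply(cols, function(v) 2 * mu_g - v)
  prof_r <- selectivity_stats(make_rsm(refl, "E"))
  o <- order(prof$stats$aa); or <- order(prof_r$stats$aa)
  expect_equal(prof_r$stats$t[or], -prof$stats$t[o], tolerance = 1e-10)
  expect_equal(unname(logo_scores(prof_r)), -unname(logo_scores(prof)),
               tolerance = 1e-10)
})

test_that("region caller: worked examples of the >=4 residues / gaps <=2 rule", {
  f <- function(pos, n = 40) seq_len(n) %in% pos
  r1 <- call_epitope_regions(f(10:13))
  expect_equal(r1[, c(start, end, n_selective)], c(10L, 13L, 4L))

  seqc <- paste(rep("Q", 40), collapse = "")
  r2 <- call_epitope_regions(f(c(10:13, 16:19)), sequence = seqc)
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$end), c(10L, 19L))
  expect_equal(r2$region, "QQQQ--QQQQ")

  expect_equal(nrow(call_epitope_regions(f(30:32))), 0L)   # only 3 residues
  expect_equal(nrow(call_epitope_regions(f(c(5:8, 12:15)))), 2L)  # gap of 3 splits
  expect_equal(nrow(call_epitope_regions(logical(40))), 0L)
})

test_that("region caller equals the brute-force enumerator on random vectors", {
  set.seed(55)
  for (rep in 1:1000) {
    dens <- runif(1, 0.05, 0.6)
    flags <- runif(120) < dens
    got <- call_epitope_regions(flags)
    want <- brute_force_regions(flags)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_selective, want$n_selective)
    }
  }
})

test_that("planted selectivity class is recovered with correct signs", {
  tolerated <- c("I", "L", "V", "M")   # a non-polar-tolerant position
  ok <- 0L
  for (run in 1:20) {
    set.seed(1000 + run)
    cols <- setNames(lapply(AA_ALPHABET, function(a) {
      center <- if (a %in% c(tolerated, "L")) 1 else 0.2
      pmax(rnorm(6, center, 0.1), 0)
    }), AA_ALPHABET)
    prof <- selectivity_stats(make_rsm(cols, "L"))
    s <- logo_scores(prof)
    good <- all(s[tolerated] > 0) &&
      all(s[setdiff(AA_ALPHABET, c(tolerated, "L"))] < 0)
    ok <- ok + as.integer(good)
  }
  expect_gte(ok, 19L)
})
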