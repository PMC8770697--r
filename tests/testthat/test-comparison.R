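test_that("FSr of a model against itself is unity", {
  fv <- fva(toy_microbe(), gamma = 1)
  fsr <- flux_span_ratio(fv, fv)
  live <- fsr$class != "degenerate"
  expect_true(all(abs(fsr$fsr[live] - 1) < 1e-6))
})

test_that("FSr reproduces the crafted demand-widening pair", {
  a <- metabolic_model(dplyr::bind_rows(
    rxn_row("SK_S", "S[c] <=>", -1000, 1000, kind = "sink"),
    rxn_row("R1", "S[c] -> P[c]", 0, 1000),
    rxn_row("DM_P", "P[c] ->", 0, 2, kind = "demand")),
    objective = c(R1 = 1))
  b <- metabolic_model(dplyr::bind_rows(
    a$reactions,
    rxn_row("DM_P_extra", "P[c] ->", 0, 8, kind = "demand")),
    objective = c(R1 = 1))
  fsr <- flux_span_ratio(fva(a, gamma = 0), fva(b, gamma = 0))
  r1 <- fsr[fsr$reaction_id == "R1", ]
  expect_equal(r1$span_a, 2, tolerance = 1e-6)
  expect_equal(r1$span_b, 10, tolerance = 1e-6)
  expect_equal(r1$fsr, 0.2, tolerance = 1e-6)
  expect_true("DM_P_extra" %in% attr(fsr, "only_b"))
  # swapping the conditions inverts the ratio
  fsr2 <- flux_span_ratio(fva(b, gamma = 0), fva(a, gamma = 0))
  expect_equal(fsr2$fsr[fsr2$reaction_id == "R1"], 5, tolerance = 1e-6)
})

test_that("degenerate and infinite ratios are flagged, never classified", {
  fake_a <- tibble::tibble(reaction_id = c("r1", "r2", "r3"),
                           vmin = c(0, 0, 0), vmax = c(3, 0, 0))
  fake_b <- tibble::tibble(reaction_id = c("r1", "r2", "r3"),
                           vmin = c(0, 0, 0), vmax = c(0, 0, 5))
  fsr <- flux_span_ratio(fake_a, fake_b)
  expect_equal(fsr$fsr[1], Inf)
  expect_identical(fsr$class[2], "degenerate")
  cl <- classify_fsr(fsr)
  expect_identical(cl$class, c("decreased_in_b", "degenerate",
                               "increased_in_b"))
})

test_that("classification partitions records at the stated thresholds", {
  rec <- structure(tibble::tibble(
    reaction_id = paste0("r", 1:5),
    span_a = c(0.5, 1, 2.5, 0.8, 2) , span_b = 1,
    fsr = c(0.5, 1, 2.5, 0.8, 2), class = "unchanged"),
    class = c("fsr_result", "tbl_df", "tbl", "data.frame"))
  cl <- classify_fsr(rec, low = 0.8, high = 2)
  expect_identical(cl$class,
                   c("increased_in_b", "unchanged", "decreased_in_b",
                     "unchanged", "unchanged"))
  expect_equal(nrow(affected_reactions(cl)), 2)
})

test_that("FSr is anti-symmetric under condition swap", {
  pp <- perturbation_pair()
  fa <- fva(pp$model_a); fb <- fva(pp$model_b)
  fwd <- classify_fsr(flux_span_ratio(fa, fb))
  rev <- classify_fsr(flux_span_ratio(fb, fa))
  i <- match(fwd$reaction_id, rev$reaction_id)
  live <- fwd$class != "degenerate" & is.finite(fwd$fsr) & fwd$fsr > 0
  expect_equal(rev$fsr[i][live], 1 / fwd$fsr[live], tolerance = 1e-5)
  swapped <- ifelse(fwd$class == "increased_in_b", "decreased_in_b",
                    ifelse(fwd$class == "decreased_in_b",
                           "increased_in_b", fwd$class))
  expect_identical(rev$class[i][live], swapped[live])
})

test_that("maxabs mode ratios absolute maximal fluxes", {
  fake_a <- tibble::tibble(reaction_id = "r", vmin = -4, vmax = 2)
  fake_b <- tibble::tibble(reaction_id = "r", vmin = -1, vmax = 8)
  fsr <- flux_span_ratio(fake_a, fake_b, mode = "maxabs")
  expect_equal(fsr$fsr, 0.5)
})

test_that("min-norm deltas vanish for identical models and flag missing ids", {
  m <- toy_microbe()
  d <- minnorm_delta(m, m)
  expect_true(all(abs(d$delta) < 1e-5))
  pp <- perturbation_pair()
  d2 <- minnorm_delta(pp$model_a, pp$model_b)
  expect_true(all(d2$missing_in[d2$reaction_id %in%
                                  ros_reaction_ids()] == "a"))
  expect_false(any(is.na(d2$reaction_id)))
})

test_that("secretome profiling reads maximal secretion per exchange", {
  m <- chain_model()
  prof <- secretome_profile(m, condition = "toy")
  expect_equal(prof$max_secretion[prof$exchange_id == "EX_B"], 10,
               tolerance = 1e-5)
  closed <- apply_medium(m, medium_spec(c(EX_A = 0)))
  prof0 <- secretome_profile(closed)
  expect_true(all(abs(prof0$max_secretion) < 1e-5))
})

test_that("secretome comparison classifies three ways and is scale invariant", {
  mk <- function(v) tibble::tibble(exchange_id = paste0("e", seq_along(v)),
                                   metabolite = paste0("m", seq_along(v)),
                                   max_secretion = v, condition = "x")
  cmp <- compare_secretomes(mk(c(10, 10, 10)), mk(c(15, 10.2, 0)))
  expect_identical(cmp$change, c("increased", "same", "decreased"))
  cmp2 <- compare_secretomes(mk(c(10, 10, 10) * 7), mk(c(15, 10.2, 0) * 7))
  expect_identical(cmp2$change, cmp$change)
})

test_that("hypergeometric enrichment matches the exact combinatorial tail", {
  # N = 100, K = 10, n = 5, k = 4
  mk_model <- function(N, K) {
    rx <- tibble::tibble(
      id = paste0("r", seq_len(N)), name = paste0("r", seq_len(N)),
      stoichiometry = rep(list(c("x[c]" = 1)), N),
      lb = 0, ub = 1, subsystem = c(rep("target", K),
                                    rep("other", N - K)),
      gpr = "", kind = "internal")
    metabolic_model(rx, objective = c(r1 = 1))
  }
  m <- mk_model(100, 10)
  affected <- c(paste0("r", 1:4), "r99")
  enr <- flux_enrichment(affected, m)
  p_exact <- sum(vapply(4:5, function(j) {
    choose(10, j) * choose(90, 5 - j) / choose(100, 5)
  }, numeric(1)))
  expect_equal(enr$p[enr$subsystem == "target"], p_exact,
               tolerance = 1e-12)
  # zero hits: upper tail at k = 0 is 1
  enr0 <- flux_enrichment(paste0("r", 95:99), m)
  expect_equal(enr0$p[enr0$subsystem == "target"],
               stats::phyper(-1, 10, 90, 5, lower.tail = FALSE))
  expect_equal(enr0$p[enr0$subsystem == "target"], 1)
  # exhaustive sweep against the explicit sum for all N <= 30
  withr::with_seed(5, {
    for (rep in 1:20) {
      N <- sample(5:30, 1)
      K <- sample(1:(N - 1), 1)
      n <- sample(1:N, 1)
      mm <- mk_model(N, K)
      aff <- paste0("r", sample(N, n))
      enr <- flux_enrichment(aff, mm)
      k <- sum(aff %in% paste0("r", seq_len(K)))
      p_oracle <- sum(vapply(k:min(K, n), function(j) {
        choose(K, j) * choose(N - K, n - j) / choose(N, n)
      }, numeric(1)))
      expect_equal(enr$p[enr$subsystem == "target"], p_oracle,
                   tolerance = 1e-10)
      expect_true(all(enr$k <= pmin(enr$K, enr$n)))
      expect_true(all(enr$p > 0 & enr$p <= 1))
    }
  })
})
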