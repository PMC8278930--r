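test_that("unit conversions follow their closed forms", {
  expect_equal(mass_to_molar(0.96, 146000), 6.58e-6, tolerance = 1e-3)
  expect_equal(mass_to_molar(1, 1000), 1e-3)
  expect_error(mass_to_molar(0, 1000), class = "mabtherm_validation_error")

  expect_equal(compute_KD(1e5, 1e-3), 1e-8)
  expect_equal(compute_KD(3.3e4, 6.6e-4), 2e-8)
  expect_equal(compute_KD(1e5, 2e-3), 2 * compute_KD(1e5, 1e-3))
  expect_error(compute_KD(0, 1e-3), class = "mabtherm_domain_error")
})

test_that("1:1 closed form matches ODE integration to 1e-8 over all phases", {
  kon <- 1e5; koff <- 1e-3; Rmax <- 1; C <- 6.58e-6
  sg <- simulate_1to1(kon, koff, Rmax, C, t_baseline = 60, t_assoc = 120,
                      t_dissoc = 120, dt = 0.5)
  ## oracle: integrate dR/dt = kon C (Rmax - R) - koff R phase by phase
  f_assoc <- function(t, y, p) list(kon * C * (Rmax - y) - koff * y)
  f_diss <- function(t, y, p) list(-koff * y)
  ta <- 60; td <- 180
  t1 <- sg$t[sg$t >= ta & sg$t <= td]
  sol1 <- deSolve::ode(c(R = 0), t1, f_assoc, NULL, rtol = 1e-12, atol = 1e-14)
  t2 <- sg$t[sg$t >= td]
  sol2 <- deSolve::ode(c(R = unname(sol1[nrow(sol1), "R"])), t2, f_diss, NULL,
                       rtol = 1e-12, atol = 1e-14)
  expect_lt(max(abs(sg$R[sg$t >= ta & sg$t <= td] - sol1[, "R"])), 1e-8)
  expect_lt(max(abs(sg$R[sg$t >= td] - sol2[, "R"])), 1e-8)

  ## C = 0: flat zero; saturation limit for C >> KD
  expect_equal(simulate_1to1(kon, koff, Rmax, 0)$R,
               rep(0, length(simulate_1to1(kon, koff, Rmax, 0)$t)))
  sat <- simulate_1to1(kon, koff, Rmax, 1e-3, t_assoc = 2000, dt = 1)
  expect_equal(max(sat$R), Rmax, tolerance = 1e-3)
})

test_that("1:2 simulation reduces, superposes and conserves sites", {
  C <- bli_C
  ## kon2 = 0, Rmax2 = 0 reduces to 1:1 in both model forms
  base <- simulate_1to1(bli_truth$kon1, bli_truth$koff1, bli_truth$Rmax1, C)
  par0 <- simulate_1to2(bli_truth$kon1, bli_truth$koff1, bli_truth$Rmax1,
                        0, 1e-3, 0, C)
  expect_equal(par0$R, base$R, tolerance = 1e-12)
  seq0 <- simulate_1to2(bli_truth$kon1, bli_truth$koff1, bli_truth$Rmax1,
                        0, 1e-3, 0, C, model_form = "sequential_bivalent")
  expect_equal(seq0$R, base$R, tolerance = 1e-6)

  ## parallel sites is the superposition of two independent 1:1 traces
  p12 <- do.call(simulate_1to2, c(bli_truth, list(C = C)))
  second <- simulate_1to1(bli_truth$kon2, bli_truth$koff2, bli_truth$Rmax2, C)
  expect_equal(p12$R, base$R + second$R, tolerance = 1e-12)

  ## sequential bivalent conserves L + AL + 2 AL2
  sq <- do.call(simulate_1to2, c(bli_truth, list(
    C = C, model_form = "sequential_bivalent")))
  sp <- attr(sq, "species")
  expect_lt(max(abs(sp$AL + 2 * sp$AL2 + sp$L - 1)), 1e-9)
  ## response continuous, non-negative, non-increasing in dissociation
  expect_true(all(sq$R >= -1e-12))
  dis <- sq$R[sq$phase == "dissociation"]
  expect_true(all(diff(dis) <= 1e-10))
})

test_that("noiseless parallel-sites parameters are recovered within 1 percent", {
  sg <- do.call(simulate_1to2, c(bli_truth, list(C = bli_C, dt = 0.2)))
  fit <- bli_fit(sg, "one_to_two")
  expect_true(fit$converged)
  est <- unlist(fit$params)
  expect_equal(unname(est), unname(unlist(bli_truth)), tolerance = 0.01)
  expect_equal(fit$KD, bli_truth$koff1 / bli_truth$kon1, tolerance = 0.01)

  ## the nested 1:1 model fits strictly worse
  f1 <- bli_fit(sg, "one_to_one")
  expect_gt(f1$rmse, fit$rmse)
  expect_equal(fit$rmse, sqrt(fit$rss / fit$n), tolerance = 1e-12)
})

test_that("seeded noisy recovery of kon1/koff1 is within 10% in >=90% of runs", {
  ## dissociation observed for 300 s: at koff1 = 5e-4 1/s a shorter window
  ## sees almost no decay and koff is then fundamentally underdetermined
  n <- 30L; ok <- 0L
  for (s in seq_len(n)) {
    sg <- generate_sensorgram(bli_truth, bli_C,
                              noise_sd = 0.005 * bli_truth$Rmax1,
                              seed = 500 + s, dt = 0.2, t_dissoc = 300)
    fit <- tryCatch(bli_fit(sg, "one_to_two"), error = function(e) NULL)
    if (is.null(fit)) next
    if (abs(fit$params$kon1 / bli_truth$kon1 - 1) < 0.1 &&
        abs(fit$params$koff1 / bli_truth$koff1 - 1) < 0.1) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.9 * n))
})

test_that("degenerate sensorgrams raise typed errors", {
  flat <- sensorgram(0:99, rep(0, 100),
                     rep(c("baseline", "association", "dissociation"),
                         c(20, 40, 40)), 1e-6)
  expect_error(bli_fit(flat), class = "mabtherm_fit_error")

  no_diss <- sensorgram(0:99, c(rep(0, 20), seq(0, 1, length.out = 80)),
                        rep(c("baseline", "association"), c(20, 80)), 1e-6)
  expect_error(bli_fit(no_diss), class = "mabtherm_fit_error")

  expect_error(sensorgram(c(0, 0, 1), 1:3, rep("baseline", 3), 1e-6),
               class = "mabtherm_validation_error")
  expect_error(sensorgram(0:2, 1:3, c("baseline", "assoc", "dissociation"),
                          1e-6), class = "mabtherm_validation_error")
})
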