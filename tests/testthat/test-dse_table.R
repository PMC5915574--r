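test_that("DSE table invariants hold on random data", {
  set.seed(23)
  dse <- compute_dse_timeseries(random_scaled(40, 25))
  tab <- dse_table(dse, include_nonglobal = TRUE)
  expect_equal(tab["A", "pct_avar"], 100)
  expect_equal(tab["A", "rel_iid"], 1)
  expect_equal(sum(tab[c("D", "S", "E"), "pct_avar"]), 100, tolerance = 1e-10)
  expect_true(all(tab$rms >= 0))
  expect_equal(tab$ms, tab$rms^2)
  # non-global rows are the whole-minus-global complement
  expect_equal(tab["AN", "ms"], tab["A", "ms"] - tab["AG", "ms"])
  expect_error(dse_table(dse, I = 41), "inconsistent")
})

test_that("IID expectations: T = 100 gives %D-var 49.5 and rel_iid 1 everywhere", {
  e <- expected_dse_table("iid", sigma_bar_sq = 7, I = 50, T = 100,
                          include_nonglobal = TRUE)
  expect_equal(e["D", "pct_avar"], 49.5)
  expect_equal(e$rel_iid, rep(1, nrow(e)), tolerance = 1e-12)
})

test_that("separable expectations: D/S split, E term, S-D gap, spatial index", {
  # under independence D and S are equal
  e0 <- expected_dse_table("separable", sigma_bar_sq = 3, rho = 0,
                           sigma_dbar_sq = 0.5, I = 200, T = 300)
  expect_equal(e0["D", "ms"], e0["S", "ms"])
  # E whole MS = sigma^2/T for any rho
  for (rho in c(0, 0.3, 0.6, 0.9)) {
    e <- expected_dse_table("separable", sigma_bar_sq = 3, rho = rho,
                            sigma_dbar_sq = 0.5, I = 200, T = 300)
    expect_equal(e["E", "ms"], 3 / 300)
    # normalized S - D = rho (T-1)/T on a grid
    expect_equal((e["S", "pct_avar"] - e["D", "pct_avar"]) / 100,
                 rho * 299 / 300, tolerance = 1e-12)
    # AG normalized to A is sigma_dbar^2 / sigma_bar^2; relative to the IID
    # value 1/I it becomes the spatial-structure index I * ratio
    expect_equal(e["AG", "pct_avar"], 100 * 0.5 / 3, tolerance = 1e-12)
    expect_equal(e["AG", "rel_iid"], 200 * 0.5 / 3, tolerance = 1e-12)
  }
  e6 <- expected_dse_table("separable", sigma_bar_sq = 1, rho = 0.6, I = 10,
                           T = 1200)
  expect_equal((e6["S", "pct_avar"] - e6["D", "pct_avar"]) / 100,
               0.6 * 1199 / 1200)
})

test_that("simulated IID data sits at rel_iid close to 1", {
  set.seed(29)
  sim <- simulate_null(simulation_spec(I = 4000, T = 600, sigma_min = 200,
                                       sigma_max = 500))
  tab <- dse_table(compute_dse_timeseries(sim$data))
  expect_true(all(abs(tab[c("D", "S"), "rel_iid"] - 1) < 0.02))
  expect_gt(tab["AG", "rel_iid"], 0.5)
  expect_lt(tab["AG", "rel_iid"], 2)
})

test_that("lag-1 heuristic: limits and Monte-Carlo recovery", {
  # exact repetition: D = 0, rho_hat = S/A * T/(T-1)
  v <- rnorm(5)
  dse <- compute_dse_timeseries(cbind(v, v))  # Y_{t+1} = Y_t
  expect_equal(dse$averages$whole$D, 0)
  l <- lag1_estimate(dse)
  expect_equal(l$rho_hat, dse$averages$whole$S / dse$averages$whole$A * 2)

  set.seed(31)
  iid <- simulate_null(simulation_spec(I = 2000, T = 600, sigma_min = 200,
                                       sigma_max = 500))
  expect_lt(abs(lag1_estimate(compute_dse_timeseries(iid$data))$rho_hat), 0.03)
  ar <- simulate_ar1_spikes(simulation_spec(I = 2000, T = 600, rho = 0.4))
  lr <- lag1_estimate(compute_dse_timeseries(ar$data))
  expect_lt(abs(lr$rho_hat - 0.4), 0.05)
  expect_equal(length(lr$rho_t), 599)
  # per-pair series averages back to the scan-level estimate
  expect_equal(mean(lr$rho_t) * 599 / 600, lr$rho_hat, tolerance = 1e-10)
})

test_that("table writers are schema-stable and readable back", {
  set.seed(37)
  tab <- dse_table(compute_dse_timeseries(random_scaled(20, 15)))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  txt <- tempfile(fileext = ".txt")
  write_dse_table(tab, tsv, "tsv")
  write_dse_table(tab, js, "json")
  write_dse_table(tab, txt, "txt")
  back <- read.delim(tsv)
  expect_named(back, c("source", "component", "ms", "rms", "pct_avar",
                       "rel_iid"))
  expect_equal(back$rms, tab$rms, tolerance = 1e-6)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$T, 15)
  expect_equal(j$rows$rel_iid, tab$rel_iid, tolerance = 1e-9)
  expect_true(any(grepl("Relative to IID", readLines(txt))))
})
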