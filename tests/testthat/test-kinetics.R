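test_that("langmuir boundaries: zero at t=0, saturation when C >> KD", {
  expect_equal(langmuir_response(0, 1e5, 1e-3, 100, 1e-8, "association"), 0)
  # dissociation starts at the association end level
  r_end <- langmuir_response(300, 1e5, 1e-3, 100, 1e-8, "association")
  expect_equal(
    langmuir_response(0, 1e5, 1e-3, 100, 1e-8, "dissociation", assoc_duration = 300),
    r_end
  )
  # C = 1000 * KD, long time: response ~ rmax
  kd <- 1e-3 / 1e5
  expect_equal(
    langmuir_response(1e5, 1e5, 1e-3, 100, 1000 * kd, "association"),
    100,
    tolerance = 2e-3
  )
  expect_error(langmuir_response(10, -1, 1e-3, 100, 1e-8), "positive")
  expect_error(langmuir_response(10, 1e5, 1e-3, 100, 1e-8, "dissociation"), "assoc_duration")
})

test_that("closed form matches numerical ODE integration across a parameter grid", {
  skip_if_not_installed("deSolve")
  grid <- expand.grid(
    kon = c(1e4, 1e5, 1e6), koff = c(1e-4, 1e-3, 1e-2), conc = c(1e-9, 1e-8, 1e-7)
  )
  times <- seq(0, 1000, by = 50)
  for (k in seq_len(nrow(grid))) {
    with(grid[k, ], {
      closed <- langmuir_response(times, kon, koff, 100, conc, "association")
      ode <- ode_langmuir(times, kon, koff, 100, conc)
      expect_lt(max(abs(closed - ode)), 1e-6)
      # dissociation from the 1000 s association level
      r0 <- closed[length(closed)]
      closed_d <- langmuir_response(times, kon, koff, 100, conc, "dissociation",
        assoc_duration = 1000
      )
      ode_d <- ode_langmuir(times, kon, koff, 100, conc, r0 = r0, dissociation = TRUE)
      expect_lt(max(abs(closed_d - ode_d)), 1e-6)
    })
  }
})

test_that("association is non-decreasing and dissociation non-increasing", {
  t <- seq(0, 600, by = 5)
  for (p in list(c(1e5, 1e-3), c(1e6, 1e-4), c(1e7, 1e-2))) {
    ra <- langmuir_response(t, p[1], p[2], 100, 5e-9, "association")
    rd <- langmuir_response(t, p[1], p[2], 100, 5e-9, "dissociation", assoc_duration = 600)
    expect_true(all(diff(ra) >= 0))
    expect_true(all(diff(rd) <= 0))
  }
})

test_that("KD equals koff/kon exactly in every returned fit", {
  sim <- simulate_sensorgrams(seed = 2, n_clones = 2, noise_sd = 0.5)
  for (id in unique(sim$sensorgrams$clone_id)) {
    f <- fit_one_to_one(sim$sensorgrams[sim$sensorgrams$clone_id == id, ])
    expect_identical(f$kd, f$koff / f$kon)
    expect_identical(f$kd_nM, f$kd * 1e9)
  }
  # the ratio identity at the picomolar scale: kon 1e6, koff 4e-6 -> 4 pM
  expect_equal(4e-6 / 1e6, 4e-12)
})

test_that("noiseless fits recover kon, koff, rmax to better than 0.1 percent", {
  # parameter pairs spanning ~1 pM to ~100 nM
  params <- list(
    c(kon = 1e7, koff = 1e-5), # 1 pM
    c(kon = 1e6, koff = 4e-6), # 4 pM
    c(kon = 1e6, koff = 1e-3), # 1 nM
    c(kon = 1e5, koff = 1e-2)  # 100 nM
  )
  t_assoc <- seq(0, 180, by = 3)
  t_diss <- seq(0, 420, by = 3)
  for (p in params) {
    rows <- list()
    for (conc in 1e-9 * 100 / 5^(0:4)) {
      ra <- langmuir_response(t_assoc, p["kon"], p["koff"], 100, conc, "association")
      rd <- langmuir_response(t_diss, p["kon"], p["koff"], 100, conc, "dissociation",
        assoc_duration = 180
      )
      rows[[length(rows) + 1]] <- data.frame(
        conc_M = conc,
        phase = rep(c("association", "dissociation"), c(length(t_assoc), length(t_diss))),
        time_s = c(t_assoc, t_diss), ru = c(ra, rd)
      )
    }
    f <- fit_one_to_one(do.call(rbind, rows))
    expect_true(f$converged)
    expect_lt(abs(f$kon - p["kon"]) / p["kon"], 1e-3)
    expect_lt(abs(f$koff - p["koff"]) / p["koff"], 1e-3)
    expect_lt(abs(f$rmax - 100) / 100, 1e-3)
  }
})

test_that("fits flag poor identifiability when concentrations sit below KD", {
  # KD = 1 uM but analyte only reaches 1 nM
  t_assoc <- seq(0, 180, by = 5)
  t_diss <- seq(0, 300, by = 5)
  rows <- list()
  for (conc in c(1e-9, 2e-10, 4e-11)) {
    ra <- langmuir_response(t_assoc, 1e4, 1e-2, 100, conc, "association")
    rd <- langmuir_response(t_diss, 1e4, 1e-2, 100, conc, "dissociation",
      assoc_duration = 180
    )
    rows[[length(rows) + 1]] <- data.frame(
      conc_M = conc,
      phase = rep(c("association", "dissociation"), c(length(t_assoc), length(t_diss))),
      time_s = c(t_assoc, t_diss), ru = c(ra, rd)
    )
  }
  expect_warning(f <- fit_one_to_one(do.call(rbind, rows)), "poorly identified")
  expect_false(f$well_determined)
})

test_that("input validation rejects under-determined designs", {
  sim <- simulate_sensorgrams(seed = 1, n_clones = 1)
  sg <- sim$sensorgrams
  expect_error(fit_one_to_one(sg[sg$conc_M %in% unique(sg$conc_M)[1:2], ]), "3 analyte")
  expect_error(fit_one_to_one(sg[sg$phase == "association", ]), "dissociation")
})

test_that("moderate noise leaves KD within a small log error (quick check)", {
  errs <- vapply(1:3, function(s) {
    sim <- simulate_sensorgrams(
      seed = 100 + s, n_clones = 1, noise_sd = 1,
      concentrations_nM = 100 / 5^(0:4)
    )
    f <- fit_one_to_one(sim$sensorgrams)
    abs(log10(f$kd / sim$truth$kd[1]))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
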