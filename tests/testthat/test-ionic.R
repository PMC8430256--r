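p <- epParameters()

test_that("printed calcium-handling constants are exposed unchanged", {
  expect_identical(p$V_SR, 1.094)
  expect_identical(p$V_SS, 0.05468)
  expect_identical(p$F, 96.4867)
  expect_true(all(unlist(p) > 0))
})

test_that("ryanodine-receptor open fraction vanishes without subspace calcium", {
  out <- ryrUpdate(rbar = 0.7, cass = 0, casr = 3, dt = 0.02)
  expect_identical(out$O, 0)
  expect_identical(out$Irel, 0)
})

test_that("ryanodine receptor relaxes to its analytic steady state at clamped calcium", {
  cass <- 5e-4; casr <- 3
  kcasr <- p$maxsr - (p$maxsr - p$minsr) / (1 + (p$EC / casr)^2)
  k2 <- p$k2_prime * kcasr
  rinf <- p$k4 / (k2 * cass + p$k4)
  rbar <- 1
  for (i in 1:400000) rbar <- ryrUpdate(rbar, cass, casr, dt = 0.02)$rbar
  expect_equal(rbar, rinf, tolerance = 1e-6)
})

test_that("one explicit-Euler RyR step matches a reference integration", {
  skip_if_not_installed("deSolve")
  cass <- 3e-3; casr <- 2.5; dt <- 0.02
  kcasr <- p$maxsr - (p$maxsr - p$minsr) / (1 + (p$EC / casr)^2)
  k2 <- p$k2_prime * kcasr
  ref <- deSolve::lsoda(
    c(R = 1), times = c(0, dt),
    func = function(t, y, parms) list(-k2 * cass * y[1] + p$k4 * (1 - y[1])),
    rtol = 1e-12, atol = 1e-14)
  out <- ryrUpdate(1, cass, casr, dt)
  # explicit Euler local error is O(dt^2) with rate ~1e-3/ms
  expect_equal(out$rbar, unname(ref[2, "R"]), tolerance = 1e-8)
  expect_true(out$rbar >= 0 && out$rbar <= 1)
})

test_that("conductance scaling acts linearly on its own current only", {
  st <- epInitialState("protocol")
  st[["V"]] <- -20; st[["d"]] <- 0.5; st[["f"]] <- 0.7
  st[["m"]] <- 0.4; st[["h"]] <- 0.3; st[["j"]] <- 0.3
  base <- computeCurrents(st, conductanceScaling())
  half <- computeCurrents(st, conductanceScaling(CaL = 0.5))
  expect_equal(half[["ICaL"]], base[["ICaL"]] / 2)
  expect_equal(half[names(half) != "ICaL"], base[names(base) != "ICaL"])

  # exchanger and pump are never scaled
  allhalf <- computeCurrents(st, conductanceScaling() * 0.5)
  expect_equal(allhalf[["INaCa"]], base[["INaCa"]])
  expect_equal(allhalf[["INaK"]], base[["INaK"]])
  scaled <- c("INa", "ICaL", "Ito", "IKr", "IKs", "IK1", "IpK", "IpCa",
              "IbNa", "IbCa")
  expect_equal(allhalf[scaled], base[scaled] / 2)
})

test_that("the relaxed cell is electrically at rest", {
  # relax the quiescent state for 20 s without stimulus, then the net
  # membrane current must be negligible
  tr <- runPacedEP(conductanceScaling(), bcl = 20000, n_beats = 1,
                   config = epConfig(stim_amplitude = 0, bcl_ms = 20000),
                   init = epInitialState("rest"))
  cur <- computeCurrents(tr$final_state, conductanceScaling(),
                         cell_type = "endo")
  expect_lt(abs(sum(cur)), 0.01)          # |dV/dt| < 0.01 mV/ms
  expect_lt(max(abs(tr$V - tr$V[1])), 1)  # < 1 mV drift over the run
})

test_that("a depolarizing stimulus raises V and gates stay bounded", {
  st <- epInitialState("rest")
  st1 <- stepEP(st, i_stim = -52, dt = 0.02)
  expect_gt(st1[["V"]], st[["V"]])
  gates <- c("m", "h", "j", "d", "f", "f2", "fcass", "r", "s",
             "xr1", "xr2", "xs", "Rbar")
  st2 <- stepEP(st, i_stim = -52, dt = 0.02, n_steps = 50000L)
  expect_true(all(st2[gates] >= 0 & st2[gates] <= 1))
})

test_that("the R calcium-balance update reproduces the kernel step", {
  st <- epInitialState("protocol")
  st[["V"]] <- 10; st[["d"]] <- 0.6; st[["f"]] <- 0.5
  st[["CaSS"]] <- 2e-3; st[["CaSR"]] <- 2.0; st[["Cai"]] <- 5e-4
  upd <- updateCalcium(st, dt = 0.02, cell_type = "endo")
  st1 <- stepEP(st, dt = 0.02, cell_type = "endo")
  expect_equal(upd$Cai, st1[["Cai"]], tolerance = 1e-12)
  expect_equal(upd$CaSR, st1[["CaSR"]], tolerance = 1e-12)
  expect_equal(upd$CaSS, st1[["CaSS"]], tolerance = 1e-12)
})

test_that("SR calcium is stationary when uptake balances leak and release is shut", {
  st <- epInitialState("protocol")
  cai <- 2e-4
  iup <- p$Vmaxup / (1 + p$Kup^2 / cai^2)
  st[["Cai"]] <- cai
  st[["CaSR"]] <- cai + iup / p$Vleak   # Ileak == Iup
  st[["CaSS"]] <- 0                      # O = 0, no release
  upd <- updateCalcium(st, dt = 0.02, cell_type = "endo")
  expect_equal(upd$CaSR, st[["CaSR"]], tolerance = 1e-15)
})

test_that("paced traces are deterministic and cover exactly one cycle", {
  cfg <- epConfig(bcl_ms = 600)
  a <- runPacedEP(conductanceScaling(), bcl = 600, n_beats = 3, config = cfg)
  b <- runPacedEP(conductanceScaling(), bcl = 600, n_beats = 3, config = cfg)
  expect_identical(a$V, b$V)
  expect_identical(a$Cai, b$Cai)
  expect_length(a$V, 600L)                 # samples x dt == BCL
  expect_true(all(is.finite(a$V)), all(is.finite(a$Cai)))

  # first beat of an n=1 and an n=2 run agree sample for sample
  c2 <- runPacedEP(conductanceScaling(), bcl = 600, n_beats = 1,
                   config = cfg)
  expect_identical(a$time, c2$time)
})

test_that("halving the time step moves APD90 by less than a millisecond", {
  cfg1 <- epConfig(bcl_ms = 600, dt_ms = 0.02)
  cfg2 <- epConfig(bcl_ms = 600, dt_ms = 0.01)
  a <- apd90(runPacedEP(conductanceScaling(), bcl = 600, n_beats = 5,
                        config = cfg1))
  b <- apd90(runPacedEP(conductanceScaling(), bcl = 600, n_beats = 5,
                        config = cfg2))
  expect_lt(abs(a - b), 1)
})

test_that("trace export writes the documented column layout", {
  tr <- runPacedEP(conductanceScaling(), bcl = 600, n_beats = 1,
                   config = epConfig(bcl_ms = 600))
  f <- tempfile(fileext = ".csv")
  exportTrace(tr, f)
  df <- read.csv(f)
  expect_identical(names(df), c("time_ms", "V_mV", "Cai_mM"))
  expect_equal(nrow(df), 600L)
  unlink(f)
})
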