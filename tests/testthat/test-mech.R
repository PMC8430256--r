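mp <- mechParameters()

test_that("printed regulatory constants are exposed unchanged", {
  expect_identical(mp$perm50, 0.5)
  expect_identical(mp$nperm, 15)
  expect_identical(mp$Qknp, 1.6)
  expect_identical(mp$Qkpn, 1.6)
  expect_true(mp$SL0 >= 1.4 && mp$SL0 <= 2.4)
})

test_that("troponin sites stay empty without calcium and reach the analytic steady state", {
  out <- troponinUpdate(0, 0, cai = 0, dt = 0.01)
  expect_identical(out$caTropH, 0)
  expect_identical(out$caTropL, 0)

  ca <- 1.5  # uM
  h <- 0; l <- 0
  for (i in 1:200000) {
    st <- troponinUpdate(h, l, ca, dt = 0.01)
    h <- st$caTropH; l <- st$caTropL
  }
  expect_equal(h, mp$kon * ca / (mp$kon * ca + mp$koffH), tolerance = 1e-6)
  expect_equal(l, mp$kon * ca / (mp$kon * ca + mp$koffL), tolerance = 1e-6)
})

test_that("one troponin Euler step matches a reference integration", {
  skip_if_not_installed("deSolve")
  ca <- 0.8; dt <- 0.002
  ref <- deSolve::lsoda(
    c(H = 0.3, L = 0.1), times = c(0, dt),
    func = function(t, y, parms) list(c(
      mp$kon * ca * (1 - y[1]) - mp$koffH * y[1],
      mp$kon * ca * (1 - y[2]) - mp$koffL * y[2])),
    rtol = 1e-12, atol = 1e-14)
  out <- troponinUpdate(0.3, 0.1, ca, dt = dt)
  expect_equal(out$caTropH, unname(ref[2, "H"]), tolerance = 1e-6)
  expect_equal(out$caTropL, unname(ref[2, "L"]), tolerance = 1e-6)
})

test_that("regulatory rates follow the permissiveness function", {
  # Trop_Regulatory == perm50 makes permtot = sqrt(1/2)
  sv <- cardioEMD:::sovfThin(1.9, mp)
  trop <- mp$perm50                # choose both sites at perm50
  rr <- regulatoryRates(1.9, trop, trop)
  expect_equal(rr$trop_regulatory, mp$perm50)
  expect_equal(rr$permtot, sqrt(1 / 2), tolerance = 1e-12)

  # empty troponin engages the capped inverse exactly
  rr0 <- regulatoryRates(1.9, 0, 0)
  expect_identical(rr0$inverse_permtot, 100)

  # at 37 C the temperature factors are exactly 1
  expect_equal(rr$knpT, mp$knp * rr$permtot)
  expect_equal(rr$kpnT, mp$kpn * rr$inverse_permtot)
})

test_that("occupancy pools are conserved by the crossbridge update", {
  st <- list(NNoXB = 0.9, PNoXB = 0.1, NXB = 0.6, PXB = 0.25,
             XBprer = 0.1, XBpostr = 0.05)
  # zero rates leave the state untouched
  z <- list(knpT = 0, kpnT = 0, fappT = 0, gappT = 0, hfT = 0, hbT = 0,
            gxbT = 0)
  expect_identical(xbCycleUpdate(st, z, dt = 0.01), st)

  set.seed(42)
  for (i in 1:100) {
    r <- as.list(setNames(runif(7, 0, 2),
                          c("knpT", "kpnT", "fappT", "gappT", "hfT",
                            "hbT", "gxbT")))
    o <- runif(4); o <- o / sum(o)
    s <- list(NNoXB = runif(1), PNoXB = runif(1), NXB = o[1], PXB = o[2],
              XBprer = o[3], XBpostr = o[4])
    s2 <- xbCycleUpdate(s, r, dt = 0.005)
    expect_equal(s2$NNoXB + s2$PNoXB, s$NNoXB + s$PNoXB, tolerance = 1e-12)
    expect_equal(s2$NXB + s2$PXB + s2$XBprer + s2$XBpostr, 1,
                 tolerance = 1e-12)
  }
})

test_that("one crossbridge step matches the matrix-exponential propagator", {
  skip_if_not_installed("Matrix")
  r <- list(knpT = 0.3, kpnT = 0.8, fappT = 0.5, gappT = 0.15, hfT = 2,
            hbT = 0.4, gxbT = 0.07)
  A <- rbind(c(-r$knpT, r$kpnT, 0, 0),
             c(r$knpT, -(r$kpnT + r$fappT), r$gappT, r$gxbT),
             c(0, r$fappT, -(r$gappT + r$hfT), r$hbT),
             c(0, 0, r$hfT, -(r$hbT + r$gxbT)))
  x0 <- c(0.7, 0.2, 0.06, 0.04)
  dt <- 0.002
  xref <- as.numeric(Matrix::expm(A * dt) %*% x0)
  st <- list(NNoXB = 1, PNoXB = 0, NXB = x0[1], PXB = x0[2],
             XBprer = x0[3], XBpostr = x0[4])
  s2 <- xbCycleUpdate(st, r, dt = dt)
  expect_equal(c(s2$NXB, s2$PXB, s2$XBprer, s2$XBpostr), xref,
               tolerance = 1e-5)
})

test_that("strong activation drives occupancies to the duty-fraction limit", {
  r <- list(knpT = 10, kpnT = 1e-8, fappT = 0.5, gappT = 0.07, hfT = 2,
            hbT = 0.4, gxbT = 0.07)
  duty <- dutyFractions(r)
  st <- list(NNoXB = 1, PNoXB = 0, NXB = 1, PXB = 0, XBprer = 0,
             XBpostr = 0)
  for (i in 1:50000) st <- xbCycleUpdate(st, r, dt = 0.002)
  expect_equal(st$XBprer, duty$prer, tolerance = 1e-3)
  expect_equal(st$XBpostr, duty$postr, tolerance = 1e-3)
})

test_that("distortion dynamics respect their fixed point and pure advection", {
  r <- list(knpT = 0.3, kpnT = 0.8, fappT = 0.5, gappT = 0.15, hfT = 2,
            hbT = 0.4, gxbT = 0.07)
  fx <- distortionUpdate(0, mp$x0, dSLdt = 0, rates = r, dt = 0.01)
  expect_equal(fx$xXBprer, 0)
  expect_equal(fx$xXBpostr, mp$x0)

  z <- list(knpT = 0, kpnT = 0, fappT = 0, gappT = 0, hfT = 0, hbT = 0,
            gxbT = 0)
  adv <- distortionUpdate(0.001, 0.004, dSLdt = -0.02, rates = z,
                          dt = 0.01)
  expect_equal(adv$xXBprer, 0.001 + 0.5 * -0.02 * 0.01)
  expect_equal(adv$xXBpostr, 0.004 + 0.5 * -0.02 * 0.01)
})

test_that("the force balance follows its printed algebra", {
  st <- list(XBprer = 0, XBpostr = 0, xXBprer = 0, xXBpostr = mp$x0,
             SL = 1.9, Intf = 0)
  expect_identical(totalForce(st)$F_active, 0)

  st2 <- list(XBprer = 0.1, XBpostr = 0.3, xXBprer = 0.002,
              xXBpostr = 0.008, SL = 1.9, Intf = 0)
  f <- totalForce(st2)
  xbmax <- mp$fapp * mp$hf /
    (mp$gxb * mp$hf + mp$fapp * mp$hf + mp$gapp * mp$hb +
       mp$gapp * mp$gxb + mp$fapp * mp$hb + mp$fapp * mp$gxb)
  expect_equal(f$F_active,
               cardioEMD:::sovfThick(1.9, mp) *
                 (0.002 * 0.1 + 0.008 * 0.3) / (mp$x0 * xbmax))
  # at SL == SL0 the afterload and net passive force cancel
  expect_identical(f$F_afterload, 0)
  expect_equal(f$F_integrand, f$F_active)

  # resting balance: no force integral, no length change
  st3 <- list(XBprer = 0, XBpostr = 0, xXBprer = 0, xXBpostr = mp$x0,
              SL = mp$SL0, Intf = 0)
  expect_equal(stepSL(st3, dt = 0.002)$SL, mp$SL0)
})

test_that("a calcium-free beat produces no force and no shortening", {
  flat <- list(time = seq(0, 599), Cai = rep(0, 600))
  tw <- runTwitch(flat)
  expect_lt(max(tw$tension_norm), 1e-6)
  expect_true(all(tw$length_norm > 0.999))
})

test_that("a resting-calcium beat keeps the cell within 0.1% of its length", {
  rest <- list(time = seq(0, 599), Cai = rep(1e-4, 600))
  tw <- runTwitch(rest)
  expect_true(all(abs(tw$length_norm - 1) < 1e-3))
})

test_that("peak tension grows with the calcium transient", {
  base <- syntheticCai()
  peaks <- sapply(c(0.5, 1, 2), function(f) {
    tw <- runTwitch(list(time = base$time, Cai = base$Cai * f))
    max(tw$tension_norm)
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("the kPa scale only relabels tension", {
  ca <- syntheticCai()
  t1 <- runTwitch(ca, params = mechParameters(Tmax = 300))
  t2 <- runTwitch(ca, params = mechParameters(Tmax = 600))
  expect_equal(t1$tension_norm, t2$tension_norm)
  expect_equal(t1$length_norm, t2$length_norm)
  expect_equal(t2$tension_kPa, 2 * t1$tension_kPa)
})

test_that("twitches are deterministic, conservative and step-size converged", {
  ca <- syntheticCai()
  a <- runTwitch(ca)
  b <- runTwitch(ca)
  expect_identical(a$tension_kPa, b$tension_kPa)
  expect_identical(a$length_norm, b$length_norm)
  expect_equal(a$length_norm[1], 1)

  fs <- a$final_state
  expect_equal(fs[["NNoXB"]] + fs[["PNoXB"]], 1, tolerance = 1e-8)
  expect_equal(fs[["NXB"]] + fs[["PXB"]] + fs[["XBprer"]] +
                 fs[["XBpostr"]], 1, tolerance = 1e-8)

  h <- runTwitch(ca, params = mechParameters(mech_dt_ms = 0.001))
  expect_equal(max(h$tension_norm), max(a$tension_norm),
               tolerance = 1e-3)
  expect_equal(min(h$length_norm), min(a$length_norm), tolerance = 1e-3)
})

test_that("composed R operations track the compiled kernel at rest", {
  pp <- mechParameters()
  ca <- 0.4  # uM, constant
  cs <- cardioEMD:::.rice_step(cardioEMD:::.rice_initial_state(pp),
                               ca, pp, 0.002, 500L)
  rs <- as.list(cardioEMD:::.rice_initial_state(pp))
  for (i in 1:500) {
    tr <- troponinUpdate(rs$TRPNCaH, rs$TRPNCaL, ca, pp, dt = 0.002)
    rr <- regulatoryRates(rs$SL, rs$TRPNCaH, rs$TRPNCaL, pp)
    xr <- cardioEMD:::xbRates(rs, pp)
    rs2 <- xbCycleUpdate(rs, c(rr, xr), dt = 0.002)
    dx <- distortionUpdate(rs$xXBprer, rs$xXBpostr, rs$dSLdt %||% 0,
                           xr, pp, dt = 0.002)
    rs2$xXBprer <- dx$xXBprer; rs2$xXBpostr <- dx$xXBpostr
    rs2$TRPNCaH <- tr$caTropH; rs2$TRPNCaL <- tr$caTropL
    rs2$SL <- rs$SL; rs2$Intf <- rs$Intf
    rs2 <- stepSL(rs2, pp, dt = 0.002)
    rs <- rs2
  }
  for (nm in c("TRPNCaH", "TRPNCaL", "NXB", "PXB", "XBprer", "XBpostr"))
    expect_equal(rs[[nm]], cs[[nm]], tolerance = 1e-6, label = nm)
})

test_that("twitch export writes the documented column layout", {
  tw <- runTwitch(syntheticCai())
  f <- tempfile(fileext = ".csv")
  exportTwitch(tw, f)
  df <- read.csv(f)
  expect_identical(names(df), c("time_ms", "tension_norm", "tension_kPa",
                                "length_norm"))
  unlink(f)
})
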