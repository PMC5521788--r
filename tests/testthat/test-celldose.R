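test_that("cellular S-value table loads with OOR sentinels as NA", {
  sv <- cell_s_values_6um()
  expect_s3_class(sv, "cell_s_table")
  expect_true(all(sv$s_self >= sv$s_surface))
  expect_true(is.na(sv$s_cross_100um[sv$nuclide == "Po-213"]))
  expect_equal(attr(sv, "cross_distances_um"), c(50, 100))
  expect_equal(attr(sv, "cell_radius_um"), 6)

  tmp <- tempfile(fileext = ".csv")
  writeLines(c("nuclide,s_self,s_surface",
               "X,0.2,0.5"), tmp)
  expect_error(read_cell_s_values(tmp), "self-dose")
})

test_that("branching-weighted combined S reproduces the parent+progeny rows", {
  sv <- cell_s_values_6um()
  ch <- bi213_chain()
  s_self <- combine_chain_s(sv, ch, "self")
  s_surf <- combine_chain_s(sv, ch, "surface")
  # independent arithmetic from the per-nuclide columns
  expect_equal(s_self, 1.71 + 0.9784 * 49.2 + 0.0216 * 0.73 + 0.34,
               tolerance = 1e-12)
  expect_equal(s_surf, 1.14 + 0.9784 * 33.0 + 0.0216 * 0.44 + 0.22,
               tolerance = 1e-12)
  # printed combined entries, at their printed precision
  expect_equal(s_self, 50.2, tolerance = 0.05 / 50.2)
  expect_equal(s_surf, 33.6, tolerance = 0.06 / 33.6)
  # identity for a single-member chain
  lu <- lu177_chain()
  expect_equal(combine_chain_s(sv, lu, "self"), 0.67)
  expect_equal(combine_chain_s(sv, lu, "surface"), 0.42)
  expect_error(combine_chain_s(sv[sv$nuclide != "Pb-209", ], ch, "self"),
               "Pb-209")
})

test_that("combine_chain_s is linear in each member S-value", {
  sv <- cell_s_values_6um()
  ch <- bi213_chain()
  base <- combine_chain_s(sv, ch, "self")
  sv2 <- sv
  sv2$s_self[sv2$nuclide == "Po-213"] <- sv2$s_self[sv2$nuclide == "Po-213"] + 1
  expect_equal(combine_chain_s(sv2, ch, "self"), base + 0.9784,
               tolerance = 1e-12)
})

test_that("cell mean dose follows the f_int/f_mem partition of bound activity", {
  sv <- cell_s_values_6um()
  ch <- bi213_chain()
  # no binding -> no dose
  d0 <- cell_mean_dose(0, ch, f_int = 0, f_mem = 0, svals = sv)
  expect_equal(d0$total_Gy, 0)
  # invalid partitions rejected
  expect_error(cell_mean_dose(1e-8, ch, f_int = 0.5, f_mem = 0.2, svals = sv),
               "f_int")
  expect_error(cell_mean_dose(1e-8, ch, f_int = -0.1, f_mem = 1.1, svals = sv),
               "non-negative")
  expect_error(
    cell_mean_dose(1e-8, ch, svals = sv, window = c(7200, 3600)), "t1")

  # with S_self = S_surface the split is irrelevant
  sv_eq <- sv
  sv_eq$s_surface <- sv_eq$s_self
  da <- cell_mean_dose(1e-8, ch, f_int = 1, f_mem = 0, svals = sv_eq)
  db <- cell_mean_dose(1e-8, ch, f_int = 0, f_mem = 1, svals = sv_eq)
  expect_equal(da$total_Gy, db$total_Gy, tolerance = 1e-12)
})

test_that("cell mean dose matches the ODE-validated cumulated activities", {
  sv <- cell_s_values_6um()
  ch <- bi213_chain()
  A_cell <- 1e-8  # MBq bound per cell at T0 = 1 h
  window <- c(3600, 12 * 86400)
  d <- cell_mean_dose(A_cell, ch, f_int = 0, f_mem = 1, svals = sv,
                      window = window)
  lam <- ch$nuclides[["Bi-213"]]$lambda
  oracle_ca <- ode_cumulated_activity(A_cell * exp(lam * window[1]), ch,
                                      window[1], window[2])
  s_surf <- stats::setNames(sv$s_surface, sv$nuclide)
  expected <- sum(oracle_ca * s_surf[names(oracle_ca)]) * 1e-3
  expect_equal(d$total_Gy, expected, tolerance = 1e-6)
  # the parent's own cumulated activity over the (effectively infinite)
  # window is A_cell/lambda
  expect_equal(d$cumulated$per_nuclide[["Bi-213"]], A_cell / lam,
               tolerance = 1e-6)
})

test_that("the 12 d window is effectively infinite for Bi-213 but not Lu-177", {
  sv <- cell_s_values_6um()
  ch <- bi213_chain()
  d12 <- cell_mean_dose(1e-8, ch, svals = sv,
                        window = c(3600, 12 * 86400))
  d120 <- cell_mean_dose(1e-8, ch, svals = sv,
                         window = c(3600, 120 * 86400))
  expect_equal(d12$total_Gy, d120$total_Gy, tolerance = 1e-4)

  lu <- lu177_chain()
  l12 <- cell_mean_dose(1e-8, lu, svals = sv,
                        window = c(3600, 12 * 86400))
  l120 <- cell_mean_dose(1e-8, lu, svals = sv,
                         window = c(3600, 120 * 86400))
  lam <- lu$nuclides[["Lu-177"]]$lambda
  T1 <- 12 * 86400 - 3600
  T2 <- 120 * 86400 - 3600
  ratio <- (1 - exp(-lam * T2)) / (1 - exp(-lam * T1))
  expect_equal(l120$total_Gy / l12$total_Gy, ratio, tolerance = 1e-9)
})

test_that("dose per unit parent cumulated activity equals the combined S", {
  # over a complete-decay window every member's decay count is its
  # branching fraction times the parent's, so the f_mem = 1 dose per
  # MBq.s of parent decays is the combined surface S-value (in mGy)
  sv <- cell_s_values_6um()
  ch <- bi213_chain()
  d <- cell_mean_dose(1e-6, ch, f_int = 0, f_mem = 1, svals = sv,
                      window = c(0, Inf))
  atilde_parent <- d$cumulated$per_nuclide[["Bi-213"]]
  expect_equal(d$total_Gy * 1e3 / atilde_parent,
               combine_chain_s(sv, ch, "surface"), tolerance = 1e-6)
})

test_that("cross-dose bound uses tabulated distances and flags out-of-range", {
  sv <- cell_s_values_6um()
  far <- cross_dose_bound(sv, "Bi-213", 2000, 1)
  expect_equal(far$dose_Gy, 0)
  expect_true(far$out_of_range)
  none <- cross_dose_bound(sv, "Bi-213", 100, 0)
  expect_equal(none$dose_Gy, 0)
  expect_false(none$out_of_range)
  lu <- cross_dose_bound(sv, "Lu-177", 100, 1)
  expect_equal(lu$dose_Gy, 4.18e-4 * 1e-3, tolerance = 1e-12)
  # Po-213 at 100 um is beyond the alpha range (OOR in the table)
  po <- cross_dose_bound(sv, "Po-213", 100, 1)
  expect_equal(po$dose_Gy, 0)
  expect_true(po$out_of_range)
  # untabulated intermediate distance falls back to the nearest smaller
  mid <- cross_dose_bound(sv, "Lu-177", 70, 1)
  expect_equal(mid$dose_Gy, 2.00e-3 * 1e-3, tolerance = 1e-12)
  expect_error(cross_dose_bound(sv, "Nope", 50, 1), "unknown")
})
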