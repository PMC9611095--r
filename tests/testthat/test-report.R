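make_study <- function(a_ex = 5, pi_s = 20, noise = 0, seed = 1,
                       component2 = fix_p2, fractions = fix_fractions) {
  cfg <- study_config(component1 = fix_p1, component2 = component2,
                      fractions = fractions,
                      excess = excess_params(a_ex, pi_s),
                      noise_sigma = noise, seed = seed)
  generate_study_isotherms(cfg)
}

test_that("composition profiles: shape, ideality, unattained flags", {
  isos <- make_study(a_ex = 0)
  profs <- composition_profile(isos, c(10, 20, 30))
  expect_length(profs, 3L)
  for (pr in profs) {
    expect_equal(nrow(pr), 10L)           # 2 pure + 8 mixtures
    expect_equal(pr$x2[c(1, 10)], c(0, 1)) # endpoints present, sorted
    expect_false(is.unsorted(pr$x2))
    # ideal study: measured areas sit on the additivity line
    attained <- pr$flags == ""
    expect_lt(max(abs(pr$a12_A2[attained] - pr$a_ideal_A2[attained])), 0.05)
  }
  # the non-spreading pure component is flagged, not dropped
  expect_identical(profs[["10"]]$flags[10], "unattained")
  expect_identical(profs[["10"]]$a12_A2[10], 0)

  # a low-collapse component 2 attains 10 but not 30 mN/m
  isos2 <- make_study(a_ex = 5, component2 = eos_low_collapse(8))
  profs2 <- composition_profile(isos2, c(5, 30))
  expect_identical(profs2[["5"]]$flags[10], "")
  expect_identical(profs2[["30"]]$flags[10], "unattained")
})

test_that("study sets are validated and order-invariant", {
  isos <- make_study()
  expect_error(composition_profile(isos[-1]), "pure component 1")
  expect_error(composition_profile(isos[-2]), "pure component 2")
  expect_error(composition_profile(isos[1:2]), "at least one mixture")
  shuffled <- isos[c(5, 1, 9, 2, 3, 8, 4, 10, 7, 6)]
  expect_equal(as.data.frame(composition_profile(shuffled)[["10"]]),
               as.data.frame(composition_profile(isos)[["10"]]))
  expect_equal(as.data.frame(excess_profile_table(shuffled)),
               as.data.frame(excess_profile_table(isos)))
})

test_that("excess table: ordering, endpoint zeros, symmetric maximum", {
  isos <- make_study(a_ex = 5, pi_s = 20)
  tab <- excess_profile_table(isos, c(10, 20, 30))
  expect_equal(nrow(tab), 10L * 3L)
  expect_false(is.unsorted(tab$x2))
  # endpoints are exact zeros by definition
  ends <- tab$x2 %in% c(0, 1)
  expect_identical(unique(tab$a_excess_A2[ends]), 0)
  expect_identical(unique(tab$dg_excess_J_mol[ends]), 0)
  # symmetric repulsive study: dG_ex maximal at x2 = 0.5 at every pressure
  for (p in c(10, 20, 30)) {
    sub <- tab[tab$pressure_mN_per_m == p & tab$x2 > 0 & tab$x2 < 1, ]
    expect_equal(sub$x2[which.max(sub$dg_excess_J_mol)], 0.5)
  }
  # finite pi_s: dG_ex grows with pi*, A_ex decays with pi*
  for (x in fix_fractions) {
    sub <- tab[tab$x2 == x, ]
    sub <- sub[order(sub$pressure_mN_per_m), ]
    expect_true(all(diff(sub$dg_excess_J_mol) > 0))
    expect_true(all(diff(abs(sub$a_excess_A2)) < 0))
  }
})

test_that("find_extrema reports interior extrema with prominence gating", {
  # curves are indexed over the full composition domain, pure endpoints
  # included (excess quantities are pinned to 0 there), as the pipeline
  # supplies them
  x <- c(0, fix_fractions, 1)
  # single maximum of the symmetric envelope at x2 = 0.5
  e1 <- find_extrema(x, 4 * x * (1 - x), min_prominence = 0.1)
  expect_equal(nrow(e1), 1L)
  expect_identical(e1$type, "maximum")
  expect_equal(e1$x2, 0.5)
  # constructed bimodal pattern: two maxima separated by a minimum
  y <- c(0, 0.2, 0.8, 1.6, 2.0, 1.2, 0.6, 2.4, 1.8, 0)
  e2 <- find_extrema(x, y, min_prominence = 0.5)
  expect_identical(e2$type, c("maximum", "minimum", "maximum"))
  expect_equal(e2$x2, c(0.06, 0.12, 0.25))
  # monotone curve: nothing beyond the boundary, so nothing to report
  expect_equal(nrow(find_extrema(x, seq_along(x), min_prominence = 0)), 0L)
  # invariance under joint scaling of values and prominence
  e3 <- find_extrema(x, 100 * y, min_prominence = 50)
  expect_equal(e3$x2, e2$x2)
  expect_identical(e3$type, e2$type)
})

test_that("miscibility verdicts follow the decision table", {
  # ideal study
  tab0 <- excess_profile_table(make_study(a_ex = 0))
  v0 <- assess_miscibility(tab0, tol = 0.5)
  expect_identical(v0$verdict, "ideal-or-immiscible")
  expect_true(all(v0$signs == "none"))
  # repulsive study with a single symmetric maximum
  vp <- assess_miscibility(excess_profile_table(make_study(a_ex = 5)))
  expect_identical(vp$verdict, "miscible-repulsive")
  # attractive study
  vn <- assess_miscibility(excess_profile_table(make_study(a_ex = -5)))
  expect_identical(vn$verdict, "miscible-attractive")
  # bimodal excess-area pattern: partial miscibility
  bi <- data.frame(
    x2 = rep(c(0, 0.06, 0.12, 0.25, 0.5, 1), each = 1),
    pressure_mN_per_m = 10,
    a_excess_A2 = c(0, 2.5, 0.4, 2.8, 0.3, 0))
  expect_identical(assess_miscibility(bi, tol = 0.3)$verdict,
                   "partially-miscible")
  # too few fractions
  expect_error(assess_miscibility(bi[c(1, 2, 6), ]), "at least 3")
})

test_that("ideal verdict is stable under instrument noise", {
  # scaled-down version of the 100-seed stability property (full sweep in
  # the acceptance suite): 20 seeds here
  ok <- vapply(1:20, function(s) {
    tab <- excess_profile_table(make_study(a_ex = 0, noise = 0.1,
                                           seed = 7 * s))
    assess_miscibility(tab, tol = 0.5)$verdict == "ideal-or-immiscible"
  }, logical(1L))
  expect_gte(sum(ok), 19L)
})

test_that("study directories round-trip through load_study", {
  cfg <- study_config(fractions = c(0.1, 0.25, 0.5), noise_sigma = 0,
                      grid = pressure_grid(step = 0.5), seed = 2)
  dir <- tempfile()
  generate_study_dataset(cfg, dir)
  isos <- load_study(dir)
  expect_length(isos, 5L) # ground_truth.csv skipped
  x2 <- vapply(isos, function(i) i$meta$molar_fraction_x2, numeric(1L))
  expect_equal(unname(sort(x2)), c(0, 0.1, 0.25, 0.5, 1))
})
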