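# direct-arithmetic oracle used throughout: b(r) = K / r^3 with CODATA
# constants evaluated independently of the package's helper
oracle_b <- function(r_pm) {
  K <- -1.25663706212e-6 * 1.054571817e-34 * 2.6752218744e8^2 / (8 * pi^2)
  K / (r_pm * 1e-12)^3
}

test_that("dipolar prefactor and coupling match the direct evaluation", {
  K <- hh_constants()$K_HH
  expect_lt(K, 0)
  expect_lt(abs(abs(K) * (2e-10)^-3 - 1.50e4) / 1.50e4, 0.02)
  expect_equal(dipolar_coupling(200), oracle_b(200), tolerance = 1e-12)
  # cube law
  r <- c(137, 200, 411)
  expect_equal(dipolar_coupling(2 * r), dipolar_coupling(r) / 8)
  expect_equal(abs(dipolar_coupling(10 * 250)),
               abs(dipolar_coupling(250)) / 1000)
  expect_error(dipolar_coupling(0), "positive")
  expect_error(dipolar_coupling(-5), "positive")
})

fake_pair <- function(d, equivalent = TRUE, n_j = 3,
                      motion_j = "static", motion_k = motion_j) {
  structure(list(j = "A", k = if (equivalent) "A" else "B",
                 equivalent = equivalent, distances = d,
                 detail = NULL, n_j = n_j, n_k = n_j,
                 motion_j = motion_j, motion_k = motion_k,
                 cutoff_pm = 1000),
            class = "site_pair_distances")
}

test_that("effective coupling sums, with methyl three-site-jump scaling", {
  # equivalent pair, three equal distances, static
  p <- fake_pair(rep(180, 3))
  expect_equal(as.numeric(effective_coupling_squared(p)),
               3 * oracle_b(180)^2)
  # fast three-site jump: exactly 1/4 of the static value
  expect_equal(as.numeric(effective_coupling_squared(p, motion_j = "fast_3site")),
               0.75 * oracle_b(180)^2)
  # non-equivalent pair: plain sum, no scaling even if one side rotates
  q <- fake_pair(c(200, 300), equivalent = FALSE)
  expect_equal(as.numeric(effective_coupling_squared(q)),
               oracle_b(200)^2 + oracle_b(300)^2)
  expect_equal(as.numeric(effective_coupling_squared(q, motion_j = "fast_3site")),
               oracle_b(200)^2 + oracle_b(300)^2)
  # config error: fast_3site needs 3 members
  p2 <- fake_pair(rep(180, 3), n_j = 2)
  expect_error(effective_coupling_squared(p2, motion_j = "fast_3site"),
               "3-member")
})

test_that("multiplicity counts near-degenerate shortest distances", {
  expect_equal(multiplicity(c(176, 178, 179)), 3)
  expect_equal(multiplicity(200), 1)
  expect_equal(multiplicity(c(200, 300)), 1)
  expect_equal(multiplicity(c(200, 219, 221)), 2)
  expect_equal(multiplicity(c(200, 300), rel_tol = 0.6), 2)
})

test_that("effective distance: identity, methyl aggregate, two-term case", {
  expect_equal(effective_distance(M = 1, distances = 250), 250)
  r_me <- effective_distance(M = 3, distances = c(176, 178, 179))
  expect_gte(r_me, 177); expect_lte(r_me, 178)
  expect_equal(r_me, (3 / sum(c(176, 178, 179)^-6))^(1 / 6))
  expect_equal(effective_distance(M = 1, distances = c(200, 300)),
               200 * (1 + (2 / 3)^6)^(-1 / 6))
  # Hz^2 route agrees with the distance route
  b2 <- 3 * oracle_b(177)^2
  expect_equal(effective_distance(b_eff_sq = b2, M = 3), 177,
               tolerance = 1e-9)
  expect_error(effective_distance(b_eff_sq = 0, M = 1), "positive")
  # a term at 3x the minimum shifts r_eff by < 0.05%
  r0 <- effective_distance(M = 1, distances = 220)
  r1 <- effective_distance(M = 1, distances = c(220, 660))
  expect_lt(abs(r1 - r0) / r0, 5e-4)
})

test_that("pair table r_eff stays near the shortest distance", {
  for (seed in c(3, 7)) {
    tc <- toy_network(n = 4, seed = seed)
    tab <- pair_coupling_table(tc$structure, tc$groups)
    expect_true(all(tab$b_eff_sq >= 0))
    expect_true(all(tab$M >= 1 & tab$M <= tab$n_terms))
    expect_true(all(tab$r_eff_pm >= 0.90 * tab$r_min_pm))
  }
})

test_that("model fractions: normalization, merging, exclusion", {
  mk_tab <- function(b2) {
    tab <- data.frame(pair = paste0("p", seq_along(b2)),
                      j = "x", k = "y", b_eff_sq = b2, M = 1,
                      r_eff_pm = 200, r_min_pm = 200,
                      n_terms = 1, motion_applied = "static")
    class(tab) <- c("pair_coupling_table", class(tab))
    tab
  }
  expect_equal(model_fractions(mk_tab(5))$f, 1)
  expect_equal(model_fractions(mk_tab(c(2, 2)))$f, c(0.5, 0.5))
  # exclusion with renormalization: excluded reported on the retained scale
  fm <- model_fractions(mk_tab(c(1, 1, 2)), exclude = "p3")
  expect_equal(fm$f[!fm$excluded], c(0.5, 0.5))
  expect_equal(fm$f[fm$excluded], 1.0)
  expect_error(model_fractions(mk_tab(2), exclude = "p1"), "excluded")
  # merging sums weights before normalization
  fm2 <- model_fractions(mk_tab(c(1, 1, 2)),
                         grouping = list(m = c("p1", "p2")))
  expect_equal(sort(fm2$f), c(0.5, 0.5))
  # merge associativity
  tab <- mk_tab(c(1, 2, 3, 4))
  fa <- model_fractions(tab, grouping = list(ab = c("p1", "p2"),
                                             abc = c("p3", "p4")))
  g1 <- model_fractions(tab, grouping = list(all = c("p1", "p2", "p3")))
  g2 <- model_fractions(tab, grouping = list(all = c("p2", "p3", "p1")))
  expect_equal(g1$f[g1$id == "all"], g2$f[g2$id == "all"])
  expect_equal(sum(fa$f), 1)
})

test_that("kappa cancellation: uniform coupling scaling leaves fractions fixed", {
  tc <- toy_network(n = 5, seed = 11)
  tab <- pair_coupling_table(tc$structure, tc$groups)
  tab2 <- tab
  tab2$b_eff_sq <- tab2$b_eff_sq * 0.33^2
  expect_equal(model_fractions(tab)$f, model_fractions(tab2)$f,
               tolerance = 1e-12)
})

test_that("toggling fast_3site leaves external pairs unchanged", {
  toy <- toy_methyl_amide()
  tab_static <- pair_coupling_table(toy$structure, toy$groups)
  g2 <- toy$groups
  g2[[1]] <- proton_site_group("CH3", g2[[1]]$members, motion = "fast_3site",
                               shift = g2[[1]]$shift)
  tab_fast <- pair_coupling_table(toy$structure, g2)
  ext <- tab_static$pair != "CH3:CH3"
  expect_equal(tab_fast$b_eff_sq[ext], tab_static$b_eff_sq[ext])
  expect_equal(tab_fast$b_eff_sq[!ext], tab_static$b_eff_sq[!ext] / 4)
})

test_that("cutoff convergence diagnostic reports small tail changes", {
  toy <- toy_methyl_amide()
  conv <- cutoff_convergence(toy$structure, toy$groups)
  expect_true(all(conv$rel_change >= 0 & conv$rel_change < 0.01))
})
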