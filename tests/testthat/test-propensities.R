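p_def <- rate_params()

test_that("an isolated naive site can only methylate or bind", {
  st <- lattice_state(1, FALSE)
  ev <- enumerate_propensities(st, p_def)
  expect_setequal(ev$kind, c("methylate", "bind"))
  expect_equal(sum(ev$propensity), p_def$k_m + p_def$k_b)
})

test_that("without methylation no methylation-dependent event is eligible", {
  p_tm <- rate_params(k_m = 0)
  st <- lattice_state(4, c(TRUE, TRUE, FALSE, FALSE),
                      hp1_bound = c(TRUE, FALSE, TRUE, FALSE))
  st <- add_contact(st, 1, 2)
  ev <- enumerate_propensities(st, p_tm)
  expect_false(any(ev$kind %in% c("methylate", "demethylate", "spread")))
  expect_false(any(ev$kind == "break_contact_slow"))
})

test_that("a doubly methylated+bound contact breaks slowly and suppresses unbinding", {
  st <- lattice_state(2, c(TRUE, TRUE), methylated = c(TRUE, TRUE),
                      hp1_bound = c(TRUE, TRUE))
  st <- add_contact(st, 1, 2)
  ev <- enumerate_propensities(st, p_def)
  brk <- ev[grepl("break", ev$kind), ]
  expect_equal(nrow(brk), 1L)
  expect_equal(brk$kind, "break_contact_slow")
  expect_equal(brk$propensity, p_def$k_w)
  expect_false(any(grepl("unbind", ev$kind)))  # both sites are in a contact
})

test_that("contact breaking uses the fast rate when either endpoint is incomplete", {
  for (meth in list(c(TRUE, FALSE), c(FALSE, FALSE))) {
    st <- lattice_state(2, c(TRUE, TRUE), methylated = meth,
                        hp1_bound = c(TRUE, TRUE))
    st <- add_contact(st, 1, 2)
    ev <- enumerate_propensities(st, p_def)
    expect_equal(ev$kind[grepl("break", ev$kind)], "break_contact_fast")
  }
})

test_that("contact formation respects the valence cap and existing contacts", {
  p2 <- rate_params(n_val = 2L)
  st <- lattice_state(4, rep(FALSE, 4))
  st <- add_contact(st, 1, 2, n_val = 2)
  st <- add_contact(st, 1, 3, n_val = 2)   # site 1 now at cap
  ev <- enumerate_propensities(st, p2)
  form <- ev[ev$kind == "form_contact", ]
  expect_false(any(form$i == 1 | form$j == 1))
  expect_false(any(form$i == 1 & form$j == 2))  # existing pair excluded
  expect_true(all(form$propensity > 0))
})

test_that("rule-7 propensities follow k_c / L^alpha under both kernels", {
  st <- lattice_state(12, rep(FALSE, 12))
  st <- add_contact(st, 1, 10)
  ev_s <- enumerate_propensities(st, rate_params())
  ev_g <- enumerate_propensities(st, rate_params(formation_distance = "genomic"))
  fs <- ev_s[ev_s$kind == "form_contact", ]
  fg <- ev_g[ev_g$kind == "form_contact", ]
  Ls <- effective_distance(fs$i, fs$j, st$contacts)
  expect_equal(fs$propensity, p_def$k_c / Ls^p_def$alpha)
  expect_equal(fg$propensity, p_def$k_c / (fg$j - fg$i)^p_def$alpha)
  # the shortcut kernel can only increase formation propensities
  expect_true(all(fs$propensity >= fg$propensity - 1e-12))
})

test_that("binding_only variant gates residence by methylation and never stabilises contacts", {
  p_bo <- rate_params(coupling_mode = "binding_only")
  st <- lattice_state(3, c(TRUE, FALSE, FALSE),
                      methylated = c(TRUE, TRUE, FALSE),
                      hp1_bound = c(TRUE, TRUE, TRUE))
  ev <- enumerate_propensities(st, p_bo)
  ub <- ev[grepl("unbind", ev$kind), ]
  # methylated sites 1,2 use k_u; unmethylated site 3 uses k_y,
  # irrespective of binding-site status
  expect_equal(ub$kind[ub$i %in% c(1, 2)], rep("unbind_site", 2))
  expect_equal(ub$kind[ub$i == 3], "unbind_nonsite")
  st2 <- lattice_state(2, c(TRUE, TRUE), methylated = c(TRUE, TRUE),
                       hp1_bound = c(TRUE, TRUE))
  st2 <- add_contact(st2, 1, 2)
  ev2 <- enumerate_propensities(st2, p_bo)
  expect_equal(ev2$kind[grepl("break", ev2$kind)], "break_contact_fast")
})

test_that("engine propensity bookkeeping matches the reference enumeration", {
  set.seed(123)
  for (t in 1:60) {
    n <- sample(3:25, 1)
    st <- random_state(n)
    params <- rate_params(
      formation_distance = sample(c("shortcut", "genomic"), 1),
      coupling_mode = sample(c("bridging", "binding_only"), 1))
    ev <- enumerate_propensities(st, params)
    ref <- tapply(ev$propensity, ev$kind, sum)
    eng <- engine_breakdown(st, params)
    for (kind in names(ref))
      expect_equal(unname(eng[[kind]]), unname(ref[[kind]]),
                   tolerance = 1e-12)
    expect_equal(unname(eng[["total"]]), sum(ev$propensity),
                 tolerance = 1e-12)
    absent <- setdiff(setdiff(names(eng), "total"), names(ref))
    expect_true(all(eng[absent] == 0))
  }
})

test_that("fibre spreading is off by default and adds only i±1 targets", {
  st <- lattice_state(5, rep(FALSE, 5), methylated = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                      hp1_bound = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  ev0 <- enumerate_propensities(st, p_def)
  expect_false(any(ev0$kind == "spread"))     # no contacts, no fibre mode
  ev1 <- enumerate_propensities(st, p_def, spread_fiber = TRUE)
  sp <- ev1[ev1$kind == "spread", ]
  expect_setequal(sp$j, c(1L, 3L))
  expect_equal(sp$propensity, rep(p_def$k_n, 2))
})
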