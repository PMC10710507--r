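test_that("overall dissociation constant follows the scheme algebra", {
  p <- if_study_params()
  expect_rel_equal(overall_kd(p), 6e-9, 1e-12)
  expect_rel_equal(p$k_plus, 9.009009e5, 1e-6)

  # with no conformational sink the schemes reduce to one-step binding
  p_if <- mechanism_params("IF", 1e6, 0.5, k_e = 0.3, k_r = 0)
  expect_equal(overall_kd(p_if), 0.5 / 1e6)
  p_cs <- mechanism_params("CS", 1e6, 0.5, k_e = 0.3, k_r = 0)
  expect_equal(overall_kd(p_cs), 0.5 / 1e6)

  bad <- mechanism_params("IF", 0, 1, 1, 1)
  expect_error(overall_kd(bad), "k_plus")
})

test_that("k_plus inversion round-trips through overall_kd", {
  expect_rel_equal(k_plus_from_kd(6e-9, 0.005, 1.2, 0.6, "CS"), 1.25e6, 1e-12)
  set.seed(11)
  for (i in 1:50) {
    model <- if (i %% 2) "IF" else "CS"
    ks <- 10^runif(3, -3, 3)
    KD <- 10^runif(1, -9, -4)
    kp <- k_plus_from_kd(KD, ks[1], ks[2], ks[3], model)
    p <- mechanism_params(model, kp, ks[1], ks[2], ks[3])
    expect_rel_equal(overall_kd(p), KD, 1e-12)
    # identity round trip the other way
    expect_rel_equal(k_plus_from_kd(overall_kd(p), ks[1], ks[2], ks[3], model),
                     kp, 1e-12)
  }
  expect_error(k_plus_from_kd(-1e-9, 1, 1, 1, "IF"), "K_D")
  expect_error(k_plus_from_kd(6e-9, 1, 0, 1, "CS"), "k_e")
})

test_that("binding equilibrium solves the two-state quadratic", {
  # stoichiometric corner: K_D = 0
  eq <- equilibrium_delta(2e-6, 1e-6, 0)
  expect_equal(eq$delta, 1e-6)
  expect_equal(eq$L_free_eq, 1e-6)
  expect_equal(eq$RL_total_eq, 1e-6)

  eq <- equilibrium_delta(1e-6, 1e-6, 6e-9)
  expect_rel_equal(eq$delta, 1.550355e-7, 1e-6)
  # bound concentration satisfies the quadratic: L_free * R_free = K_D * RL
  r_free <- 1e-6 - eq$RL_total_eq
  expect_rel_equal(eq$L_free_eq * r_free, 6e-9 * eq$RL_total_eq, 1e-9)

  # vanishing receptor: no ligand depletion
  eq <- equilibrium_delta(1e-6, 1e-15, 6e-9)
  expect_rel_equal(eq$L_free_eq, 1e-6, 1e-6)

  # mass-balance invariants over a random grid
  set.seed(5)
  for (i in 1:100) {
    L0 <- 10^runif(1, -9, -4); P0 <- 10^runif(1, -9, -4)
    KD <- 10^runif(1, -10, -4)
    eq <- equilibrium_delta(L0, P0, KD)
    expect_gte(eq$RL_total_eq, -1e-20)
    expect_lte(eq$RL_total_eq, min(L0, P0) * (1 + 1e-12))
    expect_equal(eq$L_free_eq + eq$RL_total_eq, L0, tolerance = 1e-12)
  }
  expect_error(equilibrium_delta(-1e-6, 1e-6, 0), "L0")
})

test_that("closed-form relaxation rates match frozen oracle-checked values", {
  # induced fit at the study parameters, equimolar 1 uM mixing
  r <- relaxation_rates(if_study_params(), 1e-6, 1e-6)
  expect_rel_equal(r$k1, 1.755976, 1e-5)
  expect_rel_equal(r$k2, 0.0882902, 1e-5)
  # intermediates pin the auxiliary quantities individually
  expect_rel_equal(r$intermediates$delta, 1.550355e-7, 1e-6)
  gamma_direct <- -0.01 - 1.1 + 0.6 +
    if_study_params()$k_plus * (r$intermediates$delta - 6e-9)
  expect_equal(r$intermediates$gamma, gamma_direct, tolerance = 1e-12)

  # decoupled induced-fit corner (K_D = 0): exact eigenvalues 2 +/- sqrt(2)
  p0 <- mechanism_params("IF", 1e6, 1, k_e = 0, k_r = 1)
  r0 <- relaxation_rates(p0, 3e-6, 1e-6)
  expect_equal(r0$k1, 2 + sqrt(2), tolerance = 1e-9)
  expect_equal(r0$k2, 2 - sqrt(2), tolerance = 1e-9)

  # conformational selection at the study parameters
  rc <- relaxation_rates(cs_study_params(), 1e-6, 1e-6)
  expect_rel_equal(rc$k1, 1.833403, 1e-5)
  expect_rel_equal(rc$k2, 0.1268424, 1e-5)
  alpha <- rc$intermediates$alpha
  beta <- rc$intermediates$beta
  delta <- rc$intermediates$delta
  expect_equal(alpha, 0.6 - 1.2 + 0.005 * ((2 * 1.2 + 0.6) * delta +
                 0.6 * (1e-6 - 1e-6 - 6e-9)) / (2 * 1.2 * 6e-9),
               tolerance = 1e-12)
  expect_equal(beta, 2 * 0.6 * (2 * 1.2 - 0.005 -
                 0.005 * (delta - 1e-6 + 1e-6) / 6e-9), tolerance = 1e-12)

  # conformational-selection corner with k_r = 0: pure binding + conf rates
  pc <- mechanism_params("CS", 1e6, 1, k_e = 1, k_r = 0)
  rcc <- relaxation_rates(pc, 3e-6, 1e-6)
  expect_equal(rcc$k1, sqrt(13), tolerance = 1e-9)
  expect_equal(rcc$k2, 1, tolerance = 1e-9)
})

test_that("mass-action derivatives respect conservation and fixed points", {
  p <- if_study_params()
  st <- c(R1 = 1e-6, L = 1e-6, R1L = 2e-7, R2L = 1e-7)
  d <- mass_action_derivatives(st, p)
  expect_equal(unname(d["R1"] + d["R1L"] + d["R2L"]), 0)   # receptor total
  expect_equal(unname(d["L"] + d["R1L"] + d["R2L"]), 0)    # ligand total

  # all rates zero: frozen system
  pz <- mechanism_params("CS", 0, 0, k_e = 1e-300, k_r = 0)
  pz$k_e <- 0  # fully frozen corner for the derivative check only
  dz <- mass_action_derivatives(c(R1 = 1e-6, R2 = 1e-7, L = 1e-6, R2L = 0), pz)
  expect_true(all(dz == 0))

  # single active term: association only
  p1 <- mechanism_params("IF", 1e6, 0, k_e = 0, k_r = 1e-12)
  d1 <- mass_action_derivatives(c(R1 = 1e-6, L = 1e-6, R1L = 0, R2L = 0), p1)
  expect_equal(unname(d1["R1L"]), 1e-6, tolerance = 1e-15)

  # the analytic equilibrium is a fixed point
  for (mk in list(if_study_params(), cs_study_params())) {
    eqs <- relaxkin:::equilibrium_state(mk, 2e-6, 1e-6)
    deq <- mass_action_derivatives(eqs, mk)
    expect_lt(max(abs(deq)), 1e-12 * 1e-6)
  }

  expect_error(mass_action_derivatives(c(R1 = 1, L = 1), p), "species")
})

test_that("closed forms agree with the numerical eigenvalue oracle", {
  set.seed(101)
  for (i in 1:200) {
    model <- if (i %% 2) "IF" else "CS"
    p <- random_params(model)
    cc <- random_concentrations()
    r <- relaxation_rates(p, cc[1], cc[2])
    o <- eigenrate_oracle(p, cc[1], cc[2])
    expect_lt(abs(o$k1 - r$k1) / r$k1, 1e-8)
    expect_lt(abs(o$k2 - r$k2) / r$k2, 1e-8)
    # relaxation to a stable equilibrium: real, positive, ordered
    expect_gt(o$k2, 0)
    expect_gte(r$k1, r$k2)
  }
})

test_that("slow rate approaches the conformational limit at large ligand excess", {
  # pseudo-first-order limit: IF k2 -> k_e + k_r, CS k2 -> k_e
  L_big <- 1e4 * max(P0_STUDY, KD_STUDY)
  r_if <- relaxation_rates(if_study_params(), L_big, P0_STUDY)
  expect_rel_equal(r_if$k2, 0.01 + 1.1, 0.01)
  r_cs <- relaxation_rates(cs_study_params(), L_big, P0_STUDY)
  expect_rel_equal(r_cs$k2, 1.2, 0.01)
})
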