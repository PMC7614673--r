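# Shared fixtures. Expensive simulations are built once per test run and
# memoized here.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# noiseless flat detachment sequence, Fa = 0.5 mN
flat_sim <- function() fixture("flat_sim", function() {
  sc <- synthetic_scenario(Fa_N = 0.5e-3, curvature = 0, seed = 1)
  list(scenario = sc, sim = simulate_detachment_sequence(sc))
})

default_robot <- function() fixture("robot", robot_spec)

# uniform-magnetization robot for the linear cantilever oracle
axial_robot <- function() fixture("axial_robot", function() {
  mp <- magnetization_profile(6.5e-3, M0 = 62e3,
                              phase = function(s) rep(0, length(s)))
  robot_spec(magnetization = mp)
})

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
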