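# small custom networks used to exercise the generic (non-preset) code paths

# purely asymmetric divider: S = 0, constant death
network_all_asymmetric <- function(epsilon = 0.01) {
  control_network(
    L = function(x, y) 0.6,
    P = function(x, y) 0.5,
    D = function(x, y) 0.4,
    S = function(x, y) 0,
    epsilon = epsilon, name = "asym-test"
  )
}

# neutral drift in the stem compartment: S = 1, P = 1/2 everywhere
network_neutral <- function(epsilon = 0.01) {
  control_network(
    L = function(x, y) 0.5,
    P = function(x, y) 0.5,
    D = function(x, y) 0.5,
    S = function(x, y) 1,
    epsilon = epsilon, name = "neutral-test"
  )
}

# death-dominated system used to exercise the J >= 0 guard
network_death_heavy <- function(epsilon = 0.01) {
  control_network(
    L = function(x, y) 0.05,
    P = function(x, y) 0.5,
    D = function(x, y) 0.9,
    S = function(x, y) 0.5,
    epsilon = epsilon, name = "death-test"
  )
}
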