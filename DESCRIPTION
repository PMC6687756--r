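Package: closedloop
Title: Closed-Loop Simulation of Rate-Neuron Actor-Critic Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolchain for closed-loop reinforcement
    learning with networks of noisy rate neurons.  Provides a
    stochastic-exponential-Euler integrator for rate-neuron networks,
    place-cell population coding and action-decoding adapters, a
    continuous-time temporal-difference (actor-critic) learning rule with
    three-factor Hebbian plasticity and an eligibility-delay variant,
    built-in MountainCar and FrozenLake benchmark environments with
    reward shaping, a closed-loop driver with independent agent and
    environment update intervals, an optional socket bridge exchanging
    JSON messages, and a Q-learning baseline with multi-layer-perceptron
    function approximation for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
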