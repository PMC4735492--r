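Package: raidnet
Title: Agent-Based Simulation of Collective Raiding on Friendship Networks
Version: 0.1.0
Authors@R: person("Raidnet", "Maintainers", email = "maintainers@raidnet.invalid",
    role = c("aut", "cre"))
Description: Simulates the emergence and suppression of risky collective
    action (raiding) on fixed friendship networks. A small set of leaders
    recruits a raid nucleus within a social radius; the nucleus recruits its
    direct friends; a raid occurs when enough followers join. Coordination
    payoffs feed population-wide pairwise imitation learning. The package
    provides seeded Watts-Strogatz network fixtures, intervention experiments
    (population-level attitude bias and targeted 'saint'/'devil' control
    nodes placed randomly or on top-degree nodes), replicate batch runners,
    parameter sweeps, the Mean Risk-taking Ratio summary statistic with
    bootstrap intervals and regression fits, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
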