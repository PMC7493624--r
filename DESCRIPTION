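Package: emergesim
Title: Stochastic Seed-by-Seed Simulation of Soybean Seedling Emergence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates soybean germination parameters (base and optimum
    temperature, base water potential, thermal-time distribution) from
    laboratory time-courses via Gompertz fits and x-intercept regression,
    simulates seed-by-seed germination and seedling emergence in virtual
    seedbeds under daily weather at a daily time step, partitions
    non-emergence causes (non-germination, post-germination water stress,
    blocking by soil aggregates or surface crust), and evaluates predicted
    emergence courses against observations with model efficiency, root mean
    square error of prediction, and mean deviation. Includes a synthetic-data
    generator for lab time-courses, weather scenarios, and seedbed templates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
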