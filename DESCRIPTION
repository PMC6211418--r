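Package: sportabm
Title: Agent-Based Simulation of Sports Participation and Income Inequality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based model of adult sports participation in a gridded
    city. Individuals start, quit and restart sport in three categories
    (fitness centre, sports club, self-organized) at exponentially
    distributed times whose rate is a multiplicative tendency score built
    from age, sex, income, facility price and accessibility, neighbourhood
    safety and cohesion, and the participation of near neighbours. Sports
    facilities open and close annually in response to demand. The package
    ships a synthetic-city generator matching published aggregate city
    statistics, a calibration harness (grid search and scale calibration
    against participation targets), five intervention scenarios (health
    education, price reduction, facility availability, neighbourhood
    safety, and their combination) with matched counterfactuals under
    common random numbers, and run-ensemble uncertainty summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
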