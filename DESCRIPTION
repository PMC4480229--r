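Package: windrift
Title: Individual-Based Windage and Current Drift Modelling for Pleustonic
    Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lagrangian individual-based simulation of pleustonic (surface
    floating) organisms such as the Portuguese Man-of-War (Physalia physalis),
    advected by gridded surface currents plus a configurable windage fraction
    (default 10 percent) of the 10-m wind.  Provides generators for idealized
    coastal domains and flow fields (two-basin strait with an eastward jet,
    anticyclonic gyre basin, open coast with a slope current, episodic wind
    events), seeding of virtual populations in a bathymetric depth band,
    fourth-order Runge-Kutta trajectory integration with beaching detection,
    backward-trajectory source localization, aggregation of strandings into
    densities per 100 m of coastline with rank-based pattern comparison, and
    wind diagnostics (monthly zonal-wind climatology, winter anomaly ratios,
    bulk kinematic wind stress).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
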