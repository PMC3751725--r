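Package: cvloop
Title: Closed-Loop Lumped-Parameter Simulation of Cardiovascular
    Hemodynamics and Oxygen Transport
Version: 0.9.0
Authors@R:
    person("cvloop", "maintainers", email = "cvloop@example.org",
           role = c("aut", "cre"))
Description: A distributed lumped-parameter (0D) closed-loop model of the
    adult human cardiovascular system. Four cardiac chambers driven by
    Double-Hill time-varying elastance functions with a Starling
    contractility roll-off, nonlinear passive diastole, septal and
    pericardial coupling; gradually opening and closing heart valves with
    Bernoulli and inertial pressure gradients; Gorlin-orifice intracardiac
    and ductal shunts; a 26-segment nonlinear viscoelastic vascular network
    covering the systemic, pulmonary and coronary circulations; convective
    oxygen transport with pulmonary shunt and pressure-volume-area based
    myocardial oxygen consumption; and an optional baroreceptor reflex.
    The 62 coupled differential states are advanced with an implicit Euler
    scheme at a 0.25 ms time step.  Ships a calibrated baseline preset of a
    healthy resting adult plus pathology and maneuver scenarios (systolic
    and diastolic heart failure, aortic stenosis and regurgitation,
    Valsalva, exercise, arteriosclerosis), beat-level clinical metrics,
    one-at-a-time parameter sensitivity analysis, and a command line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
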