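Package: ncctrend
Title: Time-Trend-Adjusted Analysis of Platform Trials with Non-Concurrent Controls
Version: 0.1.0
Authors@R: person("Platform Trials", "Methods Group", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for designing, simulating, and analysing multi-arm platform
    trials in which experimental arms enter the trial in a staggered fashion
    and share a common control group.  When a late-entering arm is compared to
    control, control patients recruited before that arm opened (non-concurrent
    controls) can increase power, but temporal drift in the response can bias
    the comparison.  The package implements frequentist model-based
    adjustments for such time trends: fixed-effect regression on trial periods
    or fixed-length calendar-time intervals, B-spline regression on patient
    entry time, linear mixed models with independent or AR(1) random
    time-interval effects, and mixed models with a random treatment-by-time
    interaction that relax the equal-trends assumption.  A deterministic
    recruitment planner, a block-randomised trial simulator with four
    time-trend patterns (linear, stepwise, inverted-U, seasonal), and a
    Monte-Carlo harness for type I error and power studies are included,
    together with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    splines,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
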