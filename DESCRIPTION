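Package: csibreath
Title: Respiratory Rate Estimation from Wi-Fi Channel State Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Contactless respiratory rate (RR) estimation from the subcarrier
    magnitudes of a Wi-Fi channel state information (CSI) stream. Implements
    per-window principal component analysis with a component quality index,
    dual time-domain (breath counting) and frequency-domain (spectral peak)
    RR estimators, signal-quality weighting, and per-source Kalman filtering
    with inverse-variance fusion into a 1 Hz RR series. Ships a synthetic
    CSI/airflow session generator emulating a metronome-paced breathing
    protocol, an airflow-based reference RR pipeline with quartile-thresholded
    breath-peak detection, and Bland-Altman style agreement reporting, so the
    whole method can be exercised end to end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
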