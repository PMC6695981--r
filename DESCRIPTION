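Package: rbcg
Title: Heart Rate from Ballistocardiographic Head Movements in Facial Video
Version: 0.1.0
Authors@R:
    person("rbcg", "maintainers", email = "rbcg@example.org", role = c("aut", "cre"))
Description: Camera-based (non-contact) heart-rate estimation from the small
    vertical head oscillations produced by carotid blood flow (remote
    ballistocardiography). Tracks corner features on the forehead and nose of
    a facial video, extracts the cardiac component of the trajectories by
    Butterworth bandpass filtering, principal component analysis and a
    spectral-periodicity selector, converts it to a relative power density
    (RPD) feature over 0.75-2.5 Hz, and estimates heart rate with a
    kurtosis-gated k-means model matched by nearest-neighbour averaging.
    Includes peak-detection and FFT baselines, sliding-window
    leave-one-subject-out evaluation with Bland-Altman agreement analysis,
    and a synthetic-data generator (trajectories, ECG beat trains, textured
    videos) with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
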