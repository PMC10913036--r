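Package: oscillotrack
Title: Cortico-Acoustic Entrainment Analysis for Rhythmic Auditory Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying neural entrainment to rhythmic auditory
    stimulation. Synthesizes click and syllable token trains with parametric
    presentation rate and interstimulus-interval jitter, simulates
    source-level EEG cohorts with known von Mises brain-to-stimulus phase
    locking, projects source currents through a leadfield montage to the
    scalp and back, and measures entrainment with the band-scanned
    phase-locking value (PLV) between the Hilbert phase of the stimulus
    envelope and auditory-cortex source waveforms. Includes a
    cross-correlation control analysis and within-subject trend statistics
    for rate and periodicity designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
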