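Package: emegscan
Title: Combined EEG/MEG Dipole Deviation Scanning with Intracranial Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Source analysis of interictal epileptic spikes in simultaneous
    EEG/MEG recordings: a digital spherical-head phantom with propagating
    spike simulation, analytic four-shell EEG and spherical-conductor MEG
    forward models, template-based spike detection, bootstrap subaveraging
    with SNR gating, single-dipole deviation scanning for EEG, MEG and
    noise-normalized combined EEG/MEG (EMEG), skull-conductivity calibration
    from somatosensory evoked responses, and validation statistics against
    stereo-EEG contacts (centroid dipoles, outlier pruning, Square Distance
    Index, within-radius coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    readxl,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
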